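# Breeding-trial summaries and the study-wide statistical tests.
# Breeding records hold one row per litter (dam_id, group, month,
# pups_born, pups_weaned); a dam that never delivered is carried as a
# single row with NA month and zero pups so group denominators are
# preserved.

check_breeding <- function(records) {
  need <- c("dam_id", "group", "month", "pups_born", "pups_weaned")
  if (!all(need %in% names(records)))
    stop_adq("missing columns: ", paste(setdiff(need, names(records)), collapse = ", "))
  lit <- records[!is.na(records$month), ]
  if (any(lit$pups_weaned > lit$pups_born) || any(lit$pups_born < 0) ||
      any(lit$pups_weaned < 0))
    stop_adq("need 0 <= pups_weaned <= pups_born for every litter")
  records
}

#' Percentage of dams delivering at least one litter
#'
#' @param records breeding table (see module notes above).
#' @param group group label to summarize.
#' @return percentage (half-up, 2 decimals).
#' @export
percent_delivering <- function(records, group) {
  records <- check_breeding(records)
  r <- records[records$group == group, ]
  if (!nrow(r)) stop_adq("empty group: ", group)
  dams <- unique(r$dam_id)
  delivered <- vapply(dams, function(d) any(!is.na(r$month[r$dam_id == d])),
                      logical(1))
  round_half_up(100 * sum(delivered) / length(dams), 2)
}

#' Mean litter size of a group
#'
#' Total pups divided by total litters, the trial-level estimator; the
#' per-dam mean of per-dam ratios is also returned for comparison.
#'
#' @param records breeding table.
#' @param group group label.
#' @param at_weaning if `TRUE` (default) count pups alive at weaning,
#'   else pups born.
#' @return list `pooled` (total pups / total litters), `per_dam_mean`,
#'   `n_litters`, `n_pups`; pooled is `NA` (flagged) with zero litters.
#' @export
mean_litter_size <- function(records, group, at_weaning = TRUE) {
  records <- check_breeding(records)
  r <- records[records$group == group & !is.na(records$month), ]
  pupcol <- if (at_weaning) "pups_weaned" else "pups_born"
  if (!nrow(r))
    return(list(pooled = NA_real_, per_dam_mean = NA_real_,
                n_litters = 0L, n_pups = 0L, flag = "no litters"))
  per_dam <- tapply(r[[pupcol]], r$dam_id, function(p) sum(p) / length(p))
  list(pooled = sum(r[[pupcol]]) / nrow(r),
       per_dam_mean = mean(per_dam),
       n_litters = nrow(r), n_pups = sum(r[[pupcol]]), flag = NA_character_)
}

#' Cumulative pups per dam by month
#'
#' @param records breeding table.
#' @param months number of trial months (default 3).
#' @param at_weaning count pups at weaning (default) or at birth.
#' @return data frame, one row per dam with `group` and cumulative
#'   counts `month1..monthK` (non-decreasing by construction).
#' @export
cumulative_pups <- function(records, months = 3, at_weaning = TRUE) {
  records <- check_breeding(records)
  pupcol <- if (at_weaning) "pups_weaned" else "pups_born"
  dams <- unique(records[, c("dam_id", "group")])
  out <- lapply(seq_len(nrow(dams)), function(i) {
    r <- records[records$dam_id == dams$dam_id[i] & !is.na(records$month), ]
    monthly <- vapply(seq_len(months), function(m) sum(r[[pupcol]][r$month == m]),
                      numeric(1))
    cum <- cumsum(monthly)
    row <- as.data.frame(as.list(cum))
    names(row) <- paste0("month", seq_len(months))
    cbind(data.frame(dam_id = dams$dam_id[i], group = dams$group[i]), row)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exact two-sided Mann-Whitney p by full enumeration of the C(n+m, n)
# group-label assignments (tie-free samples only)
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(i) sum(outer(pooled[i], pooled[-i], ">")))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(u = u_obs, p = p)
}

#' Mann-Whitney U test (exact or tie-corrected normal)
#'
#' Exact two-sided p by full enumeration of label assignments when both
#' samples are small enough (`max(n) <= exact_max_n`) and the pooled
#' data are tie-free; otherwise the mid-rank U statistic with the
#' tie-corrected normal approximation and continuity correction.  The
#' two-sided exact p is the doubled smaller tail, capped at 1.
#'
#' @param x,y numeric samples.
#' @param exact_max_n largest group size for the enumeration path.
#' @return list `statistic` (U, number of (x, y) pairs with x > y, with
#'   ties counted 1/2), `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_adq("both samples must be non-empty")
  if (anyNA(c(x, y))) stop_adq("missing values are not supported")
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && max(length(x), length(y)) <= exact_max_n) {
    e <- mw_exact_p(x, y)
    return(list(statistic = e$u, p = e$p, method = "exact"))
  }
  n <- length(x); m <- length(y); N <- n + m
  rk <- rank(c(x, y))                       # mid-ranks
  u <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  tie_tab <- table(c(x, y))
  tiesum <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n * m / 12 * ((N + 1) - tiesum / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1, method = "normal"))
  z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
  list(statistic = u, p = min(1, 2 * stats::pnorm(-z)),
       method = "tie-corrected normal")
}

#' Two-way ANOVA with interaction
#'
#' Ordinary two-factor analysis of variance (main effects + interaction)
#' via `stats::aov`, as used for cumulative pup counts over time.  Note
#' the repeated-measures structure of per-dam series is deliberately not
#' modelled, mirroring the plain two-way layout; terms with a zero sum
#' of squares report F = 0.
#'
#' @param values numeric response.
#' @param factor_group,factor_time the two factors.
#' @return data frame per term: `term`, `df`, `sum_sq`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_group, factor_time) {
  g <- factor(factor_group); t <- factor(factor_time)
  if (nlevels(g) < 2 || nlevels(t) < 2)
    stop_adq("both factors need at least two levels")
  fit <- stats::aov(values ~ g * t)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  term[term == "g"] <- "group"; term[term == "t"] <- "time"
  term[term == "g:t"] <- "group:time"
  out <- data.frame(term = term, df = tab$Df, sum_sq = tab$`Sum Sq`,
                    F = tab$`F value`, p = tab$`Pr(>F)`)
  zero <- !is.na(out$sum_sq) & out$sum_sq < .Machine$double.eps^0.5 &
    out$term != "Residuals"
  out$F[zero] <- 0
  out$p[zero] <- 1
  out
}

#' Cohort ledger check
#'
#' Sums per-arm euthanasia group sizes across timepoints and, when
#' declared enrolments are supplied, reports whether they are consistent.
#'
#' @param sizes_by_timepoint named list: one integer vector of group
#'   sizes per arm.
#' @param declared optional named vector of declared enrolments.
#' @return data frame `arm`, `total` (and `declared`, `consistent` when
#'   declared enrolments are given).
#' @export
cohort_ledger_check <- function(sizes_by_timepoint, declared = NULL) {
  tot <- vapply(sizes_by_timepoint, function(v) {
    if (length(v) && (any(v < 0) || any(v != floor(v))))
      stop_adq("group sizes must be non-negative integers")
    as.integer(sum(v))
  }, integer(1))
  out <- data.frame(arm = names(tot), total = as.integer(tot))
  if (!is.null(declared)) {
    out$declared <- as.integer(declared[out$arm])
    out$consistent <- out$total == out$declared
  }
  rownames(out) <- NULL
  out
}
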