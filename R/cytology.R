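# Estrous-stage calling from vaginal smear cell composition and
# cyclicity metrics over a daily observation window.  A smear carries
# counts of nucleated epithelial cells, cornified epithelial cells and
# leukocytes; stages are called by deterministic rules mirroring the
# classic cytological descriptions:
#   1. cornified AND leukocyte fractions both substantial -> metestrus
#      (the sloughing stage mixes the two),
#   2. else leukocytes at very high density -> diestrus,
#   3. else the majority cell type decides (nucleated -> proestrus,
#      cornified -> estrus, leukocyte -> diestrus).

#' Call the estrous stage of a single smear
#'
#' @param n_nucleated,n_cornified,n_leukocyte non-negative cell counts.
#' @param m_lo metestrus rule: minimum fraction that both cornified
#'   cells and leukocytes must reach (default 0.25).
#' @param d_hi diestrus rule: leukocyte fraction called "very high
#'   density" (default 0.60).
#' @return list with `stage` (factor), `fractions` (named, sums to 1)
#'   and `rule` (which rule fired).
#' @export
classify_stage <- function(n_nucleated, n_cornified, n_leukocyte,
                           m_lo = 0.25, d_hi = 0.60) {
  cnt <- c(nucleated = n_nucleated, cornified = n_cornified,
           leukocyte = n_leukocyte)
  if (any(cnt < 0) || any(cnt != floor(cnt))) stop_adq("counts must be non-negative integers")
  tot <- sum(cnt)
  if (tot == 0) stop_adq("uncallable smear: all cell counts are zero")
  fr <- cnt / tot
  if (fr[["cornified"]] >= m_lo && fr[["leukocyte"]] >= m_lo) {
    stage <- "metestrus"; rule <- "cornified+leukocyte combination"
  } else if (fr[["leukocyte"]] >= d_hi) {
    stage <- "diestrus"; rule <- "leukocyte high density"
  } else {
    maj <- names(fr)[which.max(fr)]   # deterministic: first maximum
    stage <- switch(maj, nucleated = "proestrus", cornified = "estrus",
                    leukocyte = "diestrus")
    rule <- paste("majority", maj)
  }
  list(stage = factor(stage, levels = ESTROUS_STAGES),
       fractions = fr, rule = rule)
}

#' Call stages for a table of daily smears
#'
#' @param smears data frame with columns `day`, `n_nucleated`,
#'   `n_cornified`, `n_leukocyte` (optionally `mouse_id`).
#' @inheritParams classify_stage
#' @return the input with `stage` and `rule` columns appended; days
#'   whose counts are all `NA` (failed smears) get `stage = NA`.
#' @export
classify_stages <- function(smears, m_lo = 0.25, d_hi = 0.60) {
  need <- c("day", "n_nucleated", "n_cornified", "n_leukocyte")
  if (!all(need %in% names(smears))) stop_adq("missing columns: ",
    paste(setdiff(need, names(smears)), collapse = ", "))
  stage <- rep(NA_character_, nrow(smears))
  rule <- rep(NA_character_, nrow(smears))
  for (i in seq_len(nrow(smears))) {
    cnt <- as.numeric(smears[i, c("n_nucleated", "n_cornified", "n_leukocyte")])
    if (anyNA(cnt)) next                       # gap day
    cl <- classify_stage(cnt[1], cnt[2], cnt[3], m_lo = m_lo, d_hi = d_hi)
    stage[i] <- as.character(cl$stage)
    rule[i] <- cl$rule
  }
  smears$stage <- factor(stage, levels = ESTROUS_STAGES)
  smears$rule <- rule
  smears
}

#' Percentage of observed days spent in each stage
#'
#' Gap days (NA calls) are excluded from the denominator.
#'
#' @param stages vector of stage calls (character/factor, NA = gap).
#' @return named numeric vector over the four stages, summing to 100.
#' @export
stage_percentages <- function(stages) {
  s <- factor(as.character(stages), levels = ESTROUS_STAGES)
  s <- s[!is.na(s)]
  if (!length(s)) stop_adq("no callable days in the window")
  p <- 100 * as.vector(table(s)) / length(s)
  names(p) <- ESTROUS_STAGES
  p
}

#' Count completed estrous cycles in an observation window
#'
#' A cycle is counted at each entry into estrus (an estrus day whose
#' previous called day is not estrus; the first called day being estrus
#' also counts as an entry) that is followed, before the next estrus
#' entry, by at least one metestrus or diestrus day.  Gap days are
#' stage-unknown: they neither create an entry nor complete a cycle.
#'
#' @param stages vector of stage calls in day order (NA = gap).
#' @return integer number of completed cycles.
#' @export
count_cycles <- function(stages) {
  s <- as.character(stages)
  s <- s[!is.na(s)]                  # gaps break nothing either way
  if (length(s) < 2) return(0L)
  entries <- which(s == "estrus" & c(TRUE, s[-length(s)] != "estrus"))
  if (!length(entries)) return(0L)
  completed <- 0L
  bounds <- c(entries[-1] - 1L, length(s))
  for (k in seq_along(entries)) {
    span <- s[entries[k]:bounds[k]]
    if (any(span %in% c("metestrus", "diestrus"))) completed <- completed + 1L
  }
  completed
}

#' Per-mouse cyclicity metrics from a smear table
#'
#' @param smears table as in [classify_stages()], with a `mouse_id`
#'   column; stages are called if not already present.
#' @inheritParams classify_stage
#' @return data frame per mouse: completed cycles and percent of days
#'   per stage.
#' @export
cyclicity_metrics <- function(smears, m_lo = 0.25, d_hi = 0.60) {
  if (!"mouse_id" %in% names(smears)) smears$mouse_id <- "m1"
  if (!"stage" %in% names(smears))
    smears <- classify_stages(smears, m_lo = m_lo, d_hi = d_hi)
  out <- lapply(split(smears, smears$mouse_id), function(d) {
    d <- d[order(d$day), ]
    p <- stage_percentages(d$stage)
    data.frame(mouse_id = d$mouse_id[1],
               n_cycles = count_cycles(d$stage),
               pct_proestrus = p[["proestrus"]], pct_estrus = p[["estrus"]],
               pct_metestrus = p[["metestrus"]], pct_diestrus = p[["diestrus"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
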