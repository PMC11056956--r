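# Independent brute-force oracles used across the suite.  These are
# deliberately written as naive loops, separate from the package's
# implementation paths.

# Otsu oracle: exhaustive search over all 256 candidate thresholds,
# minimizing the weighted within-class variance of the raw values.
oracle_otsu <- function(values) {
  values <- as.integer(values)
  best_t <- NA_integer_
  best_w <- Inf
  for (t in 0:254) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    # population variances, weighted by class probability
    pv <- function(v) mean((v - mean(v))^2)
    w <- (length(lo) * pv(lo) + length(hi) * pv(hi)) / length(values)
    if (w < best_w - 1e-12) {   # strict improvement -> lowest minimizer kept
      best_w <- w
      best_t <- t
    }
  }
  best_t
}

# even-odd point-in-polygon oracle: scalar crossing count per point,
# same half-open convention as the package (left/top edges inside)
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    x2 <- poly[k %% n + 1, 1]; y2 <- poly[k %% n + 1, 2]
    if (y1 == y2) next
    if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
      xi <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (xi <= x) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracle_polygon_mask <- function(poly, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    m[i, j] <- oracle_point_in_polygon(j - 1, i - 1, poly)
  m
}

# distance oracle: minimum distance to a dense sampling of the polygon
# outline (sub-pixel steps), accurate to ~step/2
oracle_boundary_distance <- function(px, py, poly, step = 0.05) {
  n <- nrow(poly)
  bx <- numeric(0); by <- numeric(0)
  for (k in seq_len(n)) {
    p1 <- poly[k, ]; p2 <- poly[k %% n + 1, ]
    len <- sqrt(sum((p2 - p1)^2))
    t <- seq(0, 1, by = min(1, step / max(len, 1e-9)))
    bx <- c(bx, p1[1] + t * (p2[1] - p1[1]))
    by <- c(by, p1[2] + t * (p2[2] - p1[2]))
  }
  vapply(seq_along(px), function(i) sqrt(min((bx - px[i])^2 + (by - py[i])^2)),
         numeric(1))
}

# random intensity sample with a bimodal histogram (for Otsu checks)
random_bimodal_sample <- function(n = 400) {
  mu <- sort(sample(0:255, 2))
  v <- c(round(rnorm(n %/% 2, mu[1], sample(3:20, 1))),
         round(rnorm(n - n %/% 2, mu[2], sample(3:20, 1))))
  pmax(0, pmin(255, v))
}

# naive litter-size oracle
oracle_mean_litter_size <- function(records, grp, weaning) {
  tot <- 0; nl <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$group != grp || is.na(r$month)) next
    tot <- tot + if (weaning) r$pups_weaned else r$pups_born
    nl <- nl + 1
  }
  tot / nl
}
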