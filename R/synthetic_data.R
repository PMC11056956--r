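# Synthetic-data generators.  Every pipeline input can be produced here
# with known ground truth: geometric fluorescence phantoms (disk nuclei,
# no histology texture), estrous-cycle smear series, Ct tables with
# programmed fold changes, and cohort fixtures reconstructed from
# printed percentages.  All generators are bit-reproducible under a
# fixed seed.

#' Parameters for a trichrome fluorescence phantom
#'
#' The phantom is a rectangular studied region holding a luminal
#' epithelium band, two circular glands, and stroma; nuclei are
#' identical non-overlapping disks fully inside their compartment, so
#' area-based ground truth is exact: painting a fraction f of the disks
#' red makes the red/blue area ratio exactly round(f * n) / n.
#'
#' @param width,height image size in pixels.
#' @param nucleus_radius disk radius in pixels (must fit in the image).
#' @param n_nuclei named integer vector: nuclei per compartment
#'   (epithelium, glands, stroma).
#' @param pgr_positive_fraction named vector in \[0, 1\]: fraction of
#'   nuclei that are PGR-positive (red), per compartment.
#' @param noise background noise level in \[0, 1): each pixel of every
#'   channel gets an independent uniform integer offset in
#'   \[0, noise * 255\].
#' @param signal intensity painted for positive pixels.
#' @param pixel_size micrometres per pixel (metadata).
#' @param seed integer random seed; fixes the output bit-exactly.
#' @return validated parameter list of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 160, height = 160, nucleus_radius = 3,
                             n_nuclei = c(epithelium = 30, glands = 30, stroma = 90),
                             pgr_positive_fraction = c(epithelium = 0.8, glands = 0.6, stroma = 0.6),
                             noise = 0, signal = 220, pixel_size = 0.65,
                             seed = 1) {
  comp <- c("epithelium", "glands", "stroma")
  if (!all(comp %in% names(n_nuclei)) || any(n_nuclei < 0) || any(n_nuclei != floor(n_nuclei)))
    stop_adq("n_nuclei must name non-negative counts for ", paste(comp, collapse = ", "))
  if (!all(comp %in% names(pgr_positive_fraction)) ||
      any(pgr_positive_fraction < 0) || any(pgr_positive_fraction > 1))
    stop_adq("pgr_positive_fraction must name values in [0, 1] for each compartment")
  if (noise < 0 || noise >= 1) stop_adq("noise must lie in [0, 1)")
  if (nucleus_radius < 1) stop_adq("nucleus_radius must be >= 1")
  if (2 * nucleus_radius >= min(width, height))
    stop_adq("nucleus radius too large for the image size")
  if (width < 64 || height < 64) stop_adq("image must be at least 64 x 64 px")
  structure(list(width = as.integer(width), height = as.integer(height),
                 nucleus_radius = as.integer(nucleus_radius),
                 n_nuclei = n_nuclei[comp],
                 pgr_positive_fraction = pgr_positive_fraction[comp],
                 noise = noise, signal = as.integer(signal),
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "image_sim_params")
}

# phantom layout: fixed polygons given the image size
phantom_rois <- function(w, h) {
  m <- 18                      # studied region inset; leaves a muscle band outside
  bh <- round((h - 2 * m) * 0.22)
  total <- rbind(c(m, m), c(w - 1 - m, m), c(w - 1 - m, h - 1 - m), c(m, h - 1 - m))
  epi <- rbind(c(m, m), c(w - 1 - m, m), c(w - 1 - m, m + bh), c(m, m + bh))
  r <- round(min(w, h) * 0.14)
  cy <- m + bh + (h - 2 * m - bh) * 0.45
  g1 <- circle_polygon(m + (w - 2 * m) * 0.30, cy, r, 24)
  g2 <- circle_polygon(m + (w - 2 * m) * 0.70, cy, r, 24)
  compartment_rois(total, luminal_epithelium = epi, glands = list(g1, g2))
}

disk_offsets <- function(r) {
  d <- expand.grid(dx = -r:r, dy = -r:r)
  d[d$dx^2 + d$dy^2 <= r^2, ]
}

# rejection-sample k non-overlapping disk centres fully inside `mask`
place_nuclei <- function(mask, k, r, forbidden, max_tries = 50000) {
  if (k == 0) return(cbind(x = integer(0), y = integer(0)))
  off <- disk_offsets(r)
  nr <- nrow(mask); nc <- ncol(mask)
  cand <- which(mask)
  cx <- ceiling(cand / nr) - 1L
  cy <- (cand - 1L) %% nr
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0
  # centre distance strictly > 2r guarantees disjoint disk pixel sets
  min_d2 <- (2 * r)^2
  while (nrow(centres) < k) {
    tries <- tries + 1
    if (tries > max_tries)
      stop_adq("could not place ", k, " non-overlapping nuclei; compartment too crowded")
    i <- sample.int(length(cand), 1)
    x <- cx[i]; y <- cy[i]
    px <- x + off$dx; py <- y + off$dy
    if (any(px < 0 | px >= nc | py < 0 | py >= nr)) next
    if (!all(mask[cbind(py + 1, px + 1)])) next
    if (any(forbidden[cbind(py + 1, px + 1)])) next
    if (nrow(centres) &&
        any((centres[, 1] - x)^2 + (centres[, 2] - y)^2 <= min_d2)) next
    centres <- rbind(centres, c(x, y))
  }
  colnames(centres) <- c("x", "y")
  centres
}

paint_disks <- function(mat, centres, r, value) {
  off <- disk_offsets(r)
  nr <- nrow(mat)
  for (i in seq_len(nrow(centres))) {
    px <- centres[i, 1] + off$dx
    py <- centres[i, 2] + off$dy
    mat[cbind(py + 1, px + 1)] <- value
  }
  mat
}

#' Simulate a trichrome fluorescence phantom with known ground truth
#'
#' Builds the compartment ROIs, scatters non-overlapping disk nuclei in
#' each compartment (blue channel), paints the chosen PGR-positive
#' subset into the red channel (red area is a subset of blue area by
#' construction), marks a muscle band outside the studied region in
#' green, then adds background noise.
#'
#' @param params an [image_sim_params].
#' @return list: `image` ([trichrome_image]), `rois`
#'   ([compartment_rois]), `masks` (ground-truth compartment masks),
#'   `truth` (per-compartment nucleus counts and true positive
#'   fraction), `centres` (per-compartment disk centres), `params`.
#' @export
simulate_trichrome_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  withr::with_seed(params$seed, {
    w <- params$width; h <- params$height; r <- params$nucleus_radius
    rois <- phantom_rois(w, h)
    blank <- trichrome_image(matrix(0L, h, w), matrix(0L, h, w), matrix(0L, h, w))
    masks <- decompose_compartments(blank, rois)
    comp <- c("epithelium", "glands", "stroma")
    red <- matrix(0L, h, w); green <- matrix(0L, h, w); blue <- matrix(0L, h, w)
    occupied <- matrix(FALSE, h, w)
    centres <- list(); truth <- list()
    for (cm in comp) {
      n <- params$n_nuclei[[cm]]
      ctr <- place_nuclei(masks[[cm]], n, r, occupied)
      occupied <- paint_disks(occupied, ctr, r, TRUE)
      blue <- paint_disks(blue, ctr, r, params$signal)
      k <- round(params$pgr_positive_fraction[[cm]] * n)
      pos <- if (k > 0) ctr[sample.int(n, k), , drop = FALSE]
             else ctr[integer(0), , drop = FALSE]
      red <- paint_disks(red, pos, r, params$signal)
      centres[[cm]] <- ctr
      truth[[cm]] <- data.frame(compartment = cm, n_nuclei = n, n_positive = k,
                                true_fraction = if (n > 0) k / n else NA_real_)
    }
    # muscle band: frame between the image border inset and the studied region
    band <- matrix(FALSE, h, w)
    band[5:(h - 4), 5:(w - 4)] <- TRUE
    band[13:(h - 12), 13:(w - 12)] <- FALSE
    green[band] <- 200L
    if (params$noise > 0) {
      lim <- params$noise * 255
      addn <- function(ch) {
        ch <- ch + matrix(floor(stats::runif(h * w) * lim), h, w)
        matrix(pmin(255L, as.integer(ch)), h, w)
      }
      red <- addn(red); green <- addn(green); blue <- addn(blue)
    }
    list(image = trichrome_image(red, green, blue, pixel_size = params$pixel_size),
         rois = rois, masks = masks,
         truth = do.call(rbind, truth), centres = centres, params = params)
  })
}

#' Parameters for an estrous-cycle smear simulation
#'
#' Defaults follow the canonical mouse cycle (proestrus 1 d, estrus 2 d,
#' metestrus 1 d, diestrus 2 d; about 4-6 days per cycle); adenomyosis
#' is emulated by multiplying the estrus duration by
#' `estrus_prolongation`.  Per-stage cell-composition profiles give the
#' expected fractions of nucleated epithelial, cornified epithelial and
#' leukocyte cells; daily counts are multinomial draws.
#'
#' @param stage_days named durations (days) of the four stages.
#' @param estrus_prolongation multiplier on the estrus duration (1 =
#'   control).
#' @param composition 4 x 3 matrix of per-stage expected cell fractions
#'   (rows proestrus/estrus/metestrus/diestrus; rows sum to 1).
#' @param cells_per_smear total cells counted per smear.
#' @param days observation length in days.
#' @param jitter if `TRUE`, stage durations are geometrically jittered
#'   around their means instead of fixed integers.
#' @param seed integer random seed.
#' @return validated parameter list of class `cycle_sim_params`.
#' @export
cycle_sim_params <- function(stage_days = c(proestrus = 1, estrus = 2,
                                            metestrus = 1, diestrus = 2),
                             estrus_prolongation = 1,
                             composition = NULL,
                             cells_per_smear = 100, days = 14,
                             jitter = FALSE, seed = 1) {
  if (is.null(composition)) {
    composition <- rbind(proestrus = c(0.80, 0.15, 0.05),
                         estrus = c(0.05, 0.90, 0.05),
                         metestrus = c(0.10, 0.45, 0.45),
                         diestrus = c(0.10, 0.15, 0.75))
    colnames(composition) <- c("nucleated", "cornified", "leukocyte")
  }
  if (!all(ESTROUS_STAGES %in% names(stage_days)) || any(stage_days <= 0))
    stop_adq("stage_days must name positive durations for all four stages")
  if (estrus_prolongation <= 0) stop_adq("estrus_prolongation must be > 0")
  if (!all(dim(composition) == c(4, 3)) ||
      any(abs(rowSums(composition) - 1) > 1e-9) || any(composition < 0))
    stop_adq("composition must be 4 x 3 with rows summing to 1")
  rownames(composition) <- ESTROUS_STAGES
  if (days < 1 || cells_per_smear < 1) stop_adq("days and cells_per_smear must be >= 1")
  structure(list(stage_days = stage_days[ESTROUS_STAGES],
                 estrus_prolongation = estrus_prolongation,
                 composition = composition,
                 cells_per_smear = as.integer(cells_per_smear),
                 days = as.integer(days), jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "cycle_sim_params")
}

#' Simulate a daily smear series with true stage labels
#'
#' @param params a [cycle_sim_params].
#' @return data frame per day: `day`, `stage_true`, `n_nucleated`,
#'   `n_cornified`, `n_leukocyte`.
#' @export
simulate_cycles <- function(params = cycle_sim_params()) {
  stopifnot(inherits(params, "cycle_sim_params"))
  withr::with_seed(params$seed, {
    dur <- params$stage_days
    dur[["estrus"]] <- dur[["estrus"]] * params$estrus_prolongation
    labels <- character(0)
    while (length(labels) < params$days) {
      cyc <- unlist(lapply(ESTROUS_STAGES, function(st) {
        d <- if (params$jitter) stats::rgeom(1, 1 / dur[[st]]) + 1
             else max(1L, as.integer(round(dur[[st]])))
        rep(st, d)
      }))
      labels <- c(labels, cyc)
    }
    labels <- labels[seq_len(params$days)]
    counts <- t(vapply(labels, function(st)
      as.integer(stats::rmultinom(1, params$cells_per_smear,
                                  params$composition[st, ])),
      integer(3)))
    data.frame(day = seq_len(params$days),
               stage_true = factor(labels, levels = ESTROUS_STAGES),
               n_nucleated = counts[, 1], n_cornified = counts[, 2],
               n_leukocyte = counts[, 3], row.names = NULL)
  })
}

#' Simulate a duplicate-well Ct table with programmed fold changes
#'
#' Target Cts in the case group are shifted by -log2(fold) relative to
#' control, so the programmed fold change is recovered exactly by
#' [delta_delta_ct()] on noiseless tables.
#'
#' @param fold_changes named vector: programmed case/control fold change
#'   per target gene.
#' @param n_per_group samples per group.
#' @param noise_sd Gaussian well-level Ct noise (cycles).
#' @param base_ct control-group target Ct.
#' @param reference_cts named Cts of the two housekeepers.
#' @param seed integer random seed.
#' @return well-level data frame: `sample_id`, `group`, `gene`, `well`, `ct`.
#' @export
simulate_ct_table <- function(fold_changes = c(Pgr = 0.5), n_per_group = 8,
                              noise_sd = 0, base_ct = 24,
                              reference_cts = c(Rplp0 = 18, Gapdh = 16),
                              seed = 1) {
  stopifnot(all(fold_changes > 0), n_per_group >= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    rows <- list()
    for (grp in c("control", "adenomyosis")) {
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", grp, i)
        genes <- c(reference_cts,
                   vapply(names(fold_changes), function(g) {
                     base_ct + if (grp == "control") 0 else -log2(fold_changes[[g]])
                   }, numeric(1)))
        for (g in names(genes)) for (wl in 1:2) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, group = grp, gene = g, well = wl,
            ct = genes[[g]] + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Build a synthetic transcript embedding a primer pair
#'
#' Constructs `5'pad + forward + spacer + revcomp(reverse) + 3'pad` with
#' random filler such that (a) both primers bind uniquely, (b) the
#' in-silico product size equals `product_bp`, and (c) the concatenated
#' forward+reverse string has a unique valid split point.  This is a
#' synthetic stand-in for a reference transcript, suitable for testing
#' the amplicon machinery offline; it is not the real sequence.
#'
#' @param forward,reverse primer sequences (5'-3').
#' @param product_bp desired product size (>= total primer length).
#' @param pad_5,pad_3 lengths of the flanking filler.
#' @param seed integer random seed (incremented internally until the
#'   uniqueness constraints hold; deterministic).
#' @return character transcript sequence.
#' @export
simulate_transcript <- function(forward, reverse, product_bp,
                                pad_5 = 30, pad_3 = 30, seed = 1) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  spacer_len <- product_bp - nchar(forward) - nchar(reverse)
  if (spacer_len < 0) stop_adq("product_bp smaller than the primers themselves")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(reverse)))
  for (s in seed + 0:49) {
    tx <- withr::with_seed(s, {
      rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
      paste0(rnd(pad_5), forward, rnd(spacer_len), rc, rnd(pad_3))
    })
    ok <- tryCatch({
      # the split-scan only applies when both primers reach its minimum length
      if (min(nchar(forward), nchar(reverse)) >= 15)
        split_concatenated_primers(paste0(forward, reverse), tx)
      insilico_pcr(forward, reverse, tx) == product_bp
    }, error = function(e) FALSE)
    if (isTRUE(ok)) return(tx)
  }
  stop_adq("could not build a transcript satisfying the uniqueness constraints")
}

#' Reconstruct integer counts from printed percentages
#'
#' Finds the smallest denominator n (and the counts) such that every
#' count / n, expressed as a percentage rounded half-up to two decimals,
#' reproduces the printed value exactly.  This inverts pie-chart /
#' text percentages into an exact cohort fixture.
#'
#' @param percentages numeric vector of printed percentages (2-decimal),
#'   each in (0, 100), summing to about 100.
#' @param n_max largest denominator to try.
#' @return list `n`, `counts` (non-negative integers summing to `n`).
#' @export
reconstruct_counts_from_percentages <- function(percentages, n_max = 500) {
  p <- as.numeric(percentages)
  if (any(p <= 0 | p >= 100)) stop_adq("percentages must lie in (0, 100)")
  if (abs(sum(p) - 100) > 0.2) stop_adq("percentages must sum to ~100")
  for (n in seq_len(n_max)) {
    cand <- lapply(p, function(pi) {
      k <- max(0, floor(pi * n / 100) - 1):min(n, ceiling(pi * n / 100) + 1)
      k[abs(round_half_up(100 * k / n, 2) - pi) < 1e-9]
    })
    if (any(vapply(cand, length, integer(1)) == 0)) next
    grid <- as.matrix(expand.grid(cand))
    hit <- which(rowSums(grid) == n)
    if (length(hit)) {
      counts <- as.integer(grid[hit[1], ])
      return(list(n = n, counts = counts))
    }
  }
  stop_adq("no consistent denominator n <= ", n_max, " reproduces these percentages")
}

# unique count in 0..n whose percentage re-rounds to p (errors otherwise)
count_matching_percentage <- function(p, n) {
  k <- (0:n)[abs(round_half_up(100 * (0:n) / n, 2) - p) < 1e-9]
  if (length(k) != 1)
    stop_adq(length(k), " counts of ", n, " round to ", p, "% (need exactly one)")
  as.integer(k)
}

#' Cohort grade fixture reconstructed from printed proportions
#'
#' Per-mouse grade labels for the treated 3-month cohort, reconstructed
#' by smallest-denominator percentage matching of the published grade
#' shares (1.47 / 2.94 / 4.41 / 91.18 % for grades 0/I/II/III, giving
#' n = 68 with counts 1, 2, 3, 62).  Note the study enrolment ledger
#' reports 55 treated mice euthanized at 3 months while these shares
#' imply a denominator of 68; the fixture follows the percentages and
#' the discrepancy is documented, not resolved.
#'
#' @param percentages grade-0/I/II/III percentages to invert.
#' @return data frame `mouse_id`, `group`, `grade`.
#' @export
cohort_grade_fixture <- function(percentages = c(1.47, 2.94, 4.41, 91.18)) {
  rec <- reconstruct_counts_from_percentages(percentages)
  data.frame(mouse_id = sprintf("adm_%02d", seq_len(rec$n)),
             group = "adenomyosis",
             grade = rep(GRADE_LEVELS, rec$counts))
}

#' Breeding-trial fixture matching the printed group outcomes
#'
#' Six control dams, all delivering (100 %), and six
#' adenomyosis-induced dams of which the number delivering is the
#' unique count whose share of 6 re-rounds to the printed 33.33 %
#' (i.e. 2 dams).  Litter sizes are deterministic synthetic values
#' consistent with the printed group means (control 220 pups over 17
#' litters = 12.94/litter; adenomyosis 19 pups over 3 litters =
#' 6.33/litter, at weaning).
#'
#' @return breeding table: `dam_id`, `group`, `month`, `pups_born`,
#'   `pups_weaned` (NA month = dam never delivered).
#' @export
make_breeding_fixture <- function() {
  adm_deliver <- count_matching_percentage(33.33, 6)
  ctl <- list()
  for (i in 1:5)
    ctl[[i]] <- data.frame(dam_id = sprintf("ctl_%d", i), group = "control",
                           month = 1:3, pups_born = c(13, 13, 13),
                           pups_weaned = c(13, 13, 13))
  ctl[[6]] <- data.frame(dam_id = "ctl_6", group = "control",
                         month = 1:2, pups_born = c(13, 12),
                         pups_weaned = c(13, 12))
  adm <- list(
    data.frame(dam_id = "adm_1", group = "adenomyosis", month = 1,
               pups_born = 7, pups_weaned = 7),
    data.frame(dam_id = "adm_2", group = "adenomyosis", month = 2:3,
               pups_born = c(6, 6), pups_weaned = c(6, 6)))
  barren <- lapply((adm_deliver + 1):6, function(i)
    data.frame(dam_id = sprintf("adm_%d", i), group = "adenomyosis",
               month = NA_integer_, pups_born = 0, pups_weaned = 0))
  out <- do.call(rbind, c(ctl, adm[seq_len(adm_deliver)], barren))
  rownames(out) <- NULL
  out
}
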