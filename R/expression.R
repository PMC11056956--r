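# Relative expression analysis: 2^-ddCt qPCR with two reference genes
# (Rplp0 and Gapdh by default, combined as the arithmetic mean of their
# Cts, i.e. geometric-mean normalization on the linear scale) and
# Western-blot densitometry fold changes against a loading control.

#' Collapse replicate Ct wells to a mean with a QC flag
#'
#' @param ct_table data frame with `sample_id`, `group`, `gene`, `ct`
#'   (one row per well; a `well` column is allowed and ignored).
#' @param max_range replicate range (cycles) above which a sample/gene
#'   pair is flagged (default 0.5).
#' @return data frame per sample x gene: `ct_mean`, `ct_range`,
#'   `n_wells`, `flagged`.
#' @export
collapse_replicates <- function(ct_table, max_range = 0.5) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stop_adq("missing columns: ", paste(setdiff(need, names(ct_table)), collapse = ", "))
  if (any(ct_table$ct <= 0)) stop_adq("Ct values must be positive")
  key <- interaction(ct_table$sample_id, ct_table$gene, drop = TRUE)
  out <- lapply(split(ct_table, key), function(d) {
    rng <- diff(range(d$ct))
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               gene = d$gene[1], ct_mean = mean(d$ct), ct_range = rng,
               n_wells = nrow(d), flagged = rng > max_range)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, the reference Ct is the arithmetic mean of the two
#' housekeeper mean-Cts; dCt = Ct(target) - Ct(ref); ddCt subtracts the
#' mean control-group dCt of that target; fold = 2^-ddCt (amplification
#' efficiency fixed at 2).  Samples missing a reference gene are
#' excluded with a warning.
#'
#' @param ct_table well-level table as in [collapse_replicates()].
#' @param reference_genes the two housekeeping genes.
#' @param control_group label of the calibrator group.
#' @param max_range replicate QC threshold passed through.
#' @return data frame per sample x target gene: `dct`, `ddct`, `fold`,
#'   with replicate QC flags carried along.
#' @export
delta_delta_ct <- function(ct_table, reference_genes = c("Rplp0", "Gapdh"),
                           control_group = "control", max_range = 0.5) {
  cc <- collapse_replicates(ct_table, max_range = max_range)
  if (!control_group %in% cc$group)
    stop_adq("no samples in control group '", control_group, "'")
  refs <- cc[cc$gene %in% reference_genes, ]
  ref_ct <- tapply(refs$ct_mean, refs$sample_id, mean)
  n_ref <- tapply(refs$gene, refs$sample_id, function(g) length(unique(g)))
  ok_samples <- names(n_ref)[n_ref == length(reference_genes)]
  dropped <- setdiff(unique(cc$sample_id), ok_samples)
  if (length(dropped))
    warning("excluding sample(s) missing a reference gene: ",
            paste(dropped, collapse = ", "))
  tg <- cc[!cc$gene %in% reference_genes & cc$sample_id %in% ok_samples, ]
  if (!nrow(tg)) stop_adq("no target-gene measurements left")
  tg$dct <- tg$ct_mean - as.numeric(ref_ct[as.character(tg$sample_id)])
  out <- lapply(split(tg, tg$gene), function(d) {
    ctrl <- d$dct[d$group == control_group]
    if (!length(ctrl)) stop_adq("no control samples for gene ", d$gene[1])
    d$ddct <- d$dct - mean(ctrl)
    d$fold <- 2^(-d$ddct)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$sample_id), ]
}

#' Western densitometry fold change versus the control group
#'
#' Band intensities are normalized to the loading control (HSP70) and
#' expressed relative to the mean normalized intensity of the control
#' group, per protein.
#'
#' @param band_table data frame with `sample_id`, `group`, `protein`,
#'   `intensity`, `loading_intensity`.
#' @param control_group label of the reference group.
#' @return the input with `normalized` and `fold` columns appended.
#' @export
densitometry_fold_change <- function(band_table, control_group = "control") {
  need <- c("sample_id", "group", "protein", "intensity", "loading_intensity")
  if (!all(need %in% names(band_table)))
    stop_adq("missing columns: ", paste(setdiff(need, names(band_table)), collapse = ", "))
  if (any(band_table$loading_intensity <= 0))
    stop_adq("loading-control intensities must be positive")
  if (any(band_table$intensity <= 0)) stop_adq("band intensities must be positive")
  band_table$normalized <- band_table$intensity / band_table$loading_intensity
  out <- lapply(split(band_table, band_table$protein), function(d) {
    base <- mean(d$normalized[d$group == control_group])
    if (!is.finite(base) || is.na(base))
      stop_adq("no control samples for protein ", d$protein[1])
    d$fold <- d$normalized / base
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
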