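# Follicle densitometry from per-section annotation tables.  Ovaries are
# serially sectioned at 5 um and one section in ten is stained, so
# consecutive stained sections are 50 um apart.  Follicles are typed
# upstream (primordial / primary / secondary-or-more / corpus luteum);
# this module turns annotation tables into pooled densities (n/mm^2)
# and raw, deduplicated corpora lutea counts.

FOLLICLE_TYPES <- c("primordial", "primary", "secondary_plus", "corpus_luteum")

check_sections <- function(sections) {
  need <- c("section_index", "surface_area_mm2")
  if (!all(need %in% names(sections)))
    stop_adq("missing columns: ", paste(setdiff(need, names(sections)), collapse = ", "))
  if (!"type" %in% names(sections)) sections$type <- NA_character_
  if (!"follicle_id" %in% names(sections)) sections$follicle_id <- NA_character_
  bad <- !is.na(sections$type) & !sections$type %in% FOLLICLE_TYPES
  if (any(bad)) stop_adq("unknown follicle type(s): ",
                         paste(unique(sections$type[bad]), collapse = ", "))
  sections
}

#' Per-type follicle density of one ovary
#'
#' Pooled estimator: total count of each type across sections divided by
#' the total sectioned surface area.  One row of the input per follicle
#' annotation; a section with no follicles is represented by a row with
#' `type = NA`.  Fewer than `min_sections` quantified sections flags the
#' result (still computed).
#'
#' @param sections data frame with `section_index`, `surface_area_mm2`,
#'   `follicle_id`, `type` (one area per section, repeated across its rows).
#' @param min_sections minimum sections expected per ovary (default 6).
#' @return data frame `type`, `count`, `density_per_mm2`, plus a
#'   `total` row; attributes `n_sections`, `total_area_mm2`, `qc_flag`.
#' @export
follicle_density <- function(sections, min_sections = 6) {
  sections <- check_sections(sections)
  per_sec <- unique(sections[, c("section_index", "surface_area_mm2")])
  if (anyDuplicated(per_sec$section_index))
    stop_adq("inconsistent surface areas within a section")
  if (any(per_sec$surface_area_mm2 <= 0)) stop_adq("surface areas must be > 0")
  area <- sum(per_sec$surface_area_mm2)
  if (area == 0) stop_adq("zero total surface area")
  n_sections <- nrow(per_sec)
  cnt <- vapply(FOLLICLE_TYPES, function(tp) sum(!is.na(sections$type) & sections$type == tp),
                integer(1))
  out <- data.frame(type = c(FOLLICLE_TYPES, "total"),
                    count = c(cnt, sum(cnt)),
                    density_per_mm2 = c(cnt, sum(cnt)) / area)
  attr(out, "n_sections") <- n_sections
  attr(out, "total_area_mm2") <- area
  attr(out, "qc_flag") <- if (n_sections < min_sections)
    sprintf("only %d sections quantified (expected >= %d)", n_sections, min_sections)
    else NA_character_
  if (n_sections < min_sections)
    warning("only ", n_sections, " sections quantified (expected >= ", min_sections, ")")
  out
}

#' Raw corpora lutea count over a fixed section span
#'
#' Counts distinct corpus luteum identities within a span of consecutive
#' stained sections (default 8, i.e. 400 um at 5 um thickness and 1-in-10
#' staining), so a corpus luteum visible on adjacent sections is counted
#' once.  Counts are raw: no volumetric (Abercrombie-type) correction is
#' applied.  Annotations without an id are each counted as distinct,
#' which reproduces plain unadjusted counting.
#'
#' @param sections annotation table as in [follicle_density()].
#' @param span_sections number of consecutive stained sections to use.
#' @return integer count; attribute `qc_flag` set when fewer sections
#'   than the span are available.
#' @export
corpora_lutea_count <- function(sections, span_sections = 8) {
  sections <- check_sections(sections)
  idx <- sort(unique(sections$section_index))
  lo <- min(idx)
  keep <- sections$section_index >= lo & sections$section_index < lo + span_sections
  cl <- sections[keep & !is.na(sections$type) & sections$type == "corpus_luteum", ]
  ids <- cl$follicle_id
  n <- length(unique(ids[!is.na(ids)])) + sum(is.na(ids))
  flag <- if (length(idx) < span_sections)
    sprintf("only %d sections available for a %d-section span", length(idx), span_sections)
    else NA_character_
  if (!is.na(flag)) warning(flag)
  structure(as.integer(n), qc_flag = flag)
}

#' Number of stained sections spanning a tissue depth
#'
#' With `thickness`-um sections and one in `sampling_interval` stained,
#' a tissue span of `span_um` covers
#' `floor(span_um / (thickness_um * sampling_interval))` stained
#' sections; 400 um at 5 um / 1-in-10 gives the canonical 8-section
#' corpora lutea span.
#'
#' @param span_um tissue depth in micrometres.
#' @param thickness_um section thickness in micrometres.
#' @param sampling_interval every n-th section stained.
#' @return integer number of stained sections.
#' @export
sections_for_span <- function(span_um, thickness_um, sampling_interval) {
  stopifnot(span_um > 0, thickness_um > 0, sampling_interval > 0)
  as.integer(floor(span_um / (thickness_um * sampling_interval)))
}
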