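# Depth-of-invasion (Bird) grading of adenomyosis.  The myometrial wall
# is the region between the endometrial-myometrial interface (inner
# boundary) and the serosal edge (outer boundary).  Each wall pixel gets
# a normalized depth d = d_in / (d_in + d_out) in [0, 1]; the deepest
# pixel of any ectopic focus dictates the grade: inner third -> I,
# inner two-thirds -> II, beyond -> III.

#' Uterine section geometry for invasion grading
#'
#' @param inner_boundary polygon of the endometrial-myometrial interface.
#' @param outer_boundary polygon of the serosal (outer) myometrial edge;
#'   must strictly contain the inner boundary.
#' @param foci list of polygons of ectopic endometrial foci (may be empty).
#' @param pixel_size optional micrometres per pixel (metadata only; the
#'   grade is scale-free).
#' @return object of class `uterus_section_geometry`.
#' @export
uterus_section_geometry <- function(inner_boundary, outer_boundary,
                                    foci = list(), pixel_size = NULL) {
  inner <- as_polygon(inner_boundary)
  outer <- as_polygon(outer_boundary)
  if (is.matrix(foci)) foci <- list(foci)
  foci <- lapply(foci, as_polygon)
  if (polygons_outlines_intersect(inner, outer))
    stop_adq("invalid geometry: inner and outer boundaries intersect")
  if (!all(point_in_polygon(inner[, 1], inner[, 2], outer)))
    stop_adq("invalid geometry: inner boundary must lie inside the outer boundary")
  structure(list(inner = inner, outer = outer, foci = foci,
                 pixel_size = pixel_size),
            class = "uterus_section_geometry")
}

#' Normalized depth field over the myometrial wall
#'
#' For every pixel p of the wall (inside the outer, outside the inner
#' boundary) computes d(p) = dist(p, inner) / (dist(p, inner) +
#' dist(p, outer)), which is 0 on the inner and 1 on the outer boundary.
#'
#' @param geometry a [uterus_section_geometry].
#' @return list with `depth` (numeric matrix, `NA` outside the wall),
#'   `myometrium` (logical matrix), and the raster dimensions.
#' @export
normalized_depth_field <- function(geometry) {
  stopifnot(inherits(geometry, "uterus_section_geometry"))
  xy <- rbind(geometry$inner, geometry$outer)
  if (any(xy < 0)) stop_adq("boundary coordinates must be non-negative")
  nc <- ceiling(max(xy[, 1])) + 2L
  nr <- ceiling(max(xy[, 2])) + 2L
  outer_m <- polygon_mask(geometry$outer, nr, nc)
  inner_m <- polygon_mask(geometry$inner, nr, nc)
  myo <- outer_m & !inner_m
  depth <- matrix(NA_real_, nr, nc)
  idx <- which(myo)
  if (length(idx)) {
    px <- (ceiling(idx / nr)) - 1    # column -> x
    py <- ((idx - 1) %% nr)          # row -> y
    din <- dist_to_polygon_boundary(px, py, geometry$inner)
    dout <- dist_to_polygon_boundary(px, py, geometry$outer)
    depth[idx] <- din / (din + dout)
  }
  list(depth = depth, myometrium = myo, nrow = nr, ncol = nc)
}

#' Assign a Bird grade to a uterine section
#'
#' The maximum normalized depth over all focus pixels inside the wall
#' sets the grade: 0 < d <= 1/3 -> I, 1/3 < d <= 2/3 -> II, d > 2/3 ->
#' III; no (in-wall) foci -> grade 0.  A focus entirely outside the wall
#' is ignored with a warning.
#'
#' @param geometry a [uterus_section_geometry].
#' @return list with `max_normalized_depth`, `grade` (factor with
#'   levels 0, I, II, III) and `invasion_present`.
#' @export
assign_grade <- function(geometry) {
  f <- normalized_depth_field(geometry)
  dmax <- -Inf
  any_focus <- FALSE
  for (i in seq_along(geometry$foci)) {
    fm <- polygon_mask(geometry$foci[[i]], f$nrow, f$ncol) & f$myometrium
    if (!any(fm)) {
      warning("focus ", i, " lies entirely outside the myometrium; ignored")
      next
    }
    any_focus <- TRUE
    dmax <- max(dmax, f$depth[fm], na.rm = TRUE)
  }
  if (!any_focus)
    return(list(max_normalized_depth = NA_real_,
                grade = factor("0", levels = GRADE_LEVELS),
                invasion_present = FALSE))
  g <- if (dmax <= 1 / 3) "I" else if (dmax <= 2 / 3) "II" else "III"
  list(max_normalized_depth = dmax,
       grade = factor(g, levels = GRADE_LEVELS),
       invasion_present = TRUE)
}

#' Cohort grade distribution
#'
#' Percentages of mice per grade (half-up, two decimals) plus the share
#' with any myometrial invasion (grade I or higher).
#'
#' @param grades vector of grades ("0", "I", "II", "III"), one per mouse.
#' @return data frame `grade`, `count`, `percent`; the invasion
#'   percentage is attached as attribute `invasion_percent`.
#' @export
cohort_grade_distribution <- function(grades) {
  g <- factor(as.character(grades), levels = GRADE_LEVELS)
  if (!length(g)) stop_adq("empty cohort")
  if (anyNA(g)) stop_adq("grades must be one of ", paste(GRADE_LEVELS, collapse = ", "))
  n <- length(g)
  cnt <- table(g)
  out <- data.frame(grade = GRADE_LEVELS,
                    count = as.integer(cnt),
                    percent = round_half_up(100 * as.integer(cnt) / n, 2))
  attr(out, "invasion_percent") <- round_half_up(100 * sum(g != "0") / n, 2)
  attr(out, "n") <- n
  out
}
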