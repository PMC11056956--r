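# Polygon primitives shared by the fluorescence-quantification and
# grading pipelines.  Conventions (fixed and relied upon throughout):
#   * coordinates are 0-based with origin at the top-left pixel centre,
#     x along columns, y along rows;
#   * a pixel belongs to a polygon iff its centre is inside under the
#     even-odd rule with a half-open boundary (top/left edges included),
#     so abutting polygons never double-claim a pixel;
#   * distances are Euclidean, in pixels.

as_polygon <- function(p) {
  m <- if (is.list(p) && !is.matrix(p)) do.call(rbind, p) else as.matrix(p)
  if (!is.numeric(m) || ncol(m) != 2 || nrow(m) < 3)
    stop_adq("a polygon needs a numeric n x 2 matrix with >= 3 vertices")
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Even-odd point-in-polygon test
#'
#' @param px,py point coordinates (0-based pixel convention).
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return logical vector; boundary handling is half-open (a point on a
#'   left/top edge is inside, on a right/bottom edge outside).
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- rep(FALSE, length(px))
  for (k in seq_along(x1)) {
    if (y1[k] == y2[k]) next
    sel <- (y1[k] <= py & py < y2[k]) | (y2[k] <= py & py < y1[k])
    if (!any(sel)) next
    xi <- x1[k] + (py[sel] - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
    inside[sel] <- xor(inside[sel], xi <= px[sel])
  }
  inside
}

#' Rasterize a polygon to a boolean mask
#'
#' @param poly n x 2 vertex matrix (0-based x, y).
#' @param nrow,ncol raster dimensions; pixel (i, j) has centre
#'   (x = j - 1, y = i - 1).
#' @return logical matrix.
#' @export
polygon_mask <- function(poly, nrow, ncol) {
  px <- rep(0:(ncol - 1), each = nrow)
  py <- rep(0:(nrow - 1), times = ncol)
  matrix(point_in_polygon(px, py, poly), nrow, ncol)
}

# union of a list of polygons (overlaps counted once)
polygons_mask <- function(polys, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  for (p in polys) m <- m | polygon_mask(p, nrow, ncol)
  m
}

#' Distance from points to a closed polygon boundary
#'
#' Exact Euclidean distance from each point to the nearest point on any
#' edge of the (closed) polygon outline.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return numeric vector of distances (pixels).
#' @export
dist_to_polygon_boundary <- function(px, py, poly) {
  poly <- as_polygon(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  d2 <- rep(Inf, length(px))
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1[k]) * dx + (py - y1[k]) * dy) / l2))
    qx <- x1[k] + t * dx; qy <- y1[k] + t * dy
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

# do two closed polygons' outlines intersect? (O(n*m) segment test)
polygons_outlines_intersect <- function(a, b) {
  a <- as_polygon(a); b <- as_polygon(b)
  seg <- function(p) cbind(p, rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]))
  sa <- seg(a); sb <- seg(b)
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(nrow(sa))) {
    d1 <- ccw(sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4], sb[, 1], sb[, 2])
    d2 <- ccw(sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4], sb[, 3], sb[, 4])
    d3 <- ccw(sb[, 1], sb[, 2], sb[, 3], sb[, 4], sa[i, 1], sa[i, 2])
    d4 <- ccw(sb[, 1], sb[, 2], sb[, 3], sb[, 4], sa[i, 3], sa[i, 4])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Regular polygon approximating a circle
#'
#' Convenience constructor for phantom ROIs and test geometries.
#'
#' @param cx,cy centre coordinates.
#' @param r radius.
#' @param n number of vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Read / write region-of-interest polygons as JSON
#'
#' The JSON dialect is `{"total_region": [[x, y], ...],
#' "luminal_epithelium": [[[x, y], ...], ...], "glands": [...]}` with
#' 0-based pixel coordinates; any other top-level names are kept as
#' generic named polygons (used for grading geometry).
#'
#' @param path file path.
#' @return named list of vertex matrices / lists of vertex matrices.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  fix <- function(x) {
    if (is.array(x) && length(dim(x)) == 3)       # list of equal-size polygons
      return(lapply(seq_len(dim(x)[1]), function(i) as_polygon(x[i, , ])))
    if (is.matrix(x)) return(as_polygon(x))
    lapply(x, as_polygon)
  }
  lapply(obj, fix)
}

#' @rdname read_roi_json
#' @param rois named list of polygons (matrices) or lists of polygons.
#' @export
write_roi_json <- function(rois, path) {
  strip <- function(x) {
    if (is.matrix(x)) unname(x) else lapply(x, strip)
  }
  jsonlite::write_json(lapply(rois, strip), path, digits = NA)
  invisible(path)
}
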