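# Compartment-wise quantification of nuclear PGR immunofluorescence.
# A section is imaged in three co-registered channels (red = PGR,
# green = alpha-SMA, blue = DAPI); manually drawn ROIs split the studied
# endometrial region into luminal epithelium, glands and stroma; red and
# blue are binarized independently by Otsu's method (one threshold per
# channel per image, computed over the studied region) and the readout
# per compartment is area(red) / area(blue).

#' Construct a three-channel fluorescence image
#'
#' @param red,green,blue integer matrices of identical dimensions with
#'   values in \[0, 255\] (red = PGR, green = alpha-SMA, blue = DAPI).
#' @param pixel_size optional pixel size in micrometres.
#' @return object of class `trichrome_image`.
#' @export
trichrome_image <- function(red, green, blue, pixel_size = NULL) {
  chans <- list(red = red, green = green, blue = blue)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop_adq("channel '", nm, "' must be a numeric matrix")
    if (any(ch < 0 | ch > 255) || any(ch != floor(ch)))
      stop_adq("channel '", nm, "' must hold integers in [0, 255]")
  }
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue)))
    stop_adq("all three channels must have identical dimensions")
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0))
    stop_adq("pixel_size must be a positive number")
  structure(list(red = matrix(as.integer(red), nrow(red)),
                 green = matrix(as.integer(green), nrow(green)),
                 blue = matrix(as.integer(blue), nrow(blue)),
                 pixel_size = pixel_size),
            class = "trichrome_image")
}

#' @export
dim.trichrome_image <- function(x) dim(x$red)

#' @export
print.trichrome_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<trichrome_image %d x %d px%s>\n", d[1], d[2],
              if (is.null(x$pixel_size)) "" else
                sprintf(", %.4g um/px", x$pixel_size)))
  invisible(x)
}

#' Read a three-channel image from TIFF or PNG
#'
#' @param path image file (.tif/.tiff or .png), 8-bit, 3 channels.
#' @param channel_order 3-letter permutation of "RGB" declaring what each
#'   stored plane is; plane i is assigned to the channel named by letter i.
#' @param pixel_size optional pixel size in micrometres, attached as-is.
#' @return a [trichrome_image].
#' @export
read_trichrome <- function(path, channel_order = "RGB", pixel_size = NULL) {
  if (!file.exists(path)) stop_adq("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = round(tiff::readTIFF(path) * 255),
    png = round(png::readPNG(path) * 255),
    stop_adq("unsupported image format: .", ext))
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    stop_adq("expected a 3-channel raster, got ",
             if (length(dim(arr)) == 2) "a single channel"
             else paste0(dim(arr)[3], " channel(s)"))
  ord <- strsplit(toupper(channel_order), "")[[1]]
  if (length(ord) != 3 || !setequal(ord, c("R", "G", "B")))
    stop_adq("channel_order must be a permutation of 'RGB'")
  plane <- function(letter) arr[, , which(ord == letter)]
  trichrome_image(plane("R"), plane("G"), plane("B"), pixel_size = pixel_size)
}

#' Write a three-channel image to TIFF or PNG
#'
#' @param image a [trichrome_image].
#' @param path output path; format chosen from the extension.
#' @param channel_order plane order to store (default "RGB").
#' @return `path`, invisibly.
#' @export
write_trichrome <- function(image, path, channel_order = "RGB") {
  stopifnot(inherits(image, "trichrome_image"))
  ord <- strsplit(toupper(channel_order), "")[[1]]
  chan <- list(R = image$red, G = image$green, B = image$blue)
  arr <- array(0, c(dim(image), 3))
  for (i in 1:3) arr[, , i] <- chan[[ord[i]]]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L),
    png = png::writePNG(arr / 255, path),
    stop_adq("unsupported image format: .", ext))
  invisible(path)
}

#' Otsu automatic threshold
#'
#' Picks the integer threshold in \[0, 255\] maximizing the between-class
#' variance of the 256-bin intensity histogram; pixels strictly greater
#' than the threshold are foreground.  Ties are broken toward the lowest
#' optimal threshold so the result is deterministic.
#'
#' @param channel integer matrix/vector with values in \[0, 255\].
#' @param within optional logical mask restricting the histogram.
#' @return integer threshold.
#' @export
otsu_threshold <- function(channel, within = NULL) {
  v <- if (is.null(within)) as.vector(channel) else channel[within]
  if (length(v) == 0) stop_adq("no pixels selected for thresholding")
  if (any(v < 0 | v > 255)) stop_adq("intensities must lie in [0, 255]")
  v <- as.integer(v)
  if (length(unique(v)) < 2)
    stop_adq("degenerate histogram: region has a single intensity value")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  csum <- cumsum(h)                 # pixels <= t at index t + 1
  cmu <- cumsum(h * (0:255))
  mu_t <- cmu[256]
  t <- 0:254
  w0 <- csum[t + 1]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, 255)
  m0 <- cmu[t + 1][valid] / w0[valid]
  m1 <- (mu_t - cmu[t + 1][valid]) / w1[valid]
  sb[valid] <- w0[valid] * w1[valid] * (m0 - m1)^2
  as.integer(t[which.max(sb)])      # which.max -> lowest maximizer
}

#' Compartment regions of interest
#'
#' Bundles the manually drawn polygons: the total studied region, the
#' luminal epithelium outline(s) and the gland outlines.  Epithelium and
#' gland polygons must lie within the total region (checked at
#' rasterization time).
#'
#' @param total_region vertex matrix of the studied region.
#' @param luminal_epithelium polygon or list of polygons (may be empty).
#' @param glands list of polygons (may be empty).
#' @return object of class `compartment_rois`.
#' @export
compartment_rois <- function(total_region, luminal_epithelium = list(),
                             glands = list()) {
  aslist <- function(x) {
    if (is.matrix(x)) list(as_polygon(x)) else lapply(x, as_polygon)
  }
  structure(list(total_region = as_polygon(total_region),
                 luminal_epithelium = if (length(luminal_epithelium)) aslist(luminal_epithelium) else list(),
                 glands = if (length(glands)) aslist(glands) else list()),
            class = "compartment_rois")
}

#' Decompose an image into epithelium, gland and stroma masks
#'
#' Rasterizes the ROIs into three pairwise-disjoint boolean masks whose
#' union is the studied region: epithelium = epithelium polygons; glands
#' = gland polygons minus epithelium; stroma = the remainder.
#'
#' @param image a [trichrome_image] (only its dimensions are used).
#' @param rois a [compartment_rois].
#' @return list of logical matrices `epithelium`, `glands`, `stroma`,
#'   `studied_region`.
#' @export
decompose_compartments <- function(image, rois) {
  stopifnot(inherits(rois, "compartment_rois"))
  d <- dim(image)
  nr <- d[1]; nc <- d[2]
  allv <- rbind(rois$total_region,
                do.call(rbind, c(rois$luminal_epithelium, rois$glands,
                                 list(matrix(numeric(0), 0, 2)))))
  if (any(allv[, 1] < 0 | allv[, 1] > nc - 1 | allv[, 2] < 0 | allv[, 2] > nr - 1))
    stop_adq("ROI polygon extends outside the image bounds")
  studied <- polygon_mask(rois$total_region, nr, nc)
  epi <- polygons_mask(rois$luminal_epithelium, nr, nc)
  gla <- polygons_mask(rois$glands, nr, nc)
  if (any(epi & !studied) || any(gla & !studied))
    stop_adq("epithelium/gland polygons must lie within the total region")
  gla <- gla & !epi
  stroma <- studied & !epi & !gla
  list(epithelium = epi, glands = gla, stroma = stroma,
       studied_region = studied)
}

#' Quantify PGR-positive area per compartment
#'
#' One Otsu threshold per channel (red, blue) is computed over the whole
#' studied region and applied to every compartment; per compartment the
#' red and blue foreground pixel areas and their ratio are reported.
#' The green (alpha-SMA) channel delineates the myometrium visually and
#' is deliberately not used in quantification.
#'
#' @param image a [trichrome_image].
#' @param masks compartment masks from [decompose_compartments()].
#' @return data frame with one row per compartment (plus the studied
#'   region total): `compartment`, `area_red`, `area_blue`, `ratio`
#'   (`NA` where `area_blue` is 0), `threshold_red`, `threshold_blue`.
#' @export
quantify_pgr <- function(image, masks) {
  stopifnot(inherits(image, "trichrome_image"))
  need <- c("epithelium", "glands", "stroma", "studied_region")
  if (!all(need %in% names(masks))) stop_adq("invalid compartment masks")
  if (!all(dim(masks$studied_region) == dim(image)))
    stop_adq("mask dimensions do not match the image")
  tr <- otsu_threshold(image$red, masks$studied_region)
  tb <- otsu_threshold(image$blue, masks$studied_region)
  comp <- c("epithelium", "glands", "stroma", "studied_region")
  res <- lapply(comp, function(cm) {
    m <- masks[[cm]]
    ar <- sum(image$red > tr & m)
    ab <- sum(image$blue > tb & m)
    data.frame(compartment = cm, area_red = ar, area_blue = ab,
               ratio = if (ab > 0) ar / ab else NA_real_)
  })
  out <- do.call(rbind, res)
  out$threshold_red <- tr
  out$threshold_blue <- tb
  out
}

#' Compare PGR ratios between two groups, per compartment
#'
#' Runs a two-sided Mann-Whitney test on the per-image red/blue ratios
#' of each compartment (exact when group sizes permit; see
#' [mann_whitney()]).
#'
#' @param quants list of [quantify_pgr()] results, one per image.
#' @param groups factor/character of group labels, one per image
#'   (exactly two levels).
#' @param compartments compartments to test.
#' @return data frame `compartment`, `U`, `p`, `method`.
#' @export
compare_groups_pgr <- function(quants, groups,
                               compartments = c("epithelium", "glands", "stroma")) {
  if (length(quants) != length(groups))
    stop_adq("one group label per quantified image is required")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop_adq("exactly two groups are required")
  df <- do.call(rbind, Map(function(q, g) cbind(q, group = g), quants, groups))
  out <- lapply(compartments, function(cm) {
    r <- df[df$compartment == cm, ]
    x <- r$ratio[r$group == lev[1]]
    y <- r$ratio[r$group == lev[2]]
    if (!length(x) || !length(y)) stop_adq("a group has no samples for ", cm)
    mw <- mann_whitney(x, y)
    data.frame(compartment = cm, U = mw$statistic, p = mw$p, method = mw$method)
  })
  do.call(rbind, out)
}
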