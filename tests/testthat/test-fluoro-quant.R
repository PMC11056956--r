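phantom_30 <- function(seed = 11, noise = 0) {
  simulate_trichrome_image(image_sim_params(
    n_nuclei = c(epithelium = 20, glands = 20, stroma = 60),
    pgr_positive_fraction = c(epithelium = 0.3, glands = 0.3, stroma = 0.3),
    noise = noise, seed = seed))
}

test_that("otsu threshold handles the two-level image with the lowest-tie rule", {
  v <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  t0 <- otsu_threshold(v)
  expect_identical(t0, 0L)
  expect_equal(sum(v > t0), 50)                # foreground = the 255s
})

test_that("otsu equals the exhaustive within-class-variance search", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      v <- random_bimodal_sample(300)
      if (length(unique(v)) < 2) next
      expect_identical(otsu_threshold(v), oracle_otsu(v))
    }
  })
})

test_that("constant regions give a degenerate-histogram error", {
  expect_error(otsu_threshold(matrix(7L, 5, 5)), "degenerate")
  expect_error(otsu_threshold(matrix(0:24, 5, 5), within = matrix(FALSE, 5, 5)),
               "no pixels")
})

test_that("trichrome images round-trip through TIFF and PNG bit-exactly", {
  sim <- phantom_30(noise = 0.04)
  for (ext in c(".tif", ".png")) {
    f <- withr::local_tempfile(fileext = ext)
    write_trichrome(sim$image, f)
    back <- read_trichrome(f)
    expect_identical(back$red, sim$image$red)
    expect_identical(back$blue, sim$image$blue)
  }
})

test_that("channel order remaps planes and wrong channel counts error", {
  sim <- phantom_30()
  f <- withr::local_tempfile(fileext = ".tif")
  write_trichrome(sim$image, f)
  bgr <- read_trichrome(f, channel_order = "BGR")
  expect_identical(bgr$red, sim$image$blue)    # planes swapped on read
  expect_identical(bgr$blue, sim$image$red)
  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 8, 8), g)          # grayscale file
  expect_error(read_trichrome(g), "channel")
})

test_that("compartment decomposition is disjoint and covers the studied region", {
  sim <- phantom_30()
  m <- decompose_compartments(sim$image, sim$rois)
  expect_false(any(m$epithelium & m$glands))
  expect_false(any(m$epithelium & m$stroma))
  expect_false(any(m$glands & m$stroma))
  expect_identical(m$epithelium | m$glands | m$stroma, m$studied_region)
})

test_that("empty epithelium/gland ROIs make stroma the whole studied region", {
  sim <- phantom_30()
  rois <- compartment_rois(sim$rois$total_region)
  m <- decompose_compartments(sim$image, rois)
  expect_identical(m$stroma, m$studied_region)
  expect_equal(sum(m$epithelium), 0)
})

test_that("out-of-bounds and out-of-region polygons are rejected", {
  sim <- phantom_30()
  big <- rbind(c(-5, 0), c(50, 0), c(50, 50), c(-5, 50))
  expect_error(decompose_compartments(sim$image, compartment_rois(big)),
               "outside the image")
  outside <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))  # outside total
  expect_error(
    decompose_compartments(sim$image,
      compartment_rois(sim$rois$total_region, glands = list(outside))),
    "within the total region")
})

test_that("phantom ratios equal the programmed PGR-positive fractions exactly", {
  sim <- phantom_30()
  q <- quantify_pgr(sim$image, sim$masks)
  expect_equal(q$ratio[q$compartment %in% c("epithelium", "glands", "stroma")],
               rep(0.3, 3))
  full <- simulate_trichrome_image(image_sim_params(
    pgr_positive_fraction = c(epithelium = 1, glands = 1, stroma = 1), seed = 2))
  qf <- quantify_pgr(full$image, full$masks)
  expect_equal(qf$ratio, rep(1, 4))            # red mask == blue mask
  expect_identical(full$image$red > 0, full$image$blue > 0)
})

test_that("compartment areas conserve: parts sum to the studied region", {
  sim <- phantom_30(noise = 0.05, seed = 3)
  q <- quantify_pgr(sim$image, sim$masks)
  parts <- q$compartment != "studied_region"
  expect_equal(sum(q$area_red[parts]), q$area_red[!parts])
  expect_equal(sum(q$area_blue[parts]), q$area_blue[!parts])
})

test_that("quantification is invariant under 90-degree rotation", {
  # ROIs on half-integer coordinates: no pixel centre lies on a polygon
  # edge, so the rasterized masks rotate exactly with the image
  sim <- phantom_30()
  half <- function(p) p + 0.5
  rois1 <- compartment_rois(half(sim$rois$total_region),
                            lapply(sim$rois$luminal_epithelium, half),
                            lapply(sim$rois$glands, half))
  rot_mat <- function(m) t(m[nrow(m):1, ])     # 90 deg clockwise
  nr <- nrow(sim$image$red)
  rot_poly <- function(p) cbind(nr - 1 - p[, 2], p[, 1])
  img2 <- trichrome_image(rot_mat(sim$image$red), rot_mat(sim$image$green),
                          rot_mat(sim$image$blue))
  rois2 <- compartment_rois(rot_poly(half(sim$rois$total_region)),
                            lapply(sim$rois$luminal_epithelium,
                                   function(p) rot_poly(half(p))),
                            lapply(sim$rois$glands,
                                   function(p) rot_poly(half(p))))
  q1 <- quantify_pgr(sim$image, decompose_compartments(sim$image, rois1))
  q2 <- quantify_pgr(img2, decompose_compartments(img2, rois2))
  expect_equal(q2, q1)
})

test_that("ratios are invariant under monotone contrast rescaling", {
  sim <- phantom_30()
  rescale <- function(m) matrix(as.integer(round(m * 0.8) + 20), nrow(m))
  img2 <- trichrome_image(rescale(sim$image$red), sim$image$green,
                          rescale(sim$image$blue))
  q1 <- quantify_pgr(sim$image, sim$masks)
  q2 <- quantify_pgr(img2, sim$masks)
  expect_equal(q2$ratio, q1$ratio)
})

test_that("empty compartments report zero areas and an undefined ratio", {
  sim <- simulate_trichrome_image(image_sim_params(
    n_nuclei = c(epithelium = 0, glands = 10, stroma = 30),
    pgr_positive_fraction = c(epithelium = 0, glands = 0.5, stroma = 0.5),
    seed = 5))
  q <- quantify_pgr(sim$image, sim$masks)
  e <- q[q$compartment == "epithelium", ]
  expect_equal(e$area_blue, 0)
  expect_true(is.na(e$ratio))
})

test_that("group comparison of ratios is symmetric and null on identical groups", {
  qs <- lapply(1:6, function(s) {
    p <- phantom_30(seed = s)
    quantify_pgr(p$image, p$masks)
  })
  same <- compare_groups_pgr(qs, rep(c("a", "b"), each = 3)[c(1, 4, 2, 5, 3, 6)])
  ident <- compare_groups_pgr(qs[c(1, 2, 3, 1, 2, 3)],
                              rep(c("a", "b"), each = 3))
  expect_true(all(ident$p == 1))
  swapped <- compare_groups_pgr(qs, rep(c("b", "a"), each = 3)[c(1, 4, 2, 5, 3, 6)])
  expect_equal(swapped$p, same$p)
  expect_error(compare_groups_pgr(qs, rep("a", 6)), "two groups")
})
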