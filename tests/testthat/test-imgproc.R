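make_disk_image <- function(centers_px, r_px = 5, size = 128, fg = 100,
                            bg = 10) {
  img <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers_px))) {
    d2 <- outer((seq_len(size) - centers_px[k, 1])^2,
                (seq_len(size) - centers_px[k, 2])^2, "+")
    img[d2 <= r_px^2] <- fg
  }
  img
}

test_that("flatfield correction with a provided field is exact", {
  img <- matrix(runif(64 * 64, 10, 20), 64, 64)
  expect_equal(flatfield_correct(img, "provided_field",
                                 field = matrix(1, 64, 64)), img)
  # scaled uniform field only renormalizes to mean 1 -> identity
  expect_equal(flatfield_correct(img, "provided_field",
                                 field = matrix(3, 64, 64)), img)
  expect_error(flatfield_correct(img, "provided_field",
                                 field = matrix(1, 32, 32)), "shape")
  bad <- matrix(1, 64, 64); bad[1, 1] <- 0
  expect_error(flatfield_correct(img, "provided_field", field = bad),
               "positive")
})

test_that("background-estimated flatfield flattens the generator bias", {
  cfg <- sim_config(rng_seed = 21, n_cells = 8, n_frames = 1, snr = Inf,
                    illumination_bias_amplitude = 0.3,
                    field_size_px = c(256L, 256L))
  sim <- simulate_timelapse(cfg, "untreated")
  img <- get_frame(sim$stack, "h2b", 1)
  corr <- flatfield_correct(img, "from_background")
  truebg <- bias_field(cfg) * cfg$background
  bgpx <- abs(img - truebg) < 1e-6      # pixels untouched by any cell
  cv <- sd(corr[bgpx]) / mean(corr[bgpx])
  expect_lt(cv, 0.02)
})

test_that("fixed-cell segmentation finds non-overlapping disks exactly", {
  set.seed(31)
  centers <- expand.grid(r = seq(15, 240, by = 32),
                         c = seq(15, 240, by = 32))
  centers <- as.matrix(centers[sample.int(nrow(centers), 50), ])
  img <- make_disk_image(centers, r_px = 5, size = 256)
  m <- segment_fixed(img, pixel_size_um = 1.5)
  expect_identical(nrow(m$props), 50L)
  d <- sqrt(outer(m$props$y_um / 1.5 + 0.5, centers[, 1], "-")^2 +
            outer(m$props$x_um / 1.5 + 0.5, centers[, 2], "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)   # centroids within 1 px of truth
})

test_that("blank images yield empty masks, not errors", {
  blank <- matrix(10, 64, 64)
  expect_identical(nrow(segment_fixed(blank, 1.3)$props), 0L)
  expect_identical(nrow(segment_live(blank, 1.3)$props), 0L)
})

test_that("fused nuclei above the area cap are split by watershed", {
  # two disks fused into a single component ~1.8x the area cap
  img <- make_disk_image(rbind(c(32, 28), c(32, 40)), r_px = 8, size = 64)
  area_one <- pi * 8^2 * 1.5^2            # um^2 of one disk at 1.5 um/px
  m <- segment_fixed(img, pixel_size_um = 1.5, min_area_um2 = 30,
                     max_area_um2 = area_one * 1.1)
  expect_identical(nrow(m$props), 2L)
})

test_that("live segmentation handles a single blob and merges close seeds", {
  img <- make_disk_image(rbind(c(64, 64)), r_px = 8 / 1.3, size = 128)
  m <- segment_live(img, 1.3, radius_range_um = c(5, 12))
  expect_identical(nrow(m$props), 1L)
  expect_equal(m$props$x_um, 64 * 1.3 - 0.65, tolerance = 1.3)
  expect_equal(m$props$y_um, 64 * 1.3 - 0.65, tolerance = 1.3)
  expect_error(segment_live(img, 1.3, radius_range_um = c(12, 5)),
               "radius_range")
})

test_that("live detection is invariant to positive rescaling", {
  cfg <- sim_config(rng_seed = 41, n_cells = 10, n_frames = 1, snr = 15)
  sim <- simulate_timelapse(cfg, "untreated")
  img <- get_frame(sim$stack, "h2b", 1)
  m1 <- segment_live(img, cfg$pixel_size_um)
  m2 <- segment_live(img * 37.5, cfg$pixel_size_um)
  expect_identical(m1$labels, m2$labels)
})

test_that("segmentation is equivariant to whole-pixel translation", {
  cfg <- sim_config(rng_seed = 51, n_cells = 6, n_frames = 1, snr = Inf,
                    field_size_px = c(256L, 256L))
  sim <- simulate_timelapse(cfg, "untreated")
  img <- get_frame(sim$stack, "h2b", 1)
  sh <- 7
  img_sh <- img[c((sh + 1):256, 1:sh), ]   # circular row shift
  m1 <- segment_live(img, cfg$pixel_size_um)
  m2 <- segment_live(img_sh, cfg$pixel_size_um)
  lab_back <- m2$labels[c((256 - sh + 1):256, 1:(256 - sh)), ]
  # same geometry: identical sets of foreground pixels per object
  expect_identical(lab_back > 0, m1$labels > 0)
  expect_identical(nrow(m1$props), nrow(m2$props))
})

test_that("label areas agree between mask image and property table", {
  cfg <- sim_config(rng_seed = 61, n_cells = 8, n_frames = 1, snr = 10)
  sim <- simulate_timelapse(cfg, "untreated")
  m <- segment_live(get_frame(sim$stack, "h2b", 1), cfg$pixel_size_um)
  for (i in seq_len(nrow(m$props))) {
    expect_identical(sum(m$labels == m$props$label[i]), m$props$area_px[i])
  }
  expect_equal(m$props$area_um2, m$props$area_px * cfg$pixel_size_um^2)
})

test_that("low SNR: precision collapses at threshold ~0, calibrated threshold recovers", {
  cfg <- sim_config(rng_seed = 13, n_cells = 25, n_frames = 1,
                    field_size_px = c(420L, 420L), snr = 2)
  sim <- simulate_timelapse(cfg, "untreated")
  img <- get_frame(sim$stack, "h2b", 1)
  loose <- segmentation_metrics(
    list(segment_live(img, cfg$pixel_size_um, detection_threshold = 0.5)),
    sim$truth)
  calib <- segmentation_metrics(
    list(segment_live(img, cfg$pixel_size_um, detection_threshold = 5)),
    sim$truth)
  expect_lt(loose$precision, 0.5)
  expect_gte(calib$recall, 0.9)
  expect_gt(calib$precision, loose$precision)
})

test_that("live segmentation recovers a dense field at high SNR", {
  cfg <- sim_config(rng_seed = 71, n_cells = 30, n_frames = 1,
                    field_size_px = c(420L, 420L), snr = 10)
  sim <- simulate_timelapse(cfg, "untreated")
  m <- segment_live(get_frame(sim$stack, "h2b", 1), cfg$pixel_size_um)
  met <- segmentation_metrics(list(m), sim$truth)
  expect_gte(met$recall, 0.98)
  expect_gte(met$precision, 0.98)
})
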