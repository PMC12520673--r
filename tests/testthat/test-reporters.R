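single_disk_mask <- function(size = 64, center = c(32, 32), r_px = 6,
                             pixel_size_um = 1.5) {
  labels <- matrix(0L, size, size)
  d2 <- outer((seq_len(size) - center[1])^2,
              (seq_len(size) - center[2])^2, "+")
  labels[d2 <= r_px^2] <- 1L
  label_mask(labels, pixel_size_um)
}

test_that("cn_ratio reproduces forced median ratios", {
  m <- single_disk_mask()
  img <- matrix(200, 64, 64)           # cytoplasm/background level
  img[m$labels == 1L] <- 100           # nucleus level
  r <- cn_ratio(img, m)
  expect_true(r$valid)
  expect_equal(r$ratio, 2.0)
  # constant sensor image -> ratio 1 for every cell
  r1 <- cn_ratio(matrix(7, 64, 64), m)
  expect_equal(r1$ratio, 1.0)
})

test_that("cn_ratio is invariant to positive rescaling of the sensor", {
  set.seed(5)
  fx <- random_disk_labels(3, size = 64)
  m <- label_mask(fx$labels, fx$pixel_size_um)
  img <- matrix(runif(64 * 64, 50, 150), 64, 64)
  r1 <- cn_ratio(img, m)
  r2 <- cn_ratio(img * 13.7, m)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("cn_ratio matches the per-pixel brute-force oracle", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(2:5, 1)
    # occasionally force close pairs so rings overlap and contest pixels
    fx <- random_disk_labels(n, size = 64, r_px = 5,
                             min_sep_px = sample(c(12, 14, 18), 1))
    m <- label_mask(fx$labels, fx$pixel_size_um)
    img <- matrix(runif(64 * 64, 20, 220), 64, 64)
    got <- cn_ratio(img, m, min_ring_px = 10)
    want <- oracle_cn_ratio(img, fx$labels, fx$pixel_size_um,
                            min_ring_px = 10)
    expect_equal(got$valid, want$valid)
    expect_equal(got$ratio, want$ratio)
  }
})

test_that("invalid rings are flagged, not errors", {
  # two nuclei so close that one ring is fully contested
  labels <- matrix(0L, 48, 48)
  d2a <- outer((1:48 - 24)^2, (1:48 - 20)^2, "+")
  d2b <- outer((1:48 - 24)^2, (1:48 - 28)^2, "+")
  labels[d2a <= 16] <- 1L
  labels[d2b <= 16 & labels == 0L] <- 2L
  m <- label_mask(labels, 3)   # coarse pixels: ring almost all contested
  r <- cn_ratio(matrix(50, 48, 48), m, min_ring_px = 1e6)
  expect_false(any(r$valid))
  expect_true(all(is.na(r$ratio)))
})

test_that("nuclear intensity is the (eroded-mask) median", {
  m <- single_disk_mask()
  expect_equal(nuclear_intensity(matrix(42, 64, 64), m)$nuclear_median, 42)
  empty <- label_mask(matrix(0L, 16, 16), 1)
  expect_identical(nrow(nuclear_intensity(matrix(1, 16, 16), empty)), 0L)
})

test_that("build_traces aligns, interpolates bridged gaps and flags them", {
  det <- do.call(rbind, lapply(setdiff(1:11, 6), function(f)
    data.frame(frame = f, label = 1L, x_um = 50, y_um = 50,
               intensity = 100)))
  tracks <- link_frames(det, frame_interval_h = 0.2, max_gap_frames = 2)
  readouts <- data.frame(frame = setdiff(1:11, 6), label = 1L,
                         cdk46 = 0.5, cdk2 = seq(1, 2, length.out = 10),
                         degron = 20, valid = TRUE)
  traces <- build_traces(tracks, readouts, min_duration_h = 0)
  expect_identical(nrow(traces), 11L)
  gap <- traces[traces$frame == 6, ]
  expect_true(gap$interpolated)
  expect_true(gap$valid)
  # linear midpoint between the neighbouring frames
  v5 <- readouts$cdk2[readouts$frame == 5]
  v7 <- readouts$cdk2[readouts$frame == 7]
  expect_equal(gap$cdk2, (v5 + v7) / 2)
  expect_identical(sum(traces$interpolated), 1L)
})

test_that("treatment time shifts the trace clock and is validated", {
  det <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, label = 1L, x_um = 10, y_um = 10,
               intensity = 1)))
  tracks <- link_frames(det, frame_interval_h = 0.5)
  readouts <- data.frame(frame = 1:5, label = 1L, cdk46 = 1, cdk2 = 1,
                         degron = 1, valid = TRUE)
  tr <- build_traces(tracks, readouts, treatment_time_h = 1,
                     frame_interval_h = 0.5, min_duration_h = 0)
  expect_equal(tr$t_h, seq(0, 2, by = 0.5) - 1)
  expect_error(build_traces(tracks, readouts, treatment_time_h = 10,
                            frame_interval_h = 0.5), "span")
})

test_that("short traces are excluded from the persister-eligible set", {
  det <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, label = 1L, x_um = 10, y_um = 10,
               intensity = 1)))
  tracks <- link_frames(det, frame_interval_h = 0.2)
  readouts <- data.frame(frame = 1:5, label = 1L, cdk46 = 1, cdk2 = 1,
                         degron = 1, valid = TRUE)
  expect_warning(tr <- build_traces(tracks, readouts, min_duration_h = 18),
                 "min_duration")
  expect_identical(length(attr(tr, "eligible_tracks")), 0L)
})

test_that("Cdt1 degradation marks G1/S and S/G2 at constructed times", {
  t <- seq(0, 20, by = 0.2)
  cdt1 <- ifelse(t < 8, 80, ifelse(t < 14, 15, 70))
  res <- call_phase_transitions(t, cdt1, "cdt1")
  expect_equal(res$transitions$t_h[res$transitions$event == "G1/S"], 8,
               tolerance = 0.21)
  expect_equal(res$transitions$t_h[res$transitions$event == "S/G2"], 14,
               tolerance = 0.21)
  expect_identical(res$phases$phase, c("G1", "S", "G2M"))
})

test_that("geminin accumulation marks S entry at the ramp start", {
  t <- seq(0, 24, by = 0.2)
  gem <- ifelse(t < 10, 15, 15 + 9 * (t - 10))
  res <- call_phase_transitions(t, gem, "geminin")
  expect_equal(res$transitions$t_h, 10, tolerance = 0.21)
})

test_that("flat or noise-only traces yield no transitions", {
  t <- seq(0, 20, by = 0.2)
  expect_identical(nrow(call_phase_transitions(t, rep(50, length(t)),
                                               "cdt1")$transitions), 0L)
  set.seed(2)
  noise <- 50 + rnorm(length(t), 0, 0.5)
  expect_identical(nrow(call_phase_transitions(t, noise,
                                               "cdt1")$transitions), 0L)
  expect_identical(nrow(call_phase_transitions(t, rep(15, length(t)),
                                               "geminin")$transitions), 0L)
})
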