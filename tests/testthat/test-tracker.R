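# Detection tables are the natural fixture currency for the tracker.
det_df <- function(frame, x, y, intensity = NA_real_) {
  data.frame(frame = frame, label = seq_along(x), x_um = x, y_um = y,
             intensity = intensity)
}

test_that("stationary cells yield one full-length track each", {
  det <- do.call(rbind, lapply(1:10, function(f)
    det_df(f, x = c(10, 50, 90), y = c(20, 60, 30))))
  tr <- link_frames(det, frame_interval_h = 0.2)
  expect_identical(length(unique(tr$track_id)), 3L)
  lens <- table(tr$track_id)
  expect_true(all(lens == 10))
  # identity preserved: every track stays at a constant position
  for (id in unique(tr$track_id)) {
    expect_identical(length(unique(tr$x_um[tr$track_id == id])), 1L)
  }
})

test_that("a one-frame dropout is bridged into a single track", {
  det <- do.call(rbind, lapply(setdiff(1:9, 5), function(f)
    det_df(f, x = 50 + f, y = 40)))
  tr <- link_frames(det, frame_interval_h = 0.2, max_gap_frames = 2)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(sort(tr$frame), setdiff(1:9, 5L))
  # with gap closing disabled the track splits
  tr0 <- link_frames(det, frame_interval_h = 0.2, max_gap_frames = 0)
  expect_identical(length(unique(tr0$track_id)), 2L)
})

test_that("crossing cells with modest steps keep their identities", {
  # two cells swap x positions over 21 frames, passing 20 um apart in y
  fr <- 1:21
  detA <- data.frame(frame = fr, label = 1L, x_um = 10 + 4 * (fr - 1),
                     y_um = 50, intensity = NA_real_)
  detB <- data.frame(frame = fr, label = 2L, x_um = 90 - 4 * (fr - 1),
                     y_um = 70, intensity = NA_real_)
  tr <- link_frames(rbind(detA, detB), frame_interval_h = 0.2)
  expect_identical(length(unique(tr$track_id)), 2L)
  for (id in unique(tr$track_id)) {
    expect_identical(length(unique(tr$y_um[tr$track_id == id])), 1L)
  }
})

test_that("global assignment repairs deflection by a newborn detection", {
  # a continuing cell moves slightly; a newborn appears nearer to the old
  # position than the true continuation -> greedy would deflect, the
  # global optimum must not because total cost is minimized
  det1 <- det_df(1, x = c(50), y = c(50))
  det2 <- det_df(2, x = c(53, 49), y = c(50, 53))
  tr <- link_frames(rbind(det1, det2), frame_interval_h = 0.2,
                    max_step_um = 40)
  t1 <- tr$track_id[tr$frame == 1]
  cont <- tr[tr$frame == 2 & tr$track_id == t1, ]
  expect_identical(nrow(cont), 1L)
})

test_that("mitosis rule assigns daughters by combined intensity", {
  base <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, label = 1L, x_um = 50, y_um = 50,
               intensity = 100)))
  d1 <- data.frame(frame = 6:8, label = 2L, x_um = 45, y_um = 50,
                   intensity = 48)
  d2 <- data.frame(frame = 6:8, label = 3L, x_um = 55, y_um = 50,
                   intensity = 49)
  tr <- link_frames(rbind(base, d1, d2), frame_interval_h = 0.2,
                    max_step_um = 20)
  ann <- detect_mitosis(tr, max_pair_distance_um = 25,
                        intensity_tolerance = 0.3)
  div <- attr(ann, "divisions")
  expect_identical(nrow(div), 1L)
  expect_identical(div$frame, 5L)
  kids <- unique(ann$track_id[ann$parent_id == div$parent_id])
  expect_identical(length(kids), 2L)
  # |(48 + 49) - 100| / 100 = 0.03 <= 0.3
})

test_that("dim daughter pair fails the intensity-comparability test", {
  base <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, label = 1L, x_um = 50, y_um = 50,
               intensity = 100)))
  d1 <- data.frame(frame = 6:8, label = 2L, x_um = 45, y_um = 50,
                   intensity = 20)
  d2 <- data.frame(frame = 6:8, label = 3L, x_um = 55, y_um = 50,
                   intensity = 20)
  tr <- link_frames(rbind(base, d1, d2), frame_interval_h = 0.2,
                    max_step_um = 20)
  ann <- detect_mitosis(tr, intensity_tolerance = 0.3)
  expect_identical(nrow(attr(ann, "divisions")), 0L)
  # |(20 + 20) - 100| / 100 = 0.6 > 0.3
})

test_that("movies without newborn tracks have no divisions", {
  det <- do.call(rbind, lapply(1:6, function(f)
    det_df(f, x = c(20, 80), y = c(20, 80), intensity = c(100, 100))))
  tr <- link_frames(det, frame_interval_h = 0.2)
  ann <- detect_mitosis(tr)
  expect_identical(nrow(attr(ann, "divisions")), 0L)
})

test_that("each detection belongs to exactly one track record", {
  cfg <- sim_config(rng_seed = 81, n_cells = 15, n_frames = 20, snr = 15,
                    field_size_px = c(420L, 420L),
                    division_rate_per_h = 1 / 18)
  sim <- simulate_timelapse(cfg, "untreated")
  res <- suppressWarnings(analyze_timelapse(sim$stack))  # movie < 18 h
  rec <- as.data.frame(res$tracks)
  expect_false(any(duplicated(rec[, c("frame", "label")])))
  expect_false(any(duplicated(rec[, c("frame", "track_id")])))
})

test_that("time reversal preserves the lineage partition (no divisions)", {
  cfg <- sim_config(rng_seed = 91, n_cells = 10, n_frames = 15, snr = Inf,
                    division_rate_per_h = 0)
  sim <- simulate_timelapse(cfg, "cdk46i")
  masks <- lapply(seq_len(cfg$n_frames), function(f)
    segment_live(get_frame(sim$stack, "h2b", f), cfg$pixel_size_um))
  fwd <- link_frames(masks, 0.2)
  bwd <- link_frames(rev(masks), 0.2)
  part <- function(tr, flip = FALSE) {
    fr <- if (flip) max(tr$frame) + 1L - tr$frame else tr$frame
    keys <- paste(fr, round(tr$x_um, 3), round(tr$y_um, 3))
    unname(lapply(split(keys, tr$track_id), sort))
  }
  a <- part(fwd); b <- part(bwd, flip = TRUE)
  expect_setequal(vapply(a, paste, "", collapse = "|"),
                  vapply(b, paste, "", collapse = "|"))
})

test_that("empty input yields an empty track set", {
  tr <- link_frames(list(), frame_interval_h = 0.2)
  expect_identical(nrow(tr), 0L)
})
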