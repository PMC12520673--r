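test_that("simulated timelapse is a pure function of its configuration", {
  cfg <- sim_config(rng_seed = 11, n_cells = 5, n_frames = 3,
                    field_size_px = c(160L, 160L), snr = 10)
  a <- simulate_timelapse(cfg, "cdk46i")
  b <- simulate_timelapse(cfg, "cdk46i")
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$frames, b$truth$frames)
  cfg2 <- sim_config(rng_seed = 12, n_cells = 5, n_frames = 3,
                     field_size_px = c(160L, 160L), snr = 10)
  c <- simulate_timelapse(cfg2, "cdk46i")
  expect_false(identical(a$stack$channels, c$stack$channels))
})

test_that("persister fates honour the configured fraction exactly", {
  cfg <- sim_config(rng_seed = 1, n_cells = 20, n_frames = 240)
  sim <- simulate_traces(cfg, "cdk46i")
  expect_identical(sum(sim$truth$cells$is_persister), 10L)
  # combination scenario suppresses re-activation
  cfg$combo_factor <- 0.25
  sim2 <- simulate_traces(cfg, "cdk46i_plus_cdk7i")
  expect_identical(sum(sim2$truth$cells$is_persister),
                   as.integer(round(20 * 0.5 * 0.25)))
  # untreated cells cycle: no arrest plateau labels
  sim3 <- simulate_traces(sim_config(rng_seed = 2, n_cells = 10,
                                     n_frames = 60), "untreated")
  expect_true(all(c("G1", "S") %in% sim3$truth$frames$phase))
})

test_that("ground-truth persister labels equal the brute-force rule", {
  cfg <- sim_config(rng_seed = 42, n_cells = 30, n_frames = 240)
  sim <- simulate_traces(cfg, "cdk46i")
  for (id in sim$truth$cells$cell_id) {
    d <- sim$truth$frames[sim$truth$frames$cell_id == id, ]
    run <- oracle_persister_run(d$t_h, d$cdk2, dt = cfg$frame_interval_h)
    expect_equal(sim$truth$cells$longest_run_h[
      sim$truth$cells$cell_id == id], run)
  }
})

test_that("illumination bias field has the configured corner fall-off", {
  cfg <- sim_config(illumination_bias_amplitude = 0.3,
                    field_size_px = c(200L, 200L))
  b <- bias_field(cfg)
  expect_equal(max(b), 1, tolerance = 1e-4)
  expect_equal(b[1, 1] / max(b), 0.7, tolerance = 1e-4)
  # rendered noiseless background reproduces the fall-off
  cfg2 <- sim_config(rng_seed = 3, n_cells = 1, n_frames = 1, snr = Inf,
                     illumination_bias_amplitude = 0.3,
                     field_size_px = c(200L, 200L))
  sim <- simulate_timelapse(cfg2, "cdk46i")
  img <- get_frame(sim$stack, "h2b", 1)
  corner <- mean(img[1:3, 1:3])
  center_bg <- img[99:102, 99:102]
  center_bg <- center_bg[center_bg < 50]   # drop the (single) bright cell
  expect_equal(corner / mean(center_bg), 0.7, tolerance = 0.02)
})

test_that("rendered sensor pixels carry the true C/N ratio (true masks)", {
  cfg <- sim_config(rng_seed = 5, n_cells = 6, n_frames = 2,
                    field_size_px = c(220L, 220L), snr = Inf,
                    motion_sigma_um_per_frame = 0)
  sim <- simulate_timelapse(cfg, "cdk46i")
  px <- cfg$pixel_size_um
  r_px <- cfg$nucleus_radius_um / px
  for (f in 1:2) {
    tf <- sim$truth$frames[sim$truth$frames$frame == f, ]
    labels <- matrix(0L, 220, 220)
    for (i in seq_len(nrow(tf))) {
      d2 <- outer((seq_len(220) - (tf$y_um[i] / px + 0.5))^2,
                  (seq_len(220) - (tf$x_um[i] / px + 0.5))^2, "+")
      labels[d2 <= r_px^2] <- i
    }
    m <- label_mask(labels, px)
    for (ch in c("cdk46", "cdk2")) {
      r <- cn_ratio(get_frame(sim$stack, ch, f), m)
      expect_true(all(r$valid))
      expect_lt(max(abs(r$ratio - tf[[ch]])), 0.01 * max(tf[[ch]]))
    }
    dg <- nuclear_intensity(get_frame(sim$stack, "degron", f), m)
    expect_lt(max(abs(dg$nuclear_median - tf$degron) / tf$degron), 0.01)
  }
})

test_that("overcrowded placement raises a placement error", {
  cfg <- sim_config(n_cells = 500, field_size_px = c(64L, 64L),
                    n_frames = 1)
  expect_error(simulate_timelapse(cfg, "cdk46i"), "place")
})

test_that("dose matrix reduces to Bliss independence and Hill margins", {
  da <- c(0, 1, 10, 100); db <- c(0, 10, 100, 1000)
  dm <- simulate_dose_matrix(10, 1, 100, 1.5, interaction = 0,
                             doses_a = da, doses_b = db, noise_sd = 0)
  bs <- bliss_synergy(dm, n_boot = 0)
  expect_equal(max(abs(bs$excess)), 0)
  # zero-dose column reproduces the single-agent Hill curve of A
  marg <- dm[dm$dose_b == 0, ]
  expect_equal(marg$inhibition[order(marg$dose_a)],
               hill_inhibition(da, 10, 1))
  expect_error(simulate_dose_matrix(10, 1, 100, 1, doses_a = da,
                                    doses_b = db, noise_sd = -1), "noise_sd")
})

test_that("interaction term adds exactly the configured bump", {
  da <- c(0, 1, 10, 100); db <- c(0, 10, 100, 1000)
  dm <- simulate_dose_matrix(10, 1, 100, 1.5, interaction = 0.1,
                             doses_a = da, doses_b = db, noise_sd = 0)
  # hand evaluation of the documented bump on the grid
  grid <- expand.grid(a = da, b = db)
  g <- ifelse(grid$a <= 0 | grid$b <= 0, 0,
              exp(-((log(grid$a / 10))^2 + (log(grid$b / 100))^2) / 2))
  bs <- bliss_synergy(dm, n_boot = 0)
  interior <- grid$a > 0 & grid$b > 0
  expect_equal(bs$score, mean(0.1 * g[interior]) * 100, tolerance = 1e-9)
})

test_that("section generator places CD8 cells per the enrichment rule", {
  # uniform placement: periphery and core densities agree within sampling
  sec <- simulate_section(field_mm = c(3, 3), tumor_radius_mm = 1.5,
                          boundary_amplitude = 0, n_cd8 = 4000,
                          periphery_enrichment = 1, rng_seed = 8,
                          snr = Inf)
  d <- margin_distance(sec$mask, sec$image$pixel_size_um)
  a_per <- sum(d <= 500, na.rm = TRUE)
  a_core <- sum(d > 500, na.rm = TRUE)
  n_per <- sum(sec$truth$region == "periphery")
  n_core <- sum(sec$truth$region == "core")
  dens_ratio <- (n_per / a_per) / (n_core / a_core)
  expect_gt(dens_ratio, 0.85); expect_lt(dens_ratio, 1.15)
  # degenerate core weight: all cells in periphery
  sec2 <- simulate_section(field_mm = c(3, 3), tumor_radius_mm = 1.5,
                           boundary_amplitude = 0, n_cd8 = 200,
                           periphery_enrichment = Inf, rng_seed = 9)
  expect_identical(sum(sec2$truth$region == "core"), 0L)
  # circular tumor: core area fraction matches the offset-disk geometry
  frac <- a_core / (a_per + a_core)
  expect_equal(frac, (1.0 / 1.5)^2, tolerance = 0.02)
})
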