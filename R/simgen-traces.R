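#' Configuration for the synthetic live-cell generator
#'
#' Collects every knob of the synthetic time-lapse generator. Identical
#' configurations (including `rng_seed`) yield bit-identical outputs.
#'
#' Scenario semantics (passed to [simulate_timelapse()] /
#' [simulate_traces()]):
#' * `untreated` — cells cycle continuously: CDK4/6 and CDK2 activity ramp up
#'   through the cycle and reset at mitosis; divisions occur at
#'   `division_rate_per_h`.
#' * `cdk46i` — CDK4/6 activity is suppressed to a low plateau within ~12 h;
#'   all cells arrest (CDK2 settles near 0.5) but a fraction
#'   `persister_fraction` later re-activates CDK2 along a sigmoid that
#'   crosses the 1.0 activity line at a time drawn uniformly from
#'   `rise_window_h` (the persister phenotype).
#' * `cdk46i_plus_cdk7i` — as `cdk46i` with the re-activating fraction
#'   multiplied by `combo_factor` (the combination suppresses persister
#'   emergence).
#'
#' @param rng_seed Integer seed controlling all randomness.
#' @param field_size_px Image size `c(rows, cols)`.
#' @param pixel_size_um Pixel size, micrometres.
#' @param frame_interval_h Frame interval in hours (default 0.2 = 12 min).
#' @param n_frames Number of frames (default 240, i.e. 48 h).
#' @param n_cells Number of cells seeded at frame 1.
#' @param nucleus_radius_um Nuclear radius, micrometres.
#' @param cyto_width_um Width of the rendered cytoplasm annulus beyond the
#'   nuclear radius. The default 12 um covers the downstream 2-10 um
#'   quantification ring with a 2 um guard band so the rendered C/N ratio
#'   can equal the true activity.
#' @param motion_sigma_um_per_frame Per-frame random-walk step SD.
#' @param division_rate_per_h Divisions per cell per hour (untreated
#'   scenario); 0 disables division.
#' @param snr Signal-to-noise ratio at the nuclear H2B signal level;
#'   `Inf` disables shot and read noise.
#' @param illumination_bias_amplitude Amplitude of the multiplicative
#'   quadratic illumination fall-off: the corner-to-center ratio of the bias
#'   field is `1 - illumination_bias_amplitude`. Must lie in [0, 1).
#' @param persister_fraction Fraction of cells assigned the persister
#'   trajectory under `cdk46i`.
#' @param combo_factor Multiplier on `persister_fraction` under
#'   `cdk46i_plus_cdk7i`.
#' @param rise_window_h Range (h) from which each persister's CDK2 1.0
#'   crossing time is drawn.
#' @param rise_tau_h Time constant (h) of the sigmoidal CDK2 rise.
#' @param degron_type Degron reporter rendered in the fourth channel:
#'   `"geminin"` (accumulates in S/G2, cleared at mitosis) or `"cdt1"`
#'   (high in G1, degraded in S, re-accumulates in G2).
#' @param background Background intensity (a.u.).
#' @param nucleus_intensity Nuclear signal level (a.u.) for H2B and the
#'   sensor channels.
#' @param blur_sigma_px Gaussian PSF sigma in pixels.
#' @param min_separation_um Minimum center-to-center distance at initial
#'   placement; default keeps quantification rings of neighbouring cells
#'   from touching at seeding time.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L,
                       field_size_px = c(320L, 320L),
                       pixel_size_um = 1.3,
                       frame_interval_h = 0.2,
                       n_frames = 240L,
                       n_cells = 20L,
                       nucleus_radius_um = 8,
                       cyto_width_um = 12,
                       motion_sigma_um_per_frame = 0.8,
                       division_rate_per_h = 0.05,
                       snr = 20,
                       illumination_bias_amplitude = 0,
                       persister_fraction = 0.5,
                       combo_factor = 0.25,
                       rise_window_h = c(24, 36),
                       rise_tau_h = 1.5,
                       degron_type = c("geminin", "cdt1"),
                       background = 10,
                       nucleus_intensity = 100,
                       blur_sigma_px = 1,
                       min_separation_um = NULL) {
  degron_type <- match.arg(degron_type)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (frame_interval_h <= 0) stop("frame_interval_h must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  if (illumination_bias_amplitude < 0 || illumination_bias_amplitude >= 1)
    stop("illumination_bias_amplitude must lie in [0, 1)")
  if (division_rate_per_h < 0) stop("division_rate_per_h must be >= 0")
  field_um <- field_size_px * pixel_size_um
  if (2 * nucleus_radius_um >= min(field_um))
    stop("nucleus diameter must be smaller than the field")
  if (is.null(min_separation_um))
    min_separation_um <- 2 * nucleus_radius_um + 22
  cfg <- list(rng_seed = as.integer(rng_seed),
              field_size_px = as.integer(field_size_px),
              pixel_size_um = pixel_size_um,
              frame_interval_h = frame_interval_h,
              n_frames = as.integer(n_frames),
              n_cells = as.integer(n_cells),
              nucleus_radius_um = nucleus_radius_um,
              cyto_width_um = cyto_width_um,
              motion_sigma_um_per_frame = motion_sigma_um_per_frame,
              division_rate_per_h = division_rate_per_h,
              snr = snr,
              illumination_bias_amplitude = illumination_bias_amplitude,
              persister_fraction = persister_fraction,
              combo_factor = combo_factor,
              rise_window_h = rise_window_h,
              rise_tau_h = rise_tau_h,
              degron_type = degron_type,
              background = background,
              nucleus_intensity = nucleus_intensity,
              blur_sigma_px = blur_sigma_px,
              min_separation_um = min_separation_um)
  class(cfg) <- "sim_config"
  cfg
}

# Longest contiguous run (hours) of x > threshold inside the closed time
# window, used to stamp ground-truth persister labels. Run duration is
# (frames_in_run - 1) * dt.
longest_run_h <- function(t_h, x, threshold = 1, window_h = c(30, 48),
                          dt = NULL) {
  keep <- t_h >= window_h[1] & t_h <= window_h[2] & is.finite(x)
  t_h <- t_h[keep]; x <- x[keep]
  if (length(x) == 0L) return(0)
  if (is.null(dt)) dt <- if (length(t_h) > 1) min(diff(t_h)) else 0
  above <- x > threshold
  r <- rle(above)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) return(0)
  (max(runs) - 1) * dt
}

# Degron reporter intensity given phase progression.
degron_value <- function(type, u, phase, t_h, t_cross, scenario) {
  if (scenario == "untreated") {
    if (type == "geminin") {
      # accumulates through S/G2, cleared at mitosis
      15 + 90 * pmax(0, (u - 0.35) / 0.65)
    } else {
      # cdt1: high in G1, degraded in S, partial re-accumulation in G2
      ifelse(u < 0.35, 80,
             ifelse(u < 0.7, pmax(15, 80 - 70 * (u - 0.35) / 0.1),
                    15 + 50 * (u - 0.7) / 0.3))
    }
  } else {
    if (type == "geminin") {
      v <- rep(15, length(t_h))
      if (!is.na(t_cross))
        v <- v + 90 * clamp((t_h - t_cross) / 10, 0, 1)
      v
    } else {
      v <- rep(80, length(t_h))
      if (!is.na(t_cross))
        v <- pmax(15, 80 - 70 * clamp((t_h - t_cross) / 2, 0, 1))
      v
    }
  }
}

# Assign persister/arrest fates for a treated scenario.
assign_fates <- function(cfg, scenario) {
  n <- cfg$n_cells
  frac <- switch(scenario,
                 untreated = 0,
                 cdk46i = cfg$persister_fraction,
                 cdk46i_plus_cdk7i = cfg$persister_fraction * cfg$combo_factor)
  n_pers <- round(frac * n)
  fate <- rep(FALSE, n)
  if (n_pers > 0) fate[sample.int(n, n_pers)] <- TRUE
  fate
}

#' Simulate ground-truth activity traces without rendering images
#'
#' Generates per-cell CDK4/6 / CDK2 activity and degron trajectories on the
#' frame grid for a treatment scenario, optionally adding i.i.d. Gaussian
#' measurement noise to the activities, and returns both the observed
#' [trace_set] and the noiseless ground truth. Useful for validating trace
#' classifiers at population scale without paying the imaging cost.
#'
#' @param cfg A [sim_config()].
#' @param scenario One of `"untreated"`, `"cdk46i"`, `"cdk46i_plus_cdk7i"`.
#' @param noise_sd SD of additive Gaussian noise on observed activities.
#' @return A list with `traces` (a `trace_set` data frame: `track_id`,
#'   `frame`, `t_h`, `cdk46`, `cdk2`, `degron`, `valid`, `interpolated`) and
#'   `truth` (list with per-cell `cells` table incl. `is_persister`, and the
#'   noiseless `frames` table).
#' @examples
#' sim <- simulate_traces(sim_config(n_cells = 10, n_frames = 60))
#' table(sim$truth$cells$is_persister)
#' @export
simulate_traces <- function(cfg, scenario = c("cdk46i", "untreated",
                                              "cdk46i_plus_cdk7i"),
                            noise_sd = 0) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(cfg, "sim_config"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(cfg$rng_seed, {
    truth <- simulate_truth(cfg, scenario, with_motion = FALSE)
    fr <- truth$frames
    obs <- data.frame(track_id = fr$cell_id, frame = fr$frame, t_h = fr$t_h,
                      cdk46 = fr$cdk46, cdk2 = fr$cdk2, degron = fr$degron,
                      valid = TRUE, interpolated = FALSE)
    if (noise_sd > 0) {
      obs$cdk46 <- obs$cdk46 + rnorm(nrow(obs), 0, noise_sd)
      obs$cdk2 <- obs$cdk2 + rnorm(nrow(obs), 0, noise_sd)
    }
    obs <- as_trace_set(obs, frame_interval_h = cfg$frame_interval_h)
    list(traces = obs, truth = truth)
  })
}

# Core ground-truth generator: fates, trajectories, motion, divisions.
# Must be called inside with_seed(). Returns list(cells, frames, divisions).
simulate_truth <- function(cfg, scenario, with_motion = TRUE) {
  n_frames <- cfg$n_frames
  dt <- cfg$frame_interval_h
  t_grid <- (seq_len(n_frames) - 1) * dt
  field_um <- cfg$field_size_px * cfg$pixel_size_um
  r <- cfg$nucleus_radius_um
  margin <- r + cfg$cyto_width_um + 2 * cfg$pixel_size_um

  fate <- assign_fates(cfg, scenario)
  t_cross <- ifelse(fate,
                    runif(cfg$n_cells, cfg$rise_window_h[1],
                          cfg$rise_window_h[2]),
                    NA_real_)

  # initial placement: trace-only simulations (no motion, no rendering)
  # use an unconstrained grid; rendered movies use rejection sampling
  # with a minimum separation inside the field
  pos <- matrix(NA_real_, cfg$n_cells, 2)
  if (!with_motion) {
    side <- ceiling(sqrt(cfg$n_cells))
    idx <- seq_len(cfg$n_cells) - 1L
    pos[, 1] <- margin + (idx %% side) * cfg$min_separation_um
    pos[, 2] <- margin + (idx %/% side) * cfg$min_separation_um
  }
  max_try <- 5000L
  for (i in if (with_motion) seq_len(cfg$n_cells) else integer(0)) {
    placed <- FALSE
    for (k in seq_len(max_try)) {
      cand <- c(runif(1, margin, field_um[2] - margin),   # x
                runif(1, margin, field_um[1] - margin))   # y
      if (i == 1L ||
          all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                            matrix(cand, i - 1L, 2, byrow = TRUE))^2)) >=
              cfg$min_separation_um)) {
        pos[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", cfg$n_cells, " cells at radius ",
           r, " um without overlap")
  }

  cells <- data.frame(cell_id = seq_len(cfg$n_cells), parent_id = 0L,
                      birth_frame = 1L, death_frame = n_frames,
                      is_persister_fate = fate, t_cross_h = t_cross,
                      h2b = cfg$nucleus_intensity,
                      cycle_len_h = if (cfg$division_rate_per_h > 0)
                        (1 / cfg$division_rate_per_h) *
                          runif(cfg$n_cells, 0.8, 1.2)
                      else rep(Inf, cfg$n_cells),
                      phase0 = runif(cfg$n_cells),
                      stringsAsFactors = FALSE)
  divisions <- data.frame(parent_id = integer(), frame = integer(),
                          daughter1 = integer(), daughter2 = integer())

  frames_list <- list()
  next_id <- cfg$n_cells + 1L
  # active set processed frame by frame so divisions can spawn new cells
  state <- data.frame(cell_id = cells$cell_id, x = pos[, 1], y = pos[, 2],
                      born_h = 0, row = seq_len(cfg$n_cells))
  divide_allowed <- scenario == "untreated" && cfg$division_rate_per_h > 0

  for (f in seq_len(n_frames)) {
    t_now <- t_grid[f]
    rec <- state
    ci <- cells[rec$row, ]
    u <- ((t_now - rec$born_h) / ci$cycle_len_h + ci$phase0) %% 1
    if (scenario == "untreated") {
      cdk46 <- 0.7 + 0.9 * u
      cdk2 <- 0.5 + 1.2 * u^1.2
      phase <- ifelse(u < 0.35, "G1", ifelse(u < 0.7, "S", "G2M"))
    } else {
      decay <- exp(-t_now / 6)
      cdk46 <- rep(0.35 + 0.55 * decay, nrow(rec))
      cdk2 <- rep(0.5 + 0.4 * decay, nrow(rec))
      phase <- rep("G1", nrow(rec))
      pers <- ci$is_persister_fate
      if (any(pers)) {
        tc <- ci$t_cross_h[pers]
        cdk2[pers] <- cdk2[pers] +
          (1 - 0.4 * decay) * plogis((t_now - tc) / cfg$rise_tau_h)
        phase[pers][t_now >= tc] <- "S"
      }
    }
    degron <- vapply(seq_len(nrow(rec)), function(j) {
      degron_value(cfg$degron_type, u[j], phase[j], t_now,
                   ci$t_cross_h[j], scenario)
    }, numeric(1))
    frames_list[[f]] <- data.frame(
      cell_id = rec$cell_id, frame = f, t_h = t_now,
      x_um = rec$x, y_um = rec$y,
      cdk46 = cdk46, cdk2 = cdk2, degron = degron, phase = phase,
      h2b = ci$h2b, stringsAsFactors = FALSE)

    if (f == n_frames) break

    # motion: reflected Gaussian random walk with nuclear exclusion — a
    # step may not bring two nuclei closer than contact distance unless
    # they are already closer (freshly placed daughters may separate)
    if (with_motion && cfg$motion_sigma_um_per_frame > 0) {
      contact <- 2 * r + 2
      prop_x <- reflect(state$x + rnorm(nrow(state), 0,
                                        cfg$motion_sigma_um_per_frame),
                        margin, field_um[2] - margin)
      prop_y <- reflect(state$y + rnorm(nrow(state), 0,
                                        cfg$motion_sigma_um_per_frame),
                        margin, field_um[1] - margin)
      if (nrow(state) > 1L) {
        for (j in seq_len(nrow(state))) {
          others <- setdiff(seq_len(nrow(state)), j)
          d_old <- min(sqrt((state$x[others] - state$x[j])^2 +
                            (state$y[others] - state$y[j])^2))
          d_new <- min(sqrt((state$x[others] - prop_x[j])^2 +
                            (state$y[others] - prop_y[j])^2))
          if (d_new >= contact || d_new >= d_old) {
            state$x[j] <- prop_x[j]; state$y[j] <- prop_y[j]
          }
        }
      } else {
        state$x <- prop_x; state$y <- prop_y
      }
    }

    if (divide_allowed) {
      u_next <- ((t_grid[f + 1L] - state$born_h) /
                   cells$cycle_len_h[state$row] +
                   cells$phase0[state$row]) %% 1
      wrap <- u_next < u & (t_grid[f + 1L] - state$born_h) > dt
      for (j in which(wrap)) {
        parent_row <- state$row[j]
        parent_id <- state$cell_id[j]
        cells$death_frame[parent_row] <- f
        theta <- runif(1, 0, 2 * pi)
        off <- r * c(cos(theta), sin(theta))
        split_frac <- runif(1, 0.45, 0.55)
        d_ids <- c(next_id, next_id + 1L)
        next_id <- next_id + 2L
        for (k in 1:2) {
          sgn <- if (k == 1) 1 else -1
          new_cell <- data.frame(
            cell_id = d_ids[k], parent_id = parent_id,
            birth_frame = f + 1L, death_frame = n_frames,
            is_persister_fate = FALSE, t_cross_h = NA_real_,
            h2b = cells$h2b[parent_row] *
              (if (k == 1) split_frac else 1 - split_frac),
            cycle_len_h = (1 / cfg$division_rate_per_h) * runif(1, 0.8, 1.2),
            phase0 = 0, stringsAsFactors = FALSE)
          cells <- rbind(cells, new_cell)
          state <- rbind(state, data.frame(
            cell_id = d_ids[k],
            x = reflect(state$x[j] + sgn * off[1], margin,
                        field_um[2] - margin),
            y = reflect(state$y[j] + sgn * off[2], margin,
                        field_um[1] - margin),
            born_h = t_grid[f + 1L], row = nrow(cells)))
        }
        divisions <- rbind(divisions, data.frame(
          parent_id = parent_id, frame = f,
          daughter1 = d_ids[1], daughter2 = d_ids[2]))
      }
      if (any(wrap)) state <- state[-which(wrap), , drop = FALSE]
    }
  }

  frames <- do.call(rbind, frames_list)
  frames <- frames[order(frames$cell_id, frames$frame), ]
  rownames(frames) <- NULL

  # ground-truth persister label: sliding-window rule on the true CDK2 trace
  run_by_cell <- vapply(split(frames, frames$cell_id), function(d) {
    longest_run_h(d$t_h, d$cdk2, threshold = 1, window_h = c(30, 48), dt = dt)
  }, numeric(1))
  cells$longest_run_h <- run_by_cell[as.character(cells$cell_id)]
  cells$is_persister <- cells$longest_run_h > 4
  list(cells = cells, frames = frames, divisions = divisions,
       scenario = scenario, config = cfg)
}

reflect <- function(x, lo, hi) {
  rng <- hi - lo
  y <- (x - lo) %% (2 * rng)
  lo + ifelse(y > rng, 2 * rng - y, y)
}
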