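#' Hill-curve inhibition fraction
#'
#' Fractional inhibition at dose `d` for a 4-parameter Hill model rising
#' from `bottom` (at dose 0) to `top` (at saturating dose).
#'
#' @param d Dose (same units as `ic50`), >= 0.
#' @param ic50 Half-maximal dose (> 0).
#' @param hill Hill slope (> 0).
#' @param bottom,top Asymptotic inhibition fractions.
#' @return Inhibition fraction(s) in `[bottom, top]`.
#' @export
hill_inhibition <- function(d, ic50, hill, bottom = 0, top = 1) {
  stopifnot(ic50 > 0, hill > 0)
  frac <- ifelse(d <= 0, 0, d^hill / (d^hill + ic50^hill))
  bottom + (top - bottom) * frac
}

# Interaction bump: a Gaussian in log-dose centered at (ic50_a, ic50_b),
# zero on the single-agent margins so Bliss margins stay exact.
interaction_bump <- function(a, b, ic50_a, ic50_b, width = 1) {
  ifelse(a <= 0 | b <= 0, 0,
         exp(-((log(a / ic50_a))^2 + (log(b / ic50_b))^2) / (2 * width^2)))
}

#' Simulate a checkerboard dose-combination matrix
#'
#' Generates per-well inhibition fractions for a two-drug dose grid under a
#' Bliss-independence null plus an optional interaction term:
#' `y(a, b) = clamp(ya + yb - ya*yb + interaction * g(a, b) + noise, 0, 1)`
#' where `ya`, `yb` follow Hill curves and `g` is a Gaussian bump in
#' log-dose centered at the two IC50s (zero on the margins). With
#' `interaction = 0` the matrix satisfies Bliss independence exactly.
#'
#' @param ic50_a,hill_a,ic50_b,hill_b Hill parameters of the single agents.
#' @param interaction Amplitude of the interaction bump (positive =
#'   synergistic excess over Bliss).
#' @param doses_a,doses_b Dose grids (must include 0 to carry the
#'   single-agent margins).
#' @param noise_sd SD of additive Gaussian noise per well (>= 0).
#' @param n_replicates Replicate wells per dose pair.
#' @param rng_seed Seed.
#' @return A `dose_matrix` data frame (`dose_a`, `dose_b`, `replicate`,
#'   `inhibition`) with the ground-truth parameters in
#'   `attr(, "ground_truth")`.
#' @examples
#' dm <- simulate_dose_matrix(ic50_a = 10, hill_a = 1, ic50_b = 100,
#'                            hill_b = 1.5, interaction = 0,
#'                            doses_a = c(0, 1, 10, 100),
#'                            doses_b = c(0, 10, 100, 1000), noise_sd = 0)
#' range(bliss_synergy(dm)$excess)
#' @export
simulate_dose_matrix <- function(ic50_a, hill_a, ic50_b, hill_b,
                                 interaction = 0,
                                 doses_a, doses_b,
                                 noise_sd = 0, n_replicates = 1L,
                                 rng_seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(doses_a < 0) || any(doses_b < 0)) stop("doses must be >= 0")
  grid <- expand.grid(dose_a = doses_a, dose_b = doses_b,
                      replicate = seq_len(n_replicates))
  ya <- hill_inhibition(grid$dose_a, ic50_a, hill_a)
  yb <- hill_inhibition(grid$dose_b, ic50_b, hill_b)
  g <- interaction_bump(grid$dose_a, grid$dose_b, ic50_a, ic50_b)
  y <- ya + yb - ya * yb + interaction * g
  with_seed(rng_seed, {
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  })
  grid$inhibition <- clamp(y, 0, 1)
  attr(grid, "ground_truth") <- list(
    ic50_a = ic50_a, hill_a = hill_a, ic50_b = ic50_b, hill_b = hill_b,
    interaction = interaction, noise_sd = noise_sd)
  class(grid) <- c("dose_matrix", "data.frame")
  grid
}

#' Simulate per-cell EdU (or EU) intensities as a log-normal mixture
#'
#' Draws labelled-cell intensities from a two-component log-normal mixture:
#' a dim unlabelled population and a bright S-phase (or
#' transcription-active) population.
#'
#' @param n Number of cells.
#' @param positive_fraction Fraction in the bright component.
#' @param meanlog_neg,meanlog_pos Log-means of the two components.
#' @param sdlog SD on the log scale (both components).
#' @param rng_seed Seed.
#' @return List with `intensity` (length `n`) and logical `is_positive`
#'   ground truth.
#' @export
simulate_edu_intensities <- function(n, positive_fraction,
                                     meanlog_neg = log(50),
                                     meanlog_pos = log(1000),
                                     sdlog = 0.4, rng_seed = 1L) {
  stopifnot(n >= 1, positive_fraction >= 0, positive_fraction <= 1)
  with_seed(rng_seed, {
    n_pos <- round(n * positive_fraction)
    pos <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
    pos <- sample(pos)
    x <- ifelse(pos, rlnorm(n, meanlog_pos, sdlog),
                rlnorm(n, meanlog_neg, sdlog))
    list(intensity = x, is_positive = pos)
  })
}
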