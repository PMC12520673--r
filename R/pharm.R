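#' Fit a four-parameter logistic dose-response curve (IC50)
#'
#' Fits `y = bottom + (top - bottom) / (1 + (d / ic50)^hill)` by
#' Levenberg-Marquardt least squares with multi-start initialization over a
#' grid of log-IC50 and Hill-slope starting values; the IC50 is
#' parameterized on the log scale so it stays positive. A response span too
#' small to identify the curve (flat data) or failure of every start
#' yields a non-converged fit with `NA` IC50.
#'
#' @param dose Dose vector (>= 0; vehicle 0 allowed). At least 4 distinct
#'   doses spanning >= 2 decades of positive dose are required.
#' @param response Normalized response (vehicle ~ 1, decreasing with dose).
#' @param min_span Minimum response range deemed identifiable.
#' @return An `ic50_fit` object: coefficients `bottom`, `top`, `ic50`,
#'   `hill`, plus `rss`, `converged`, and the data.
#' @examples
#' d <- c(0, 10^seq(-1, 3, length.out = 8))
#' y <- 0.1 + 0.9 / (1 + (d / 10)^1)
#' fit_ic50(d, y)
#' @export
fit_ic50 <- function(dose, response, min_span = 0.05) {
  stopifnot(length(dose) == length(response), all(dose >= 0))
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct doses")
  pos <- unique(dose[dose > 0])
  if (length(pos) < 2L || log10(max(pos) / min(pos)) < 2)
    warning("positive doses span less than 2 decades; IC50 may be poorly ",
            "identified")
  dat <- data.frame(d = dose, y = response)
  out <- structure(
    list(coefficients = c(bottom = NA_real_, top = NA_real_,
                          ic50 = NA_real_, hill = NA_real_),
         rss = NA_real_, converged = FALSE, data = dat),
    class = "ic50_fit")
  if (diff(range(response)) < min_span) return(out)

  starts <- expand.grid(
    lic50 = log(10) * seq(log10(min(pos)), log10(max(pos)),
                          length.out = 5),
    hill = c(0.5, 1, 2))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (log(pmax(d, 1e-12)) -
                                                         lic50))),
        data = dat,
        start = list(bottom = min(response), top = max(response),
                     lic50 = starts$lic50[s], hill = starts$hill[s]),
        lower = c(-Inf, -Inf, log(min(pos)) - 10, 0.05),
        upper = c(Inf, Inf, log(max(pos)) + 10, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out)
  cf <- coef(best$fit)
  out$coefficients <- c(bottom = unname(cf["bottom"]),
                        top = unname(cf["top"]),
                        ic50 = exp(unname(cf["lic50"])),
                        hill = unname(cf["hill"]))
  out$rss <- best$rss
  out$converged <- TRUE
  out
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("ic50_fit: not converged (flat or unidentifiable response)\n")
  } else {
    cf <- x$coefficients
    cat(sprintf(
      "ic50_fit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (RSS %.3g)\n",
      cf["ic50"], cf["hill"], cf["top"], cf["bottom"], x$rss))
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d else
    (if (is.data.frame(newdata)) newdata$d else newdata)
  cf <- object$coefficients
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (d / cf["ic50"])^cf["hill"])
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data$d; y <- x$data$y
  dp <- pmax(d, min(d[d > 0]) / 10)
  plot(dp, y, log = "x", xlab = "dose", ylab = "normalized response", ...)
  if (x$converged) {
    grid <- exp(seq(log(min(dp)), log(max(dp)), length.out = 200))
    lines(grid, predict(x, grid))
    abline(v = x$coefficients["ic50"], lty = 2)
  }
  invisible(x)
}

#' Bliss independence synergy score for a dose-combination matrix
#'
#' Single-agent effects `ya(a)` and `yb(b)` are taken from the matrix
#' margins (wells with the other drug at dose 0), clamped to `[0, 1]`. The
#' Bliss expectation is `ya + yb - ya * yb`; the excess is the observed
#' inhibition minus this expectation (identically 0 on the margins by
#' construction). The summary score is the mean excess over the
#' combination wells (both doses > 0) times 100, with a seeded cell-wise
#' nonparametric bootstrap over replicates for the 95% CI.
#'
#' @param dm A `dose_matrix` data frame (`dose_a`, `dose_b`,
#'   `replicate`, and `inhibition` or `response`).
#' @param response_type `"inhibition"` (already a fractional effect) or
#'   `"normalized"` (vehicle-normalized viability-style response, converted
#'   as `y = 1 - response`).
#' @param n_boot Bootstrap resamples (0 disables the CI).
#' @param rng_seed Seed for the bootstrap.
#' @return A `bliss_synergy` object: `doses_a`, `doses_b`, `observed`,
#'   `expected`, `excess` (matrices), `score`, `ci`.
#' @export
bliss_synergy <- function(dm, response_type = c("inhibition",
                                                    "normalized"),
                          n_boot = 1000L, rng_seed = 7L) {
  response_type <- match.arg(response_type)
  df <- as.data.frame(dm)
  if (!"inhibition" %in% names(df)) {
    if (!"response" %in% names(df)) stop("need inhibition or response column")
    df$inhibition <- if (response_type == "normalized") 1 - df$response
                     else df$response
  } else if (response_type == "normalized") {
    df$inhibition <- 1 - df$inhibition
  }
  if (is.null(df$replicate)) df$replicate <- 1L
  da <- sort(unique(df$dose_a)); db <- sort(unique(df$dose_b))
  if (!(0 %in% da) || !(0 %in% db))
    stop("matrix must include single-agent margins (dose 0 rows/columns)")

  score_of <- function(y_mean) {
    ya <- clamp(y_mean[, db == 0], 0, 1)
    yb <- clamp(y_mean[da == 0, ], 0, 1)
    expected <- outer(ya, yb, function(a, b) a + b - a * b)
    excess <- y_mean - expected
    interior <- outer(da > 0, db > 0, "&")
    list(expected = expected, excess = excess,
         score = mean(excess[interior]) * 100)
  }
  cell_means <- function(d) {
    m <- with(d, tapply(inhibition, list(factor(dose_a, levels = da),
                                         factor(dose_b, levels = db)),
                        mean))
    unname(m)
  }
  y_mean <- cell_means(df)
  if (anyNA(y_mean)) stop("dose grid is incomplete")
  res <- score_of(y_mean)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    groups <- split(df$inhibition, list(factor(df$dose_a, levels = da),
                                        factor(df$dose_b, levels = db)))
    scores <- with_seed(rng_seed, vapply(seq_len(n_boot), function(b) {
      means <- vapply(groups, function(g)
        mean(g[sample.int(length(g), replace = TRUE)]), numeric(1))
      score_of(matrix(means, length(da), length(db)))$score
    }, numeric(1)))
    ci <- unname(quantile(scores, c(0.025, 0.975)))
  }
  structure(list(doses_a = da, doses_b = db, observed = y_mean,
                 expected = res$expected, excess = res$excess,
                 score = res$score, ci = ci, n_boot = n_boot),
            class = "bliss_synergy")
}

#' @export
print.bliss_synergy <- function(x, ...) {
  cat(sprintf("bliss_synergy: %d x %d grid, score = %.3f",
              length(x$doses_a), length(x$doses_b), x$score))
  if (!anyNA(x$ci))
    cat(sprintf(" (95%% CI %.3f to %.3f, %d resamples)", x$ci[1], x$ci[2],
                x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
plot.bliss_synergy <- function(x, ...) {
  image(seq_along(x$doses_a), seq_along(x$doses_b), x$excess,
        xlab = "dose A index", ylab = "dose B index",
        main = sprintf("Bliss excess (score %.2f)", x$score),
        col = hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}

#' Caliper tumor volume
#'
#' `volume = width^2 * length / 2`, with the shorter caliper dimension
#' taken as the width regardless of argument order.
#'
#' @param width_mm,length_mm Caliper measurements in millimetres (> 0);
#'   vectorized.
#' @return Volume(s) in cubic millimetres.
#' @examples
#' tumor_volume(5, 8)   # 100
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0))
    stop("caliper measurements must be positive")
  w <- pmin(width_mm, length_mm)
  l <- pmax(width_mm, length_mm)
  w^2 * l / 2
}
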