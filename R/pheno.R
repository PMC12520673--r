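#' Classify a single CDK2 activity trace as persister or arrested
#'
#' A cell is a drug persister when its CDK2 activity exceeds `threshold`
#' for more than `min_duration_h` (strictly) in one contiguous run inside
#' the closed analysis window (default 30-48 h after treatment). The run
#' duration of k consecutive supra-threshold frames is
#' `(k - 1) * frame_interval_h`. Invalid frames break runs. Traces covering
#' less than `min_coverage` of the window's frames are excluded (not
#' counted in any denominator).
#'
#' @param t_h Frame times (h, relative to treatment).
#' @param cdk2 CDK2 activity values (C/N ratio).
#' @param valid Logical vector of per-frame validity (default all valid).
#' @param threshold Activity threshold (default 1.0).
#' @param window_h Closed analysis window, hours (default `c(30, 48)`).
#' @param min_duration_h Required run duration, hours, strict (default 4).
#' @param frame_interval_h Frame interval (h); inferred from `t_h` when
#'   `NULL`.
#' @param min_coverage Minimum fraction of window frames that must be
#'   valid.
#' @param cumulative If `TRUE`, sum the durations of all supra-threshold
#'   runs instead of taking the longest single run (alternative reading of
#'   the rule; default `FALSE` = contiguous).
#' @return A one-row data frame: `is_persister`, `longest_run_h`,
#'   `excluded`, `reason`.
#' @examples
#' t <- seq(0, 48, by = 0.2)
#' classify_persister(t, ifelse(t > 31, 1.2, 0.6))
#' @export
classify_persister <- function(t_h, cdk2, valid = NULL, threshold = 1.0,
                               window_h = c(30, 48), min_duration_h = 4,
                               frame_interval_h = NULL,
                               min_coverage = 0.8, cumulative = FALSE) {
  if (is.null(valid)) valid <- rep(TRUE, length(t_h))
  if (is.null(frame_interval_h)) {
    frame_interval_h <- if (length(t_h) > 1) min(diff(sort(t_h))) else NA
  }
  ord <- order(t_h)
  t_h <- t_h[ord]; cdk2 <- cdk2[ord]; valid <- valid[ord]
  eps <- 1e-9
  inw <- t_h >= window_h[1] - eps & t_h <= window_h[2] + eps
  n_expected <- floor((window_h[2] - window_h[1]) / frame_interval_h +
                        eps) + 1L
  n_valid <- sum(inw & valid & is.finite(cdk2))
  if (n_valid < min_coverage * n_expected) {
    return(data.frame(is_persister = NA, longest_run_h = NA_real_,
                      excluded = TRUE, reason = "insufficient_coverage"))
  }
  sel <- inw
  above <- sel & valid & is.finite(cdk2) & cdk2 > threshold
  r <- rle(above[sel])
  runs <- r$lengths[r$values]
  run_h <- if (length(runs) == 0L) 0 else if (cumulative)
    sum(pmax(runs - 1, 0)) * frame_interval_h
  else (max(runs) - 1) * frame_interval_h
  data.frame(is_persister = run_h > min_duration_h, longest_run_h = run_h,
             excluded = FALSE, reason = NA_character_)
}

#' Classify every trace of a trace set
#'
#' Applies [classify_persister()] to each track of a `trace_set`,
#' restricted to tracks meeting the minimum-duration eligibility recorded
#' by [build_traces()] (when present).
#'
#' @param traces A `trace_set`.
#' @param ... Passed to [classify_persister()].
#' @return A `persister_calls` data frame: `track_id`, `is_persister`,
#'   `longest_run_h`, `excluded`, `reason`.
#' @export
classify_persisters <- function(traces, ...) {
  stopifnot(inherits(traces, "trace_set"))
  dt <- attr(traces, "frame_interval_h")
  eligible <- attr(traces, "eligible_tracks")
  ids <- unique(traces$track_id)
  if (!is.null(eligible)) ids <- intersect(ids, eligible)
  rows <- lapply(ids, function(id) {
    d <- traces[traces$track_id == id, ]
    cbind(track_id = id,
          classify_persister(d$t_h, d$cdk2, d$valid,
                             frame_interval_h = dt, ...))
  })
  out <- do.call(rbind, rows) %||%
    data.frame(track_id = integer(), is_persister = logical(),
               longest_run_h = numeric(), excluded = logical(),
               reason = character())
  class(out) <- c("persister_calls", "data.frame")
  out
}

#' Persister fraction of a set of calls
#'
#' The denominator is the number of cells passing coverage QC (excluded
#' cells are dropped). With `n_boot > 0` a seeded nonparametric bootstrap
#' over cells gives percentile 95% confidence bounds.
#'
#' @param calls A `persister_calls` data frame.
#' @param n_boot Bootstrap resamples (0 = no CI).
#' @param rng_seed Seed for the bootstrap.
#' @return Named list: `fraction`, `n_persister`, `n_cells`, `ci`.
#' @export
persister_fraction <- function(calls, n_boot = 0L, rng_seed = 1L) {
  kept <- calls[!calls$excluded, ]
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(kept) > 0) {
    ci <- with_seed(rng_seed, {
      fr <- vapply(seq_len(n_boot), function(b)
        mean(kept$is_persister[sample.int(nrow(kept), replace = TRUE)]),
        numeric(1))
      unname(quantile(fr, c(0.025, 0.975)))
    })
  }
  list(fraction = if (nrow(kept)) mean(kept$is_persister) else NA_real_,
       n_persister = sum(kept$is_persister), n_cells = nrow(kept),
       ci = ci)
}

#' EdU-positive (S-phase) fraction from per-cell intensities
#'
#' Thresholds log-intensities by Otsu (`otsu_log`), a 2-component Gaussian
#' mixture (`gmm2`; falls back to Otsu with a warning when the mixture is
#' degenerate), or a fixed threshold on the raw scale (`fixed`).
#'
#' @param intensity Per-cell EdU intensities (> 0).
#' @param method Thresholding method.
#' @param fixed_threshold Raw-scale threshold for `method = "fixed"`.
#' @param min_cells Minimum cell count for automatic thresholding.
#' @return List: `fraction`, `threshold` (raw scale), `calls` (logical).
#' @export
edu_positive_fraction <- function(intensity,
                                  method = c("otsu_log", "gmm2", "fixed"),
                                  fixed_threshold = NULL, min_cells = 50L) {
  method <- match.arg(method)
  x <- intensity[is.finite(intensity)]
  if (method != "fixed" && length(x) < min_cells)
    stop("automatic thresholding needs at least ", min_cells, " cells")
  if (method == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed method needs fixed_threshold")
    thr <- fixed_threshold
  } else {
    lx <- log(pmax(x, .Machine$double.eps))
    if (method == "gmm2") {
      fit <- tryCatch(
        Mclust(lx, G = 2, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      # unimodal data split into two heavily overlapping components leave
      # most points ambiguous; well-separated modes assign them cleanly
      degenerate <- is.null(fit) ||
        mean(apply(fit$z, 1, max)) < 0.9
      if (degenerate) {
        warning("gmm2 degenerate (unimodal input); falling back to otsu_log")
        thr <- exp(otsu_threshold(lx))
      } else {
        hi <- which.max(fit$parameters$mean)
        grid <- seq(min(fit$parameters$mean), max(fit$parameters$mean),
                    length.out = 512)
        post <- predict(fit, newdata = grid)$z[, hi]
        thr <- exp(grid[which(post >= 0.5)[1]])
      }
    } else {
      thr <- exp(otsu_threshold(lx))
    }
  }
  calls <- intensity > thr
  list(fraction = mean(calls, na.rm = TRUE), threshold = thr, calls = calls)
}

#' Summarize per-cell EU (transcription) intensities on a seeded subsample
#'
#' Draws a uniform random subsample without replacement of `sample_n` cells
#' (all cells, with a warning, when fewer are available) and reports its
#' mean and SD — mirroring violin-plot summaries built on a fixed number of
#' randomly selected cells per condition and replicate.
#'
#' @param intensity Per-cell EU intensities.
#' @param sample_n Cells to sample (default 1000).
#' @param rng_seed Seed.
#' @return List: `sample`, `mean`, `sd`, `n`.
#' @export
eu_summarize <- function(intensity, sample_n = 1000L, rng_seed = 1L) {
  x <- intensity[is.finite(intensity)]
  if (length(x) == 0L) stop("no finite intensities supplied")
  with_seed(rng_seed, {
    if (length(x) <= sample_n) {
      if (length(x) < sample_n)
        warning("fewer than sample_n cells; using all")
      s <- x
    } else {
      s <- x[sample.int(length(x), sample_n)]
    }
    list(sample = s, mean = mean(s), sd = sd(s), n = length(s))
  })
}

#' Build a normalized dose-response table
#'
#' Aggregates per-dose summaries (duplicate doses averaged, n recorded) and
#' normalizes responses to the vehicle (dose 0) mean, which is set to 1.
#' Non-monotone mean responses are reported via a message, not enforced.
#'
#' @param dose Dose vector (>= 0; must include vehicle dose 0).
#' @param response Raw response per entry (e.g. mean EU per cell, EdU
#'   fraction, or C/N activity).
#' @param readout Label for the readout type.
#' @return A data frame (`dose`, `response_raw`, `n`, `response`) with the
#'   vehicle-normalized response; class `dose_response_input`.
#' @export
dose_response_table <- function(dose, response,
                                readout = c("EU", "EdU_fraction",
                                            "cn_activity")) {
  readout <- match.arg(readout)
  stopifnot(length(dose) == length(response), all(dose >= 0))
  if (!any(dose == 0)) stop("vehicle (dose 0) is required")
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct doses including vehicle")
  agg <- aggregate(response, list(dose = dose), mean)
  names(agg)[2] <- "response_raw"
  agg$n <- as.integer(table(dose)[as.character(agg$dose)])
  veh <- agg$response_raw[agg$dose == 0]
  agg$response <- agg$response_raw / veh
  agg <- agg[order(agg$dose), ]
  if (is.unsorted(-agg$response) && is.unsorted(agg$response))
    message("dose_response_table: mean response is not monotone in dose")
  rownames(agg) <- NULL
  attr(agg, "readout") <- readout
  class(agg) <- c("dose_response_input", "data.frame")
  agg
}
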