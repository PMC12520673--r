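#' Cytoplasm-to-nucleus ratio of a KTR sensor
#'
#' The cytoplasm of each nucleus is approximated as an annular ring
#' extending `ring_inner_um` to `ring_outer_um` from the nuclear mask
#' (Euclidean distance to the label's pixels). A ring pixel is excluded if
#' it lies inside, or within `ring_inner_um` of, any other label's mask, or
#' if it falls in the ring band of more than one label (contested pixels
#' are excluded from both rings). The readout per label is
#' `median(cytoplasm pixels) / median(nucleus pixels)`; labels with fewer
#' than `min_ring_px` surviving ring pixels are flagged invalid.
#'
#' The nuclear median is taken over mask pixels deeper than
#' `nucleus_erode_px` from the mask boundary (falling back to the full mask
#' for tiny nuclei), which keeps partial-volume pixels at the blurred
#' nucleus/cytoplasm interface out of the nuclear statistic.
#'
#' @param sensor_image Numeric matrix (sensor channel).
#' @param mask A [label_mask()].
#' @param ring_inner_um,ring_outer_um Ring bounds (um) measured from the
#'   nuclear mask boundary.
#' @param min_ring_px Minimum number of valid ring pixels.
#' @param nucleus_erode_px Boundary depth (px) excluded from the nuclear
#'   median; set 0 to use the full mask.
#' @return Data frame: `label`, `nucleus_median`, `cytoplasm_median`,
#'   `ratio`, `n_ring_px`, `valid`.
#' @export
cn_ratio <- function(sensor_image, mask, ring_inner_um = 2,
                     ring_outer_um = 10, min_ring_px = 30,
                     nucleus_erode_px = 2) {
  stopifnot(inherits(mask, "label_mask"),
            identical(dim(sensor_image), dim(mask$labels)))
  if (ring_inner_um >= ring_outer_um)
    stop("ring_inner_um must be < ring_outer_um")
  px <- mask$pixel_size_um
  lab <- mask$labels
  ids <- mask$props$label
  n <- length(ids)
  out <- data.frame(label = ids, nucleus_median = NA_real_,
                    cytoplasm_median = NA_real_, ratio = NA_real_,
                    n_ring_px = 0L, valid = FALSE)
  if (n == 0L) return(out)
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- ceiling(ring_outer_um / px) + 1L
  ring_count <- matrix(0L, nr, nc)   # how many rings cover each pixel
  near_count <- matrix(0L, nr, nc)   # labels with d < ring_inner (incl. inside)
  ring_owner <- matrix(0L, nr, nc)   # last ring covering the pixel
  windows <- vector("list", n)
  dists <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- lab == ids[i]
    w <- which(sel, arr.ind = TRUE)
    r1 <- max(1L, min(w[, 1]) - pad); r2 <- min(nr, max(w[, 1]) + pad)
    c1 <- max(1L, min(w[, 2]) - pad); c2 <- min(nc, max(w[, 2]) + pad)
    sub <- sel[r1:r2, c1:c2]
    # distance (um) of every window pixel to the label's mask
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - sub))) * px
    windows[[i]] <- c(r1, r2, c1, c2)
    dists[[i]] <- d
    in_ring <- d >= ring_inner_um & d <= ring_outer_um
    in_near <- d < ring_inner_um           # includes the mask itself (d = 0)
    ring_count[r1:r2, c1:c2] <- ring_count[r1:r2, c1:c2] + in_ring
    near_count[r1:r2, c1:c2] <- near_count[r1:r2, c1:c2] + in_near
    ro <- ring_owner[r1:r2, c1:c2]
    ro[in_ring] <- i
    ring_owner[r1:r2, c1:c2] <- ro
  }
  for (i in seq_len(n)) {
    wi <- windows[[i]]
    r1 <- wi[1]; r2 <- wi[2]; c1 <- wi[3]; c2 <- wi[4]
    d <- dists[[i]]
    sub_lab <- lab[r1:r2, c1:c2]
    nuc_sel <- sub_lab == ids[i]
    if (nucleus_erode_px > 0) {
      din <- EBImage::imageData(EBImage::distmap(EBImage::Image(nuc_sel * 1)))
      deep <- nuc_sel & din > nucleus_erode_px
      if (sum(deep) >= 9L) nuc_sel <- deep
    }
    nuc <- sensor_image[r1:r2, c1:c2][nuc_sel]
    in_ring <- d >= ring_inner_um & d <= ring_outer_um
    ok <- in_ring &
      ring_count[r1:r2, c1:c2] == 1L &
      near_count[r1:r2, c1:c2] == 0L
    cyto <- sensor_image[r1:r2, c1:c2][ok]
    out$nucleus_median[i] <- median(nuc)
    out$n_ring_px[i] <- length(cyto)
    if (length(cyto) >= min_ring_px && out$nucleus_median[i] != 0) {
      out$cytoplasm_median[i] <- median(cyto)
      out$ratio[i] <- out$cytoplasm_median[i] / out$nucleus_median[i]
      out$valid[i] <- TRUE
    }
  }
  out
}

#' Median nuclear intensity per label
#'
#' Used for degron reporters (geminin / Cdt1 fragments) and H2B. As in
#' [cn_ratio()], the median is taken over mask pixels deeper than
#' `nucleus_erode_px` from the boundary (full mask for tiny nuclei) to
#' keep partial-volume boundary pixels out of the statistic.
#'
#' @param reporter_image Numeric matrix.
#' @param mask A [label_mask()].
#' @param nucleus_erode_px Boundary depth (px) excluded from the median.
#' @return Data frame: `label`, `nuclear_median`.
#' @export
nuclear_intensity <- function(reporter_image, mask, nucleus_erode_px = 2) {
  stopifnot(inherits(mask, "label_mask"),
            identical(dim(reporter_image), dim(mask$labels)))
  ids <- mask$props$label
  if (length(ids) == 0L)
    return(data.frame(label = integer(), nuclear_median = numeric()))
  out <- data.frame(label = ids, nuclear_median = NA_real_)
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  for (i in seq_along(ids)) {
    w <- which(lab == ids[i], arr.ind = TRUE)
    r1 <- max(1L, min(w[, 1]) - 2L); r2 <- min(nr, max(w[, 1]) + 2L)
    c1 <- max(1L, min(w[, 2]) - 2L); c2 <- min(nc, max(w[, 2]) + 2L)
    sel <- lab[r1:r2, c1:c2] == ids[i]
    if (nucleus_erode_px > 0) {
      din <- EBImage::imageData(EBImage::distmap(EBImage::Image(sel * 1)))
      deep <- sel & din > nucleus_erode_px
      if (sum(deep) >= 9L) sel <- deep
    }
    out$nuclear_median[i] <- median(reporter_image[r1:r2, c1:c2][sel])
  }
  out
}

# Construct/validate a trace_set data frame.
as_trace_set <- function(df, frame_interval_h, treatment_time_h = 0) {
  need <- c("track_id", "frame", "t_h", "cdk46", "cdk2", "degron",
            "valid", "interpolated")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$track_id, df$frame), need]
  rownames(df) <- NULL
  class(df) <- c("trace_set", "data.frame")
  attr(df, "frame_interval_h") <- frame_interval_h
  attr(df, "treatment_time_h") <- treatment_time_h
  df
}

#' Quantify sensor readouts for every frame of a movie
#'
#' Convenience wrapper running [cn_ratio()] on the two KTR channels and
#' [nuclear_intensity()] on the degron channel for each frame's mask.
#'
#' @param stack A [frame_stack()] with channels `cdk46`, `cdk2`, `degron`.
#' @param masks List of [label_mask()], one per frame.
#' @param ... Passed to [cn_ratio()].
#' @return Data frame: `frame`, `label`, `cdk46`, `cdk2`, `degron`,
#'   `valid`.
#' @export
quantify_stack <- function(stack, masks, ...) {
  stopifnot(inherits(stack, "frame_stack"),
            length(masks) == stack$n_frames)
  rows <- lapply(seq_len(stack$n_frames), function(f) {
    m <- masks[[f]]
    if (nrow(m$props) == 0L) return(NULL)
    r46 <- cn_ratio(get_frame(stack, "cdk46", f), m, ...)
    r2 <- cn_ratio(get_frame(stack, "cdk2", f), m, ...)
    dg <- nuclear_intensity(get_frame(stack, "degron", f), m)
    data.frame(frame = f, label = r46$label,
               cdk46 = r46$ratio, cdk2 = r2$ratio,
               degron = dg$nuclear_median[match(r46$label, dg$label)],
               valid = r46$valid & r2$valid)
  })
  do.call(rbind, rows)
}

#' Assemble per-cell activity traces from tracks and per-frame readouts
#'
#' Joins track records to per-frame ratio/intensity tables, re-indexes time
#' relative to treatment, linearly interpolates (and flags) readouts across
#' bridged gaps of up to `max_gap` frames, and marks traces long enough for
#' persister analysis.
#'
#' @param tracks A `cell_tracks` table.
#' @param readouts Per-frame readout table from [quantify_stack()] (columns
#'   `frame`, `label`, `cdk46`, `cdk2`, `degron`, `valid`).
#' @param treatment_time_h Time of treatment relative to movie start (h);
#'   trace times are reported relative to this instant. Must not exceed the
#'   movie span.
#' @param frame_interval_h Frame interval (h).
#' @param max_gap Maximum bridged-gap length (frames) to interpolate.
#' @param min_duration_h Minimum trace duration to be eligible for
#'   persister analysis (attribute `eligible_tracks`).
#' @return A `trace_set` data frame.
#' @export
build_traces <- function(tracks, readouts, treatment_time_h = 0,
                         frame_interval_h = attr(tracks, "frame_interval_h"),
                         max_gap = 2, min_duration_h = 18) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (is.null(frame_interval_h)) frame_interval_h <- 0.2
  movie_span <- if (nrow(tracks)) max(tracks$frame) * frame_interval_h else 0
  if (treatment_time_h > movie_span)
    stop("treatment_time_h lies beyond the movie span")
  pieces <- lapply(split(as.data.frame(tracks), tracks$track_id),
                   function(d) {
    frames <- seq(min(d$frame), max(d$frame))
    full <- data.frame(track_id = d$track_id[1], frame = frames)
    full <- merge(full, d[, c("frame", "label")], by = "frame",
                  all.x = TRUE)
    key <- match(paste(full$frame, full$label),
                 paste(readouts$frame, readouts$label))
    full$cdk46 <- readouts$cdk46[key]
    full$cdk2 <- readouts$cdk2[key]
    full$degron <- readouts$degron[key]
    full$valid <- !is.na(key) & readouts$valid[key]
    full$interpolated <- FALSE
    # interpolate across bridged gaps (missing label rows) up to max_gap
    miss <- is.na(full$label)
    if (any(miss)) {
      r <- rle(miss)
      pos <- cumsum(c(1, r$lengths))
      for (k in seq_along(r$lengths)) {
        if (!r$values[k] || r$lengths[k] > max_gap) next
        i0 <- pos[k] - 1L; i1 <- pos[k] + r$lengths[k]
        if (i0 < 1L || i1 > nrow(full)) next
        if (!full$valid[i0] || !full$valid[i1]) next
        idx <- (i0 + 1L):(i1 - 1L)
        wgt <- (idx - i0) / (i1 - i0)
        for (col in c("cdk46", "cdk2", "degron"))
          full[[col]][idx] <- (1 - wgt) * full[[col]][i0] +
            wgt * full[[col]][i1]
        full$valid[idx] <- TRUE
        full$interpolated[idx] <- TRUE
      }
    }
    full$t_h <- (full$frame - 1) * frame_interval_h - treatment_time_h
    full
  })
  out <- do.call(rbind, pieces)
  out <- as_trace_set(out[, c("track_id", "frame", "t_h", "cdk46", "cdk2",
                              "degron", "valid", "interpolated")],
                      frame_interval_h, treatment_time_h)
  dur <- tapply(out$t_h, out$track_id, function(t) diff(range(t)))
  eligible <- as.integer(names(dur))[dur >= min_duration_h]
  if (length(eligible) == 0L)
    warning("no traces reach min_duration_h; persister analysis set empty")
  attr(out, "eligible_tracks") <- eligible
  out
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d track(s), %d record(s), dt = %.3g h\n",
              length(unique(x$track_id)), nrow(x),
              attr(x, "frame_interval_h") %||% NA))
  invisible(x)
}

#' Call cell-cycle phase transitions from a degron trace
#'
#' Cdt1-degron mode: the G1/S transition is the first sustained drop below
#' `frac_low` times the running maximum (the Cdt1 fragment is degraded on
#' S-phase entry); the S/G2 transition is the subsequent first sustained
#' rise above `frac_high` times the pre-drop level. Geminin-degron mode:
#' S-phase entry is the first sustained rise above the starting baseline
#' plus `k_mad` baseline MADs (geminin accumulates through S/G2). A
#' transition must hold for `sustain_frames` consecutive frames; traces
#' with no qualifying transition return an empty table.
#'
#' @param t_h Time vector (h).
#' @param value Degron intensity vector.
#' @param reporter `"cdt1"` or `"geminin"`.
#' @param frac_low,frac_high Cdt1 drop/recovery fractions.
#' @param k_mad Geminin rise threshold in baseline MADs.
#' @param sustain_frames Frames a crossing must persist.
#' @param baseline_frames Frames used for the geminin baseline.
#' @return List with `transitions` (data frame `event`, `t_h`) and
#'   `phases` (data frame `phase`, `t_start`, `t_end`).
#' @export
call_phase_transitions <- function(t_h, value,
                                   reporter = c("cdt1", "geminin"),
                                   frac_low = 0.5, frac_high = 0.7,
                                   k_mad = 3, sustain_frames = 3,
                                   baseline_frames = 10) {
  reporter <- match.arg(reporter)
  ok <- is.finite(value)
  t_h <- t_h[ok]; value <- value[ok]
  transitions <- data.frame(event = character(), t_h = numeric())
  phases <- data.frame(phase = character(), t_start = numeric(),
                       t_end = numeric())
  n <- length(value)
  if (n < sustain_frames + 1L)
    return(list(transitions = transitions, phases = phases))
  sustained_from <- function(cond) {
    # first index i such that cond[i..i+sustain-1] all TRUE
    if (!any(cond)) return(NA_integer_)
    r <- rle(cond)
    pos <- cumsum(c(1, r$lengths))
    hit <- which(r$values & r$lengths >= sustain_frames)
    if (length(hit) == 0L) return(NA_integer_)
    pos[hit[1]]
  }
  if (reporter == "cdt1") {
    runmax <- cummax(value)
    i_drop <- sustained_from(value < frac_low * runmax)
    if (!is.na(i_drop)) {
      pre_drop <- runmax[i_drop]
      transitions <- rbind(transitions, data.frame(
        event = "G1/S", t_h = t_h[i_drop]))
      later <- seq(i_drop, n)
      i_rise <- sustained_from(value[later] > frac_high * pre_drop)
      if (!is.na(i_rise)) {
        i_rise <- later[i_rise]
        transitions <- rbind(transitions, data.frame(
          event = "S/G2", t_h = t_h[i_rise]))
        phases <- data.frame(
          phase = c("G1", "S", "G2M"),
          t_start = c(t_h[1], t_h[i_drop], t_h[i_rise]),
          t_end = c(t_h[i_drop], t_h[i_rise], t_h[n]))
      } else {
        phases <- data.frame(phase = c("G1", "S"),
                             t_start = c(t_h[1], t_h[i_drop]),
                             t_end = c(t_h[i_drop], t_h[n]))
      }
    }
  } else {
    nb <- min(baseline_frames, n)
    base <- median(value[seq_len(nb)])
    noise <- mad(value[seq_len(nb)])
    thr <- base + k_mad * max(noise, 1e-12) + 1e-9
    i_rise <- sustained_from(value > thr)
    if (!is.na(i_rise)) {
      transitions <- data.frame(event = "S-entry", t_h = t_h[i_rise])
      phases <- data.frame(phase = c("G1", "S/G2"),
                           t_start = c(t_h[1], t_h[i_rise]),
                           t_end = c(t_h[i_rise], t_h[n]))
    }
  }
  list(transitions = transitions, phases = phases)
}
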