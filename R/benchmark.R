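#' Run the full live-cell analysis pipeline on a movie
#'
#' Segments every frame of the H2B channel ([segment_live()]), links nuclei
#' into tracks with mitosis detection ([link_frames()],
#' [detect_mitosis()]), quantifies KTR and degron readouts
#' ([quantify_stack()]), and assembles per-cell activity traces
#' ([build_traces()]).
#'
#' @param stack A [frame_stack()] with channels `h2b`, `cdk46`, `cdk2`,
#'   `degron`.
#' @param treatment_time_h Treatment time relative to movie start (h).
#' @param radius_range_um Nuclear radius range for detection.
#' @param detection_threshold LoG seed threshold (robust-SNR units).
#' @param max_step_um,max_gap_frames Tracking parameters.
#' @param flatfield Apply [flatfield_correct()] (background-estimated)
#'   before analysis.
#' @param ... Passed to [build_traces()].
#' @return List with `masks`, `tracks` (mitosis-annotated), `traces`.
#' @export
analyze_timelapse <- function(stack, treatment_time_h = 0,
                              radius_range_um = c(5, 12),
                              detection_threshold = 5,
                              max_step_um = 40, max_gap_frames = 2,
                              flatfield = FALSE, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  if (flatfield) stack <- flatfield_correct(stack)
  px <- stack$pixel_size_um
  masks <- lapply(seq_len(stack$n_frames), function(f)
    segment_live(get_frame(stack, "h2b", f), px,
                 radius_range_um = radius_range_um,
                 detection_threshold = detection_threshold))
  h2b <- lapply(seq_len(stack$n_frames), function(f)
    get_frame(stack, "h2b", f))
  tracks <- link_frames(masks, stack$frame_interval_h,
                        max_step_um = max_step_um,
                        max_gap_frames = max_gap_frames,
                        intensity_image = h2b)
  tracks <- detect_mitosis(tracks)
  readouts <- quantify_stack(stack, masks)
  traces <- build_traces(tracks, readouts,
                         treatment_time_h = treatment_time_h,
                         frame_interval_h = stack$frame_interval_h,
                         max_gap = max_gap_frames, ...)
  list(masks = masks, tracks = tracks, traces = traces)
}

#' Segmentation quality against simulation ground truth
#'
#' One-to-one matching of detections to true nuclei (a match requires the
#' detected centroid within `match_radius_um` of the true centroid; each
#' truth matches at most one detection, nearest first).
#'
#' @param masks List of [label_mask()] per frame.
#' @param truth Ground-truth list from [simulate_timelapse()].
#' @param match_radius_um Match radius (defaults to the nuclear radius).
#' @return List: `recall`, `precision`, `n_true`, `n_detected`.
#' @export
segmentation_metrics <- function(masks, truth,
                                 match_radius_um =
                                   truth$config$nucleus_radius_um) {
  byf <- split(truth$frames, truth$frames$frame)
  tp <- 0; fp <- 0; fn <- 0
  for (f in seq_along(masks)) {
    tf <- byf[[as.character(f)]]
    p <- masks[[f]]$props
    if (is.null(tf)) { fp <- fp + nrow(p); next }
    if (nrow(p) == 0L) { fn <- fn + nrow(tf); next }
    d <- sqrt(outer(tf$x_um, p$x_um, "-")^2 + outer(tf$y_um, p$y_um, "-")^2)
    used <- rep(FALSE, ncol(d))
    m <- 0
    for (i in order(apply(d, 1, min))) {
      j <- which.min(ifelse(used, Inf, d[i, ]))
      if (length(j) && is.finite(d[i, j]) && d[i, j] <= match_radius_um) {
        used[j] <- TRUE; m <- m + 1
      }
    }
    tp <- tp + m; fn <- fn + nrow(tf) - m; fp <- fp + nrow(p) - m
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       n_true = tp + fn, n_detected = tp + fp)
}

#' Tracking quality against simulation ground truth
#'
#' Each track record is matched to the nearest true cell of its frame.
#' Track purity is the fraction of a track's records coming from its
#' dominant true cell; completeness is the fraction of a true cell's
#' frames covered by its dominant track; division recall is the fraction
#' of true divisions with a detected division within one frame and
#' `match_radius_um` of the true parent's last position.
#'
#' @param tracks Mitosis-annotated `cell_tracks`.
#' @param truth Ground truth from [simulate_timelapse()].
#' @param match_radius_um Match radius for division events.
#' @return List: `purity`, `completeness`, `division_recall`,
#'   `n_true_divisions`.
#' @export
tracking_metrics <- function(tracks, truth, match_radius_um = 15) {
  rec <- as.data.frame(tracks)
  byf <- split(truth$frames, truth$frames$frame)
  rec$true_id <- NA_integer_
  for (f in unique(rec$frame)) {
    tf <- byf[[as.character(f)]]
    sel <- rec$frame == f
    d2 <- outer(rec$x_um[sel], tf$x_um, "-")^2 +
      outer(rec$y_um[sel], tf$y_um, "-")^2
    rec$true_id[sel] <- tf$cell_id[apply(d2, 1, which.min)]
  }
  purity <- vapply(split(rec$true_id, rec$track_id), function(v)
    max(table(v)) / length(v), numeric(1))
  compl <- vapply(split(rec, rec$true_id), function(d)
    max(table(d$track_id)) /
      sum(truth$frames$cell_id == d$true_id[1]), numeric(1))
  div <- attr(tracks, "divisions") %||%
    data.frame(parent_id = integer(), frame = integer())
  tdiv <- truth$divisions
  hit <- 0
  for (i in seq_len(nrow(tdiv))) {
    pf <- truth$frames
    ppos <- pf[pf$cell_id == tdiv$parent_id[i] &
                 pf$frame == tdiv$frame[i], ]
    ok <- FALSE
    for (j in seq_len(nrow(div))) {
      pr <- rec[rec$track_id == div$parent_id[j] &
                  rec$frame == div$frame[j], ]
      if (nrow(pr) > 0 && abs(div$frame[j] - tdiv$frame[i]) <= 1 &&
          sqrt((pr$x_um - ppos$x_um)^2 + (pr$y_um - ppos$y_um)^2) <=
            match_radius_um) ok <- TRUE
    }
    hit <- hit + ok
  }
  list(purity = mean(purity), completeness = mean(compl),
       division_recall = if (nrow(tdiv)) hit / nrow(tdiv) else NA_real_,
       n_true_divisions = nrow(tdiv))
}

#' Map pipeline tracks to ground-truth cells
#'
#' Returns, for each track, the dominant true cell id (by per-frame
#' nearest-centroid matching), so extracted traces can be compared with
#' true trajectories.
#'
#' @param tracks A `cell_tracks` table.
#' @param truth Ground truth from [simulate_timelapse()].
#' @return Named integer vector: track id -> true cell id.
#' @export
match_tracks_to_truth <- function(tracks, truth) {
  rec <- as.data.frame(tracks)
  byf <- split(truth$frames, truth$frames$frame)
  rec$true_id <- NA_integer_
  for (f in unique(rec$frame)) {
    tf <- byf[[as.character(f)]]
    sel <- rec$frame == f
    d2 <- outer(rec$x_um[sel], tf$x_um, "-")^2 +
      outer(rec$y_um[sel], tf$y_um, "-")^2
    rec$true_id[sel] <- tf$cell_id[apply(d2, 1, which.min)]
  }
  vapply(split(rec$true_id, rec$track_id), function(v)
    as.integer(names(sort(table(v), decreasing = TRUE))[1]), integer(1))
}
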