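# Min-cost one-to-one frame linking with births and deaths, solved as a
# square linear assignment problem (Hungarian method via clue::solve_LSAP).
# Links farther than max_step are forbidden. Returns for each row of `prev`
# the matched index into `curr` (NA = track end).
match_frame_pair <- function(prev, curr, max_step) {
  n1 <- nrow(prev); n2 <- nrow(curr)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d <- sqrt(outer(prev$x, curr$x, "-")^2 + outer(prev$y, curr$y, "-")^2)
  big <- 1e6 * (max_step + 1)
  cost <- matrix(big, n1 + n2, n1 + n2)
  link <- d
  link[link > max_step] <- big
  cost[seq_len(n1), seq_len(n2)] <- link
  for (i in seq_len(n1)) cost[i, n2 + i] <- max_step          # death
  for (j in seq_len(n2)) cost[n1 + j, j] <- max_step          # birth
  cost[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0           # dummy-dummy
  sol <- clue::solve_LSAP(cost)
  assign <- as.integer(sol)[seq_len(n1)]
  out <- ifelse(assign <= n2, assign, NA_integer_)
  # safety: never accept a forbidden link
  ok <- !is.na(out)
  out[ok][d[cbind(which(ok), out[ok])] > max_step] <- NA_integer_
  out
}

#' Link per-frame nuclei into tracks
#'
#' Frame-to-frame linking by globally optimal one-to-one assignment
#' (Hungarian algorithm) minimizing summed centroid displacement among
#' candidate pairs within `max_step_um`; competing claims between
#' continuing tracks and newborn detections are resolved by the global
#' optimum (the "deflection" repair). A second pass bridges track ends to
#' track starts over gaps of up to `max_gap_frames` missed frames when the
#' jump is within `max_step_um * (gap + 1)`, again by global assignment.
#'
#' @param masks List of [label_mask()] objects, one per frame (all sharing
#'   the same calibration), or a data frame of detections with columns
#'   `frame`, `label`, `x_um`, `y_um` and optionally `intensity`.
#' @param frame_interval_h Frame interval (h), used to stamp record times.
#' @param max_step_um Maximum per-frame displacement.
#' @param max_gap_frames Maximum number of consecutive missed frames a
#'   track may bridge.
#' @param intensity_image Optional list of matrices (e.g. the H2B channel
#'   per frame) from which integrated intensities are measured when `masks`
#'   is a list of label masks.
#' @return A `cell_tracks` data frame: `track_id`, `parent_id`, `frame`,
#'   `t_h`, `x_um`, `y_um`, `label`, `intensity`. Bridged (missed) frames
#'   are simply absent from the records.
#' @export
link_frames <- function(masks, frame_interval_h = 0.2, max_step_um = 40,
                        max_gap_frames = 2, intensity_image = NULL) {
  if (max_step_um <= 0) stop("max_step_um must be > 0")
  det <- if (is.data.frame(masks)) masks
         else detections_from_masks(masks, intensity_image)
  empty <- data.frame(track_id = integer(), parent_id = integer(),
                      frame = integer(), t_h = numeric(), x_um = numeric(),
                      y_um = numeric(), label = integer(),
                      intensity = numeric())
  class(empty) <- c("cell_tracks", "data.frame")
  attr(empty, "frame_interval_h") <- frame_interval_h
  if (nrow(det) == 0L) return(empty)
  if (is.null(det$intensity)) det$intensity <- NA_real_
  det <- det[order(det$frame, det$label), ]
  frames <- seq(min(det$frame), max(det$frame))

  det$track <- NA_integer_
  by_frame <- split(seq_len(nrow(det)), det$frame)
  # first frame: every detection starts a track
  i1 <- by_frame[[as.character(frames[1])]] %||% integer(0)
  det$track[i1] <- seq_len(length(i1))
  next_track <- length(i1) + 1L
  for (k in seq_along(frames)[-1]) {
    prev_idx <- by_frame[[as.character(frames[k - 1])]] %||% integer(0)
    curr_idx <- by_frame[[as.character(frames[k])]] %||% integer(0)
    if (length(curr_idx) == 0L) next
    prev <- data.frame(x = det$x_um[prev_idx], y = det$y_um[prev_idx])
    curr <- data.frame(x = det$x_um[curr_idx], y = det$y_um[curr_idx])
    m <- match_frame_pair(prev, curr, max_step_um)
    matched_curr <- rep(FALSE, length(curr_idx))
    for (i in seq_along(prev_idx)) {
      if (!is.na(m[i])) {
        det$track[curr_idx[m[i]]] <- det$track[prev_idx[i]]
        matched_curr[m[i]] <- TRUE
      }
    }
    for (j in which(!matched_curr)) {
      det$track[curr_idx[j]] <- next_track
      next_track <- next_track + 1L
    }
  }

  # gap closing: assign track ends to later track starts
  if (max_gap_frames > 0) {
    det <- close_gaps(det, max_step_um, max_gap_frames)
  }

  # renumber tracks in order of first appearance
  ord <- order(det$frame, det$track)
  first_seen <- det$track[ord][!duplicated(det$track[ord])]
  det$track <- match(det$track, first_seen)

  out <- data.frame(track_id = det$track, parent_id = 0L,
                    frame = det$frame,
                    t_h = (det$frame - 1) * frame_interval_h,
                    x_um = det$x_um, y_um = det$y_um,
                    label = det$label, intensity = det$intensity)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("cell_tracks", "data.frame")
  attr(out, "frame_interval_h") <- frame_interval_h
  attr(out, "max_gap_frames") <- max_gap_frames
  out
}

detections_from_masks <- function(masks, intensity_image = NULL) {
  rows <- lapply(seq_along(masks), function(f) {
    m <- masks[[f]]
    stopifnot(inherits(m, "label_mask"))
    p <- m$props
    if (nrow(p) == 0L) return(NULL)
    intensity <- if (!is.null(intensity_image)) {
      mp <- measure_labels(m, intensity_image[[f]], prefix = "i")
      mp$i_total
    } else NA_real_
    data.frame(frame = f, label = p$label, x_um = p$x_um, y_um = p$y_um,
               intensity = intensity)
  })
  do.call(rbind, rows) %||% data.frame(frame = integer(), label = integer(),
                                       x_um = numeric(), y_um = numeric(),
                                       intensity = numeric())
}

close_gaps <- function(det, max_step_um, max_gap_frames) {
  repeat {
    agg_first <- tapply(seq_len(nrow(det)), det$track, function(ix)
      ix[which.min(det$frame[ix])])
    agg_last <- tapply(seq_len(nrow(det)), det$track, function(ix)
      ix[which.max(det$frame[ix])])
    ends <- det[unlist(agg_last), ]
    starts <- det[unlist(agg_first), ]
    # candidate pairs: start strictly after end with gap 1..max_gap
    cand <- expand.grid(e = seq_len(nrow(ends)), s = seq_len(nrow(starts)))
    gap <- starts$frame[cand$s] - ends$frame[cand$e] - 1L
    dd <- sqrt((starts$x_um[cand$s] - ends$x_um[cand$e])^2 +
               (starts$y_um[cand$s] - ends$y_um[cand$e])^2)
    ok <- gap >= 1L & gap <= max_gap_frames &
      dd <= max_step_um * (gap + 1) &
      ends$track[cand$e] != starts$track[cand$s]
    if (!any(ok)) return(det)
    cand <- cand[ok, , drop = FALSE]; dd <- dd[ok]
    eu <- sort(unique(cand$e)); su <- sort(unique(cand$s))
    big <- 1e6 * (max_step_um + 1)
    n1 <- length(eu); n2 <- length(su)
    cost <- matrix(big, n1 + n2, n1 + n2)
    cost[cbind(match(cand$e, eu), match(cand$s, su))] <- dd
    no_link <- max_step_um * (max_gap_frames + 1)
    for (i in seq_len(n1)) cost[i, n2 + i] <- no_link
    for (j in seq_len(n2)) cost[n1 + j, j] <- no_link
    cost[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
    sol <- as.integer(clue::solve_LSAP(cost))
    merged <- FALSE
    for (i in seq_len(n1)) {
      j <- sol[i]
      if (j <= n2 && cost[i, j] < no_link) {
        from <- starts$track[su[j]]
        to <- ends$track[eu[i]]
        det$track[det$track == from] <- to
        merged <- TRUE
      }
    }
    if (!merged) return(det)
  }
}

#' Detect mitosis events and assign lineage
#'
#' A division is recorded when a track ending at frame `t` has two tracks
#' born at `t + 1` within `max_pair_distance_um` of its last centroid whose
#' combined intensity matches the parent's final intensity within
#' `intensity_tolerance` (relative). Because globally optimal linking
#' deflects the parent's identity onto one daughter (the parent rarely
#' "ends"), a continuing track with a single adjacent newborn is also
#' tested with the same rule; if it passes, the continuation is split at
#' the division frame and both daughters receive the parent id.
#'
#' @param tracks A `cell_tracks` data frame from [link_frames()], with
#'   per-record `intensity` (integrated nuclear H2B).
#' @param max_pair_distance_um Maximum daughter distance from the parent's
#'   last position.
#' @param intensity_tolerance Relative tolerance on
#'   `|I_d1 + I_d2 - I_parent| / I_parent`.
#' @return The track table with `parent_id` filled in for daughters (and
#'   continuing tracks split at division frames).
#' @export
detect_mitosis <- function(tracks, max_pair_distance_um = 25,
                           intensity_tolerance = 0.3) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (nrow(tracks) == 0L) return(tracks)
  tr <- as.data.frame(tracks)
  last_frame <- max(tr$frame)
  info <- do.call(rbind, lapply(split(tr, tr$track_id), function(d) {
    data.frame(track_id = d$track_id[1],
               start = min(d$frame), end = max(d$frame),
               x_start = d$x_um[which.min(d$frame)],
               y_start = d$y_um[which.min(d$frame)],
               i_start = d$intensity[which.min(d$frame)])
  }))
  newborn <- info[info$start > min(tr$frame), ]
  if (nrow(newborn) == 0L) {
    attr(tracks, "divisions") <- data.frame(
      parent_id = integer(), frame = integer(),
      daughter1 = integer(), daughter2 = integer())
    return(tracks)
  }

  events <- list()  # list of (parent, d1, d2, frame, mismatch, dist)
  taken <- integer(0)
  next_id <- max(tr$track_id) + 1L

  for (f in sort(unique(newborn$start))) {
    born <- newborn[newborn$start == f & !(newborn$track_id %in% taken), ]
    if (nrow(born) == 0L) next
    # case (a): tracks that ended at f - 1
    ended <- info[info$end == f - 1L & !(info$track_id %in% taken), ]
    cand_events <- list()
    if (nrow(ended) > 0L) {
      for (e in seq_len(nrow(ended))) {
        pe <- tr[tr$track_id == ended$track_id[e] &
                   tr$frame == ended$end[e], ]
        d_um <- sqrt((born$x_start - pe$x_um)^2 + (born$y_start - pe$y_um)^2)
        near <- which(d_um <= max_pair_distance_um)
        if (length(near) >= 2L) {
          prs <- utils::combn(near, 2)
          for (kk in seq_len(ncol(prs))) {
            i1 <- prs[1, kk]; i2 <- prs[2, kk]
            mism <- abs(born$i_start[i1] + born$i_start[i2] - pe$intensity) /
              pe$intensity
            if (is.finite(mism) && mism <= intensity_tolerance)
              cand_events[[length(cand_events) + 1L]] <- list(
                type = "pair", parent = pe$track_id,
                d1 = born$track_id[i1], d2 = born$track_id[i2],
                frame = f - 1L, mismatch = mism,
                dist = d_um[i1] + d_um[i2])
          }
        }
      }
    }
    # case (b): continuing tracks adjacent to a single newborn
    cont <- info[info$start < f & info$end >= f &
                   !(info$track_id %in% taken), ]
    if (nrow(cont) > 0L) {
      for (e in seq_len(nrow(cont))) {
        pid <- cont$track_id[e]
        p_prev <- tr[tr$track_id == pid & tr$frame == f - 1L, ]
        p_now <- tr[tr$track_id == pid & tr$frame == f, ]
        if (nrow(p_prev) == 0L || nrow(p_now) == 0L) next
        d_um <- sqrt((born$x_start - p_prev$x_um)^2 +
                     (born$y_start - p_prev$y_um)^2)
        near <- which(d_um <= max_pair_distance_um)
        for (i1 in near) {
          mism <- abs(born$i_start[i1] + p_now$intensity - p_prev$intensity) /
            p_prev$intensity
          if (is.finite(mism) && mism <= intensity_tolerance)
            cand_events[[length(cand_events) + 1L]] <- list(
              type = "split", parent = pid, d1 = born$track_id[i1],
              d2 = NA_integer_, frame = f - 1L, mismatch = mism,
              dist = d_um[i1])
        }
      }
    }
    if (length(cand_events) == 0L) next
    # greedy best-first: smallest mismatch, ties by distance; "pair" events
    # (the literal two-newborn rule) take precedence over splits
    prio <- vapply(cand_events, function(ev)
      ev$mismatch + ifelse(ev$type == "split", 1e-9, 0), numeric(1))
    dst <- vapply(cand_events, function(ev) ev$dist, numeric(1))
    for (ei in order(prio, dst)) {
      ev <- cand_events[[ei]]
      used <- c(ev$parent, ev$d1, if (!is.na(ev$d2)) ev$d2)
      if (any(used %in% taken)) next
      if (ev$type == "split") {
        # split the continuing parent: records from frame f become daughter 2
        sel <- tr$track_id == ev$parent & tr$frame >= f
        d2_id <- next_id; next_id <- next_id + 1L
        tr$track_id[sel] <- d2_id
        tr$parent_id[sel] <- ev$parent
        ev$d2 <- d2_id
      }
      tr$parent_id[tr$track_id == ev$d1] <- ev$parent
      if (ev$type == "pair")
        tr$parent_id[tr$track_id == ev$d2] <- ev$parent
      taken <- c(taken, ev$parent, ev$d1, ev$d2)
      events[[length(events) + 1L]] <- ev
    }
  }

  tr <- tr[order(tr$track_id, tr$frame), ]
  rownames(tr) <- NULL
  class(tr) <- c("cell_tracks", "data.frame")
  attr(tr, "frame_interval_h") <- attr(tracks, "frame_interval_h")
  attr(tr, "divisions") <- if (length(events))
    data.frame(
      parent_id = vapply(events, function(e) as.integer(e$parent), 1L),
      frame = vapply(events, function(e) as.integer(e$frame), 1L),
      daughter1 = vapply(events, function(e) as.integer(e$d1), 1L),
      daughter2 = vapply(events, function(e) as.integer(e$d2), 1L))
  else data.frame(parent_id = integer(), frame = integer(),
                  daughter1 = integer(), daughter2 = integer())
  tr
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("cell_tracks: %d record(s), %d track(s), frames %s\n",
              nrow(x), length(unique(x$track_id)),
              if (nrow(x)) paste(range(x$frame), collapse = "-") else "-"))
  div <- attr(x, "divisions")
  if (!is.null(div)) cat(sprintf("  %d division(s)\n", nrow(div)))
  invisible(x)
}
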