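#' Write a label mask to disk
#'
#' The label image goes to a 16-bit TIFF and the per-label property table
#' (centroids in micrometres, areas, any measured intensities) to a CSV.
#'
#' @param mask A [label_mask()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.csv`.
#' @return `path_prefix`, invisibly.
#' @export
write_label_mask <- function(mask, path_prefix) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, paste0(path_prefix, ".tif"),
                  bits.per.sample = 16L)
  write.csv(mask$props, paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(path_prefix)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path_prefix Path prefix used at writing time.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path_prefix, pixel_size_um) {
  img <- tiff::readTIFF(paste0(path_prefix, ".tif"))
  label_mask(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)),
             pixel_size_um)
}

#' Write cell tracks to CSV
#'
#' One row per track record: `track_id`, `parent_id`, `frame`, `t_h`,
#' `x_um`, `y_um`, `label`, `intensity`.
#'
#' @param tracks A `cell_tracks` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "cell_tracks"))
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Write activity traces to CSV
#'
#' One row per track and frame: `track_id`, `frame`, `t_h`, `cdk46`,
#' `cdk2`, `degron`, `valid`, `interpolated`.
#'
#' @param traces A `trace_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV back into a trace set
#'
#' @param path CSV written by [write_traces_csv()].
#' @param frame_interval_h Frame interval (h).
#' @param treatment_time_h Treatment time used when the traces were built.
#' @return A `trace_set`.
#' @export
read_traces_csv <- function(path, frame_interval_h = 0.2,
                            treatment_time_h = 0) {
  as_trace_set(read.csv(path), frame_interval_h, treatment_time_h)
}
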