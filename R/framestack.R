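#' Multi-channel calibrated image time series
#'
#' A `frame_stack` bundles one or more image channels (each a numeric array
#' of dimension rows x cols x frames) with the spatial calibration
#' (`pixel_size_um`) and temporal calibration (`frame_interval_h`) needed by
#' every downstream step. Pixels are indexed row-major with the origin at the
#' top-left; physical coordinates are pixel centers in micrometres.
#'
#' @param channels Named list of numeric arrays, all of identical dimension
#'   `c(rows, cols, n_frames)`. Matrices are promoted to single-frame arrays.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param frame_interval_h Time between frames in hours (> 0); the default
#'   0.2 h corresponds to the 12-minute live-imaging cadence.
#' @return An object of class `frame_stack`.
#' @examples
#' img <- array(runif(32 * 32 * 2), c(32, 32, 2))
#' fs <- frame_stack(list(h2b = img), pixel_size_um = 1.3)
#' dim(get_frame(fs, "h2b", 1))
#' @export
frame_stack <- function(channels, pixel_size_um, frame_interval_h = 0.2) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.numeric(frame_interval_h) || frame_interval_h <= 0)
    stop("frame_interval_h must be > 0")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, c(dim(ch), 1L))
    stopifnot(is.array(ch), length(dim(ch)) == 3L)
    ch
  })
  d <- dim(channels[[1]])
  for (ch in channels) if (!identical(dim(ch), d))
    stop("all channels must share the same dimensions")
  structure(
    list(channels = channels,
         pixel_size_um = pixel_size_um,
         frame_interval_h = frame_interval_h,
         n_frames = d[3], rows = d[1], cols = d[2]),
    class = "frame_stack")
}

#' Extract a single frame from a channel
#'
#' @param stack A [frame_stack()].
#' @param channel Channel name.
#' @param frame Frame index (1-based).
#' @return A numeric matrix.
#' @export
get_frame <- function(stack, channel, frame) {
  stopifnot(inherits(stack, "frame_stack"))
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("no channel named '", channel, "'")
  ch[, , frame]
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d x %d px, %d frame(s), %d channel(s)\n",
              x$rows, x$cols, x$n_frames, length(x$channels)))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size %.3g um, frame interval %.3g h\n",
              x$pixel_size_um, x$frame_interval_h))
  invisible(x)
}

#' Frame times in hours
#'
#' @param stack A [frame_stack()].
#' @return Numeric vector of frame times, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(stack$n_frames) - 1) * stack$frame_interval_h
}

#' Write a frame stack to disk
#'
#' Each channel is written as one multi-page 32-bit float TIFF; calibration
#' and channel names go into a JSON sidecar (`metadata.json`) so stacks
#' round-trip losslessly with [read_frame_stack()].
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- vapply(stack$channels, function(ch) max(abs(ch), 1),
                   numeric(1))
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]] / scales[[nm]]   # TIFF floats live in [0,1]
    pages <- lapply(seq_len(dim(ch)[3]), function(i) ch[, , i])
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  meta <- list(channels = names(stack$channels),
               intensity_scale = as.list(scales),
               pixel_size_um = stack$pixel_size_um,
               frame_interval_h = stack$frame_interval_h,
               rows = stack$rows, cols = stack$cols,
               n_frames = stack$n_frames)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param dir Directory containing per-channel TIFFs and `metadata.json`.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(nm) {
    pages <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")), all = TRUE,
                            as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    sc <- meta$intensity_scale[[nm]] %||% 1
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * sc
    arr
  })
  names(channels) <- meta$channels
  frame_stack(channels, meta$pixel_size_um, meta$frame_interval_h)
}
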