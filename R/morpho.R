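#' Segment the tumor region of a whole-section image
#'
#' Otsu threshold on the tumor channel, morphological closing with a disk,
#' largest-connected-component selection, and hole filling.
#'
#' @param section_image Numeric matrix (tumor marker channel).
#' @param pixel_size_um Pixel size in micrometres.
#' @param closing_radius_um Disk radius for morphological closing.
#' @return Logical matrix (the tumor mask). An image with no foreground
#'   yields an empty mask with a warning.
#' @export
segment_tumor <- function(section_image, pixel_size_um,
                          closing_radius_um = 50) {
  stopifnot(is.matrix(section_image), pixel_size_um > 0)
  th <- otsu_threshold(section_image)
  fg <- section_image > th
  # degenerate unimodal image: threshold splits noise, demand real
  # contrast relative to the within-class spread
  within_spread <- max(mad(section_image[fg]), mad(section_image[!fg]),
                       .Machine$double.eps)
  if (!any(fg) || !any(!fg) ||
      (median(section_image[fg]) - median(section_image[!fg])) <
        4 * within_spread) {
    warning("no tumor foreground found; returning empty mask")
    return(matrix(FALSE, nrow(section_image), ncol(section_image)))
  }
  r_px <- max(1L, round(closing_radius_um / pixel_size_um))
  kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::Image(fg * 1), kern)
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  if (length(tab) == 0L) {
    warning("no tumor foreground found; returning empty mask")
    return(matrix(FALSE, nrow(section_image), ncol(section_image)))
  }
  biggest <- which.max(tab)
  m <- EBImage::Image((EBImage::imageData(lab) == biggest) * 1)
  m <- EBImage::fillHull(m)
  EBImage::imageData(m) > 0
}

#' Distance-to-margin field of a tumor mask
#'
#' Exact Euclidean distance (micrometres) from each in-mask pixel to the
#' nearest background pixel; pixels outside the mask are `NA`.
#'
#' @param mask Logical matrix (tumor mask).
#' @param pixel_size_um Pixel size in micrometres.
#' @return Numeric matrix of distances (um), `NA` outside the mask.
#' @export
margin_distance <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  if (!any(mask)) stop("mask is empty")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))) * pixel_size_um
  d[!mask] <- NA_real_
  d
}

#' Detect CD8+ cells in a stain channel
#'
#' LoG spot detection (the live-nucleus detector at lymphocyte scale)
#' restricted to a dilated neighbourhood of the tumor mask.
#'
#' @param stain_image Numeric matrix (CD8 stain channel).
#' @param mask Logical tumor mask (same shape); detections outside its
#'   dilated neighbourhood are discarded.
#' @param pixel_size_um Pixel size in micrometres.
#' @param radius_range_um Spot radius range (default 3-6 um).
#' @param detection_threshold Seed threshold in robust-SNR units.
#' @param dilate_um Neighbourhood margin around the mask.
#' @return Data frame of spot centers: `x_mm`, `y_mm`.
#' @export
detect_cd8 <- function(stain_image, mask, pixel_size_um,
                       radius_range_um = c(3, 6),
                       detection_threshold = 5, dilate_um = 50) {
  stopifnot(identical(dim(stain_image), dim(mask)))
  seeds <- log_blob_seeds(stain_image, pixel_size_um,
                          radius_range_um[1], radius_range_um[2],
                          detection_threshold)
  if (nrow(seeds) == 0L) return(data.frame(x_mm = numeric(),
                                           y_mm = numeric()))
  r_px <- max(1L, round(dilate_um / pixel_size_um))
  kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  neigh <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), kern)) > 0
  keep <- neigh[cbind(seeds$row, seeds$col)]
  seeds <- seeds[keep, , drop = FALSE]
  data.frame(x_mm = (seeds$col - 0.5) * pixel_size_um / 1000,
             y_mm = (seeds$row - 0.5) * pixel_size_um / 1000)
}

#' Periphery/core immune-cell densities of a tumor section
#'
#' Assigns each cell center to the tumor periphery (margin distance
#' `<= periphery_um`; boundary ties go to the periphery), the core
#' (`> periphery_um`), or outside the mask, and reports counts, region
#' areas (mm^2) and densities (cells/mm^2). A tumor too thin to have a
#' core yields `NaN` core density with a flag.
#'
#' @param mask Logical tumor mask.
#' @param dist_um Distance field from [margin_distance()].
#' @param centroids Data frame with `x_mm`, `y_mm` cell centers.
#' @param pixel_size_um Pixel size in micrometres.
#' @param periphery_um Periphery depth (default 500 um).
#' @return A `section_morphometry` object: `counts`, `areas_mm2`,
#'   `densities`, `cells` (per-cell table with `d_um` and `region`),
#'   `core_defined`.
#' @export
region_densities <- function(mask, dist_um, centroids, pixel_size_um,
                             periphery_um = 500) {
  stopifnot(identical(dim(mask), dim(dist_um)))
  nr <- nrow(mask); nc <- ncol(mask)
  row_i <- clamp(round(centroids$y_mm * 1000 / pixel_size_um + 0.5), 1, nr)
  col_i <- clamp(round(centroids$x_mm * 1000 / pixel_size_um + 0.5), 1, nc)
  d_cell <- dist_um[cbind(row_i, col_i)]
  region <- ifelse(is.na(d_cell), "outside",
                   ifelse(d_cell <= periphery_um, "periphery", "core"))
  cells <- data.frame(x_mm = centroids$x_mm, y_mm = centroids$y_mm,
                      d_um = d_cell, region = region,
                      stringsAsFactors = FALSE)
  px_mm2 <- (pixel_size_um / 1000)^2
  n_periph_px <- sum(dist_um <= periphery_um, na.rm = TRUE)
  n_core_px <- sum(dist_um > periphery_um, na.rm = TRUE)
  areas <- c(periphery = n_periph_px * px_mm2, core = n_core_px * px_mm2)
  counts <- c(periphery = sum(region == "periphery"),
              core = sum(region == "core"))
  densities <- c(
    periphery = if (areas["periphery"] > 0)
      counts[["periphery"]] / areas[["periphery"]] else NaN,
    core = if (areas["core"] > 0)
      counts[["core"]] / areas[["core"]] else NaN)
  structure(list(counts = counts, areas_mm2 = areas,
                 densities = densities, cells = cells,
                 periphery_um = periphery_um,
                 core_defined = areas[["core"]] > 0,
                 n_outside = sum(region == "outside")),
            class = "section_morphometry")
}

#' @export
print.section_morphometry <- function(x, ...) {
  cat(sprintf(
    "section_morphometry: periphery %d cells / %.3g mm^2 = %.3g per mm^2\n",
    x$counts[["periphery"]], x$areas_mm2[["periphery"]],
    x$densities[["periphery"]]))
  if (x$core_defined) {
    cat(sprintf("  core %d cells / %.3g mm^2 = %.3g per mm^2\n",
                x$counts[["core"]], x$areas_mm2[["core"]],
                x$densities[["core"]]))
  } else {
    cat("  core undefined (tumor thinner than the periphery depth)\n")
  }
  if (x$n_outside > 0) cat(sprintf("  %d cell(s) outside mask\n",
                                   x$n_outside))
  invisible(x)
}

#' Full tumor-section morphometry pipeline
#'
#' Convenience wrapper: [segment_tumor()] on the tumor channel,
#' [margin_distance()], [detect_cd8()] on the stain channel, then
#' [region_densities()].
#'
#' @param section A [frame_stack()] with channels `tumor` and `cd8`.
#' @param ... Passed to [region_densities()].
#' @return A `section_morphometry` object.
#' @export
analyze_section <- function(section, ...) {
  stopifnot(inherits(section, "frame_stack"))
  px <- section$pixel_size_um
  tumor <- get_frame(section, "tumor", 1)
  cd8 <- get_frame(section, "cd8", 1)
  mask <- segment_tumor(tumor, px)
  d <- margin_distance(mask, px)
  cells <- detect_cd8(cd8, mask, px)
  region_densities(mask, d, cells, px, ...)
}
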