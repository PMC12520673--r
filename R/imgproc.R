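#' Label mask with per-label properties
#'
#' Wraps an integer label image (0 = background, labels positive and
#' 4-connected) with its calibration and a per-label property table
#' (centroid in micrometres, area in um^2 and px).
#'
#' @param labels Integer matrix of labels.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) > 0L) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    nr <- nrow(labels)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    area_px <- as.integer(table(factor(lab, levels = ids)))
    x_um <- tapply((cols - 0.5) * pixel_size_um, factor(lab, levels = ids),
                   mean)
    y_um <- tapply((rows - 0.5) * pixel_size_um, factor(lab, levels = ids),
                   mean)
    props <- data.frame(label = ids, x_um = as.numeric(x_um),
                        y_um = as.numeric(y_um),
                        area_px = area_px,
                        area_um2 = area_px * pixel_size_um^2)
  } else {
    props <- data.frame(label = integer(), x_um = numeric(),
                        y_um = numeric(), area_px = integer(),
                        area_um2 = numeric())
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 props = props),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d px, %d label(s), pixel %.3g um\n",
              nrow(x$labels), ncol(x$labels), nrow(x$props),
              x$pixel_size_um))
  invisible(x)
}

#' Per-label intensity statistics
#'
#' Adds mean, median and integrated intensity of `image` within each label
#' to the mask's property table.
#'
#' @param mask A [label_mask()].
#' @param image Numeric matrix, same shape as the mask.
#' @param prefix Column-name prefix for the added statistics.
#' @return The property data frame with `<prefix>_mean`, `<prefix>_median`,
#'   `<prefix>_total` columns.
#' @export
measure_labels <- function(mask, image, prefix = "int") {
  stopifnot(inherits(mask, "label_mask"),
            identical(dim(image), dim(mask$labels)))
  props <- mask$props
  if (nrow(props) == 0L) {
    props[[paste0(prefix, "_mean")]] <- numeric()
    props[[paste0(prefix, "_median")]] <- numeric()
    props[[paste0(prefix, "_total")]] <- numeric()
    return(props)
  }
  idx <- which(mask$labels > 0L)
  f <- factor(mask$labels[idx], levels = props$label)
  v <- image[idx]
  props[[paste0(prefix, "_mean")]] <- as.numeric(tapply(v, f, mean))
  props[[paste0(prefix, "_median")]] <- as.numeric(tapply(v, f, median))
  props[[paste0(prefix, "_total")]] <- as.numeric(tapply(v, f, sum))
  props
}

# Fit a smooth low-order 2-D polynomial surface to selected pixels.
fit_poly_surface <- function(img, use, order = 2L) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- ((which(use) - 1L) %% nr) + 1L
  cols <- ((which(use) - 1L) %/% nr) + 1L
  # scale coordinates to [-1, 1] for conditioning
  ry <- 2 * (rows - 1) / (nr - 1) - 1
  rx <- 2 * (cols - 1) / (nc - 1) - 1
  dat <- data.frame(z = img[use], x = rx, y = ry)
  fml <- switch(as.character(order),
                "1" = z ~ x + y,
                "2" = z ~ x + y + I(x^2) + I(y^2) + I(x * y),
                z ~ poly(x, order) + poly(y, order) + I(x * y))
  fit <- lm(fml, data = dat)
  gy <- 2 * (seq_len(nr) - 1) / (nr - 1) - 1
  gx <- 2 * (seq_len(nc) - 1) / (nc - 1) - 1
  grid <- expand.grid(y = gy, x = gx)
  matrix(predict(fit, newdata = grid), nr, nc)
}

#' Flat-field illumination correction
#'
#' Removes smooth multiplicative illumination bias. With
#' `reference = "provided_field"` the image(s) are divided by the given
#' field after scaling its mean to 1. With `reference = "from_background"`
#' the field is estimated by fitting a low-order 2-D polynomial surface to
#' background pixels (those below a robust foreground threshold) of a
#' reference frame, per channel.
#'
#' @param x A [frame_stack()] or a numeric matrix.
#' @param reference `"from_background"` or `"provided_field"`.
#' @param field Bias field matrix (required for `"provided_field"`); must be
#'   strictly positive and match the image shape.
#' @param poly_order Polynomial order of the background surface fit.
#' @return Corrected object of the same class as `x`.
#' @examples
#' cfg <- sim_config(n_cells = 5, n_frames = 1, snr = Inf,
#'                   illumination_bias_amplitude = 0.3)
#' sim <- simulate_timelapse(cfg, "untreated")
#' corr <- flatfield_correct(sim$stack, "provided_field",
#'                           field = bias_field(cfg))
#' @export
flatfield_correct <- function(x, reference = c("from_background",
                                               "provided_field"),
                              field = NULL, poly_order = 2L) {
  reference <- match.arg(reference)
  if (inherits(x, "frame_stack")) {
    out <- x
    for (nm in names(x$channels)) {
      ch <- x$channels[[nm]]
      fld <- resolve_field(ch[, , 1], reference, field, poly_order)
      for (f in seq_len(dim(ch)[3])) out$channels[[nm]][, , f] <-
          ch[, , f] / fld
    }
    return(out)
  }
  stopifnot(is.matrix(x))
  x / resolve_field(x, reference, field, poly_order)
}

resolve_field <- function(img, reference, field, poly_order) {
  if (reference == "provided_field") {
    if (is.null(field)) stop("provided_field requires a field")
    if (!identical(dim(field), dim(img)))
      stop("field shape does not match image")
    if (any(field <= 0)) stop("field must be strictly positive")
  } else {
    th <- otsu_threshold(log(pmax(img, .Machine$double.eps)))
    bg <- img < exp(th)
    if (sum(bg) < 50L) bg <- img <= quantile(img, 0.5)
    # robust refit: discard pixels far above the fitted surface (blurred
    # object halos that survive the threshold) and fit once more
    for (iter in 1:2) {
      field <- fit_poly_surface(img, bg, poly_order)
      res <- img / pmax(field, max(field) * 1e-3)
      cut <- median(res[bg]) + 2.5 * mad(res[bg])
      bg_new <- bg & res < cut
      if (sum(bg_new) < 50L) break
      bg <- bg_new
    }
    field <- fit_poly_surface(img, bg, poly_order)
    field <- pmax(field, max(field) * 1e-3)
  }
  field / mean(field)
}

#' Segment nuclei in a fixed-cell DNA-stain image
#'
#' Global histogram-based (Otsu on log-intensity) thresholding, 4-connected
#' component labelling, area filtering, and watershed splitting (on the
#' Euclidean distance transform) of components larger than `max_area_um2`.
#'
#' @param dna_image Numeric matrix (DNA-stain channel).
#' @param pixel_size_um Pixel size in micrometres.
#' @param min_area_um2,max_area_um2 Area bounds for retained nuclei.
#' @param threshold Optional fixed intensity threshold overriding Otsu.
#' @return A [label_mask()]. A blank image yields an empty mask.
#' @export
segment_fixed <- function(dna_image, pixel_size_um,
                          min_area_um2 = 30, max_area_um2 = 800,
                          threshold = NULL) {
  stopifnot(is.matrix(dna_image), pixel_size_um > 0)
  if (is.null(threshold)) {
    lth <- otsu_threshold(log(pmax(dna_image, .Machine$double.eps)))
    threshold <- exp(lth)
  }
  fg <- dna_image > threshold
  if (!any(fg)) return(label_mask(matrix(0L, nrow(dna_image),
                                         ncol(dna_image)), pixel_size_um))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  max_px <- max_area_um2 / pixel_size_um^2
  min_px <- min_area_um2 / pixel_size_um^2
  areas <- tabulate(lab[lab > 0])
  # split oversized components by watershed on the distance transform
  for (id in which(areas > max_px)) {
    comp <- lab == id
    d <- EBImage::distmap(EBImage::Image(comp * 1))
    w <- EBImage::watershed(d, tolerance = 1)
    wm <- EBImage::imageData(w)
    base <- max(lab)
    sub <- wm > 0 & comp
    lab[sub] <- base + wm[sub]
    lab[comp & wm == 0] <- 0L
  }
  # relabel sequentially, dropping out-of-bounds areas
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_px & areas <= max_px * 1.000001)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  label_mask(out, pixel_size_um)
}

#' Segment nuclei in a live-cell H2B image by LoG blob detection
#'
#' Multi-scale Laplacian-of-Gaussian detection: 8 log-spaced sigmas span
#' `radius_range_um / sqrt(2)`; scale-normalized response maxima above
#' `detection_threshold` (in robust-SNR units: multiples of the MAD of the
#' image, so detections are invariant to rescaling the image by a positive
#' constant) become seeds; seeds closer than `rmin` are merged into the
#' brighter one; each seed grows into a mask by local Otsu thresholding in
#' a window of side `4 * rmax`, restricted to `2 * rmax` around the seed,
#' with contested pixels going to the nearer seed (ties to the lower id).
#'
#' @param h2b_image Numeric matrix.
#' @param pixel_size_um Pixel size in micrometres.
#' @param radius_range_um Expected nuclear radius range `c(rmin, rmax)`.
#' @param detection_threshold Seed threshold in robust-SNR units.
#' @return A [label_mask()].
#' @export
segment_live <- function(h2b_image, pixel_size_um,
                         radius_range_um = c(5, 12),
                         detection_threshold = 5) {
  stopifnot(is.matrix(h2b_image), pixel_size_um > 0)
  rmin <- radius_range_um[1]; rmax <- radius_range_um[2]
  if (rmin <= 0 || rmin >= rmax)
    stop("radius_range_um must satisfy 0 < rmin < rmax")
  seeds <- log_blob_seeds(h2b_image, pixel_size_um, rmin, rmax,
                          detection_threshold)
  if (nrow(seeds) == 0L)
    return(label_mask(matrix(0L, nrow(h2b_image), ncol(h2b_image)),
                      pixel_size_um))
  grow_seeds(h2b_image, seeds, pixel_size_um, rmax)
}

# Multi-scale LoG seed detection shared by segment_live and detect_cd8.
log_blob_seeds <- function(img, pixel_size_um, rmin, rmax, threshold,
                           n_scales = 8L) {
  sig_um <- exp(seq(log(rmin / sqrt(2)), log(rmax / sqrt(2)),
                    length.out = n_scales))
  sig_px <- sig_um / pixel_size_um
  robust_sd <- mad(img)
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  best <- matrix(-Inf, nrow(img), ncol(img))
  best_s <- matrix(0L, nrow(img), ncol(img))
  for (si in seq_along(sig_px)) {
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sig_px[si]))
    resp <- -sig_px[si]^2 *
      EBImage::imageData(EBImage::filter2(EBImage::Image(sm), lap_kernel))
    upd <- resp > best
    best[upd] <- resp[upd]
    best_s[upd] <- si
  }
  mx <- local_maxima(best)
  if (nrow(mx) == 0L)
    return(data.frame(row = integer(), col = integer(), sigma_um = numeric(),
                      response = numeric()))
  resp <- best[mx]
  keep <- resp > threshold * robust_sd & resp > 0.02 * max(resp)
  mx <- mx[keep, , drop = FALSE]; resp <- resp[keep]
  if (nrow(mx) == 0L)
    return(data.frame(row = integer(), col = integer(), sigma_um = numeric(),
                      response = numeric()))
  seeds <- data.frame(row = mx[, 1], col = mx[, 2],
                      sigma_um = sig_um[best_s[mx]], response = resp)
  # merge seeds closer than rmin, keeping the brighter one
  seeds <- seeds[order(-seeds$response), ]
  keep <- rep(TRUE, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    if (!keep[i]) next
    if (i < nrow(seeds)) {
      later <- (i + 1):nrow(seeds)
      d_um <- sqrt((seeds$row[later] - seeds$row[i])^2 +
                   (seeds$col[later] - seeds$col[i])^2) * pixel_size_um
      keep[later][d_um < rmin] <- FALSE
    }
  }
  seeds <- seeds[keep, , drop = FALSE]
  # deterministic ordering: top-left to bottom-right
  seeds <- seeds[order(seeds$col, seeds$row), ]
  rownames(seeds) <- NULL
  seeds
}

# Grow each seed into a nuclear mask by local Otsu; contested pixels go to
# the nearer seed (ties to the lower label id).
grow_seeds <- function(img, seeds, pixel_size_um, rmax_um) {
  nr <- nrow(img); nc <- ncol(img)
  rmax_px <- rmax_um / pixel_size_um
  half <- ceiling(2 * rmax_px)
  lab <- matrix(0L, nr, nc)
  claim_d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(seeds))) {
    r0 <- seeds$row[i]; c0 <- seeds$col[i]
    rows <- max(1L, r0 - half):min(nr, r0 + half)
    cols <- max(1L, c0 - half):min(nc, c0 + half)
    win <- img[rows, cols]
    th <- otsu_threshold(win)
    d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
    cand <- win > th & d2 <= rmax_px^2
    if (!any(cand)) {
      cand <- d2 <= max(1, (seeds$sigma_um[i] / pixel_size_um))^2
    } else {
      # keep only the connected component containing the seed
      cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
      seed_lab <- cc[match(r0, rows), match(c0, cols)]
      if (is.na(seed_lab) || seed_lab == 0) {
        nearest <- which(cand & d2 == min(d2[cand]))[1]
        seed_lab <- cc[nearest]
      }
      cand <- cc == seed_lab
    }
    d <- sqrt(d2)
    take <- cand & (d < claim_d[rows, cols] |
                    (d == claim_d[rows, cols] &
                       lab[rows, cols] > i & lab[rows, cols] > 0L))
    sub_lab <- lab[rows, cols]
    sub_d <- claim_d[rows, cols]
    sub_lab[take] <- i
    sub_d[take] <- d[take]
    lab[rows, cols] <- sub_lab
    claim_d[rows, cols] <- sub_d
  }
  label_mask(lab, pixel_size_um)
}
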