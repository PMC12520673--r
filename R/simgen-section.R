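#' Simulate a tumor section with CD8 point pattern
#'
#' Builds a smooth star-convex tumor mask strictly inside the field, places
#' `n_cd8` CD8+ cell centers inside the tumor with a configurable
#' periphery-to-core density ratio, and renders a two-channel image (tumor
#' marker + CD8 stain spots). The periphery is the in-tumor band within
#' `periphery_um` (default 500 um) of the tumor margin; the core is
#' everything deeper. `periphery_enrichment = 1` gives uniform placement;
#' `Inf` puts all cells in the periphery.
#'
#' @param field_mm Field size `c(width, height)` in millimetres.
#' @param pixel_size_um Pixel size of the rendered section image.
#' @param tumor_radius_mm Mean tumor radius.
#' @param boundary_amplitude Relative amplitude of the low-order radial
#'   perturbation of the tumor boundary (0 = circle).
#' @param n_cd8 Number of CD8 cells to place.
#' @param periphery_enrichment Periphery:core density ratio (>= 0; may be
#'   `Inf`).
#' @param periphery_um Periphery depth in micrometres.
#' @param snr Image SNR (Inf = noiseless).
#' @param rng_seed Seed (controls shape and placement).
#' @return List with `image` (a [frame_stack()] with channels `tumor`,
#'   `cd8`), `mask` (true binary tumor mask), and `truth` (data frame of
#'   CD8 centers `x_mm`, `y_mm`, `d_um` distance to margin, `region`).
#' @examples
#' sec <- simulate_section(field_mm = c(2, 2), n_cd8 = 50,
#'                         periphery_enrichment = 3, rng_seed = 2)
#' table(sec$truth$region)
#' @export
simulate_section <- function(field_mm = c(3, 3), pixel_size_um = 5,
                             tumor_radius_mm = 1.0,
                             boundary_amplitude = 0.08,
                             n_cd8 = 500L,
                             periphery_enrichment = 1,
                             periphery_um = 500,
                             snr = 20, rng_seed = 1L) {
  if (periphery_enrichment < 0) stop("periphery_enrichment must be >= 0")
  nr <- round(field_mm[2] * 1000 / pixel_size_um)
  nc <- round(field_mm[1] * 1000 / pixel_size_um)
  with_seed(rng_seed, {
    # star-convex boundary: R(theta) = R0 (1 + sum_k a_k cos(k theta + phi_k))
    k <- 2:5
    amp <- if (boundary_amplitude > 0)
      rnorm(length(k), 0, boundary_amplitude / 2) else rep(0, length(k))
    phi <- runif(length(k), 0, 2 * pi)
    r0_px <- tumor_radius_mm * 1000 / pixel_size_um
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dy <- rows - cy; dx <- cols - cx
    theta <- atan2(dy, dx)
    rad <- sqrt(dx^2 + dy^2)
    rb <- r0_px * (1 + Reduce(`+`, lapply(seq_along(k), function(i)
      amp[i] * cos(k[i] * theta + phi[i]))))
    max_rb <- max(rb)
    lim <- min(nr, nc) / 2 - 2
    if (max_rb >= lim)
      rb <- rb * (lim / max_rb)          # keep the mask strictly inside
    mask <- rad <= rb

    # exact distance-to-margin field of the true mask
    d_um <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))) *
      pixel_size_um
    in_mask <- which(mask)
    if (n_cd8 > length(in_mask))
      stop("n_cd8 exceeds the placeable tumor area")
    periph <- d_um[in_mask] <= periphery_um
    w <- if (is.infinite(periphery_enrichment)) as.numeric(periph)
         else ifelse(periph, periphery_enrichment, 1)
    if (all(w == 0)) stop("no placeable pixels with positive weight")
    picks <- sample(in_mask, n_cd8, replace = TRUE, prob = w)
    pr <- ((picks - 1) %% nr) + 1
    pc <- ((picks - 1) %/% nr) + 1
    # jitter within the pixel
    y_px <- pr - 0.5 + runif(n_cd8, -0.5, 0.5)
    x_px <- pc - 0.5 + runif(n_cd8, -0.5, 0.5)
    d_cell <- d_um[picks]
    truth <- data.frame(
      x_mm = x_px * pixel_size_um / 1000,
      y_mm = y_px * pixel_size_um / 1000,
      d_um = d_cell,
      region = ifelse(d_cell <= periphery_um, "periphery", "core"),
      stringsAsFactors = FALSE)

    # render: tumor channel = mask plateau, cd8 channel = Gaussian spots
    tumor_img <- 10 + 90 * mask
    tumor_img <- EBImage::imageData(EBImage::gblur(EBImage::Image(tumor_img),
                                          sigma = 2))
    cd8_img <- matrix(0, nr, nc)
    spot_sigma_px <- 4 / pixel_size_um + 0.6
    half <- ceiling(3 * spot_sigma_px)
    for (i in seq_len(n_cd8)) {
      rr <- max(1L, round(y_px[i]) - half):min(nr, round(y_px[i]) + half)
      cc <- max(1L, round(x_px[i]) - half):min(nc, round(x_px[i]) + half)
      g <- exp(-(outer((rr - 0.5 - y_px[i])^2, (cc - 0.5 - x_px[i])^2,
                       "+")) / (2 * spot_sigma_px^2))
      cd8_img[rr, cc] <- cd8_img[rr, cc] + 150 * g
    }
    cd8_img <- cd8_img + 10
    if (is.finite(snr)) {
      gain <- snr^2 / 100
      tumor_img <- matrix(rpois(length(tumor_img),
                                pmax(tumor_img, 0) * gain) / gain, nr, nc)
      cd8_img <- matrix(rpois(length(cd8_img),
                              pmax(cd8_img, 0) * gain) / gain, nr, nc)
    }
    img <- frame_stack(list(tumor = tumor_img, cd8 = cd8_img),
                       pixel_size_um = pixel_size_um)
    list(image = img, mask = mask, truth = truth,
         periphery_um = periphery_um)
  })
}
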