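# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Longest supra-threshold run by explicit window enumeration: for every
# start index, extend while every frame stays above threshold.
oracle_persister_run <- function(t_h, cdk2, valid = NULL, threshold = 1,
                                 window_h = c(30, 48), dt = 0.2) {
  if (is.null(valid)) valid <- rep(TRUE, length(t_h))
  keep <- t_h >= window_h[1] & t_h <= window_h[2]
  x <- cdk2[keep]; v <- valid[keep] & is.finite(cdk2[keep])
  n <- length(x)
  best <- 0L
  for (i in seq_len(n)) {
    j <- i
    while (j <= n && v[j] && x[j] > threshold) j <- j + 1L
    if (j - i > best) best <- j - i
  }
  if (best == 0L) 0 else (best - 1L) * dt
}

# Per-pixel C/N classification: distance of every pixel to every label by
# direct minimization over label pixels.
oracle_cn_ratio <- function(img, labels, pixel_size_um, ring_inner_um = 2,
                            ring_outer_um = 10, min_ring_px = 30,
                            nucleus_erode_px = 2) {
  ids <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels); nc <- ncol(labels)
  coords <- lapply(ids, function(id) which(labels == id, arr.ind = TRUE))
  D <- array(NA_real_, c(nr, nc, length(ids)))
  for (k in seq_along(ids)) {
    w <- coords[[k]]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      D[i, j, k] <- sqrt(min((w[, 1] - i)^2 + (w[, 2] - j)^2)) *
        pixel_size_um
    }
  }
  out <- data.frame(label = ids, ratio = NA_real_, valid = FALSE)
  for (k in seq_along(ids)) {
    nuc_val <- c()
    cyto_val <- c()
    non <- which(labels != ids[k], arr.ind = TRUE)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      dk <- D[i, j, k]
      others <- D[i, j, -k]
      if (labels[i, j] == ids[k]) {
        # nuclear pixel; erosion by distance to nearest non-label pixel
        if (nucleus_erode_px > 0) {
          din <- sqrt(min((non[, 1] - i)^2 + (non[, 2] - j)^2))
          if (din > nucleus_erode_px) nuc_val <- c(nuc_val, img[i, j])
        } else nuc_val <- c(nuc_val, img[i, j])
      } else if (dk >= ring_inner_um && dk <= ring_outer_um) {
        near_other <- length(others) > 0 && any(others < ring_inner_um)
        contested <- length(others) > 0 &&
          any(others >= ring_inner_um & others <= ring_outer_um)
        if (!near_other && !contested) cyto_val <- c(cyto_val, img[i, j])
      }
    }
    # fall back to the full mask when erosion leaves too few pixels
    if (length(nuc_val) < 9) {
      sel <- labels == ids[k]
      nuc_val <- img[sel]
    }
    if (length(cyto_val) >= min_ring_px && median(nuc_val) != 0) {
      out$ratio[k] <- median(cyto_val) / median(nuc_val)
      out$valid[k] <- TRUE
    }
  }
  out
}

# Exact distance transform by all-pairs minimum.
oracle_distance <- function(mask, pixel_size_um) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j]) {
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) *
        pixel_size_um
    }
  }
  out
}

# Random multi-disk label fixture on a small grid (disks may touch the
# ring-exclusion zones of each other but nuclei stay disjoint).
random_disk_labels <- function(n_disks, size = 64, r_px = 5,
                               pixel_size_um = 1.5, min_sep_px = NULL) {
  if (is.null(min_sep_px)) min_sep_px <- 2 * r_px + 2
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n_disks && tries < 2000) {
    tries <- tries + 1
    cand <- runif(2, r_px + 2, size - r_px - 1)
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >=
            min_sep_px)) {
      centers <- rbind(centers, cand)
    }
  }
  labels <- matrix(0L, size, size)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(size) - centers[k, 1])^2,
                (seq_len(size) - centers[k, 2])^2, "+")
    labels[d2 <= r_px^2] <- k
  }
  list(labels = labels, centers = centers, pixel_size_um = pixel_size_um)
}
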