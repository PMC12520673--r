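# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation functions are pure with respect to the global RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Otsu threshold on a numeric vector (maximizing between-class variance over
# a fixed-bin histogram). Returns a threshold on the same scale as x.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                           n_bins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mtot * w1[valid] - n * m1[valid])^2 / (w1[valid] * w2[valid])
  breaks[which.max(between) + 1L]
}

# Pixel-center coordinate grids (um) for an nr x nc image; x runs along
# columns, y along rows, origin at the top-left pixel corner.
pixel_centers_um <- function(nr, nc, pixel_size_um) {
  list(
    x = (seq_len(nc) - 0.5) * pixel_size_um,
    y = (seq_len(nr) - 0.5) * pixel_size_um
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 3x3-neighbourhood local maxima of a matrix (strictly greater than or equal
# to neighbours and strictly greater than at least one; plateaus keep the
# first pixel in column-major order). Returns an index matrix (row, col).
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(matrix(integer(), 0L, 2L))
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dcol in -1:1) {
    if (dr == 0L && dcol == 0L) next
    shifted <- matrix(-Inf, nr, nc)
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dcol):min(nc, nc - dcol)
    shifted[r_src + dr, c_src + dcol] <- m[r_src, c_src]
    # >= against shifts that come earlier in column-major order, > otherwise,
    # so a flat plateau yields exactly one maximum.
    if (dcol < 0L || (dcol == 0L && dr < 0L)) {
      ok <- ok & (m >= shifted)
    } else {
      ok <- ok & (m > shifted)
    }
  }
  ok[c(1L, nr), ] <- FALSE
  ok[, c(1L, nc)] <- FALSE
  which(ok, arr.ind = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
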