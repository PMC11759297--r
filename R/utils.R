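# Internal numeric helpers shared across modules.

#' Round a positive value to the nearest odd integer
#'
#' Ties between the two surrounding odd integers are broken toward the
#' smaller one, so a value exactly midway (e.g. 42.5 between 41 and 43, or
#' 170 between 169 and 171) maps to the smaller odd size.
#'
#' @param x positive numeric vector.
#' @return integer vector of odd values >= 1.
#' @export
round_to_odd <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  lower <- 2L * as.integer(floor((x - 1) / 2)) + 1L
  lower <- pmax(lower, 1L)
  upper <- lower + 2L
  # ties (x equidistant) go to the smaller odd value
  ifelse((x - lower) <= (upper - x), lower, upper)
}

# fftshift for matrices: move the zero-frequency / zero-lag element (at
# [1, 1]) to the centre.  For odd n the centre index is (n+1)/2.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- ceiling(nr / 2); sc <- ceiling(nc / 2)
  m[c((sr + 1):nr, seq_len(sr)), c((sc + 1):nc, seq_len(sc)), drop = FALSE]
}

# DFT sample frequencies in cycles per sample (same layout as the output
# of stats::fft): 0, 1/n, ..., then negative frequencies.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Separable Gaussian convolution with replicate-edge padding.  Implemented
# as two dense matrix products on a padded image so boundary behaviour is
# exact and under our control.
gauss_kernel_1d <- function(sigma = NULL, kernel_px = NULL) {
  if (is.null(sigma)) {
    # common discrete convention for a k-pixel Gaussian kernel
    stopifnot(kernel_px >= 1)
    if (kernel_px == 1) return(1)
    sigma <- 0.3 * ((kernel_px - 1) * 0.5 - 1) + 0.8
  }
  if (is.null(kernel_px)) kernel_px <- 2L * ceiling(3 * sigma) + 1L
  half <- (kernel_px - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_blur <- function(img, sigma = NULL, kernel_px = NULL) {
  k <- gauss_kernel_1d(sigma, kernel_px)
  if (length(k) == 1) return(img)
  conv_sep(img, k)
}

# Convolve image with a separable symmetric 1D kernel along both axes,
# replicate padding, output same size.
conv_sep <- function(img, k) {
  half <- (length(k) - 1) / 2
  pad_idx <- function(n) c(rep(1L, half), seq_len(n), rep(n, half))
  # rows direction (filter down columns)
  A <- img[pad_idx(nrow(img)), , drop = FALSE]
  K1 <- conv_band_matrix(nrow(img), length(k), k)
  tmp <- K1 %*% A
  B <- tmp[, pad_idx(ncol(img)), drop = FALSE]
  K2 <- conv_band_matrix(ncol(img), length(k), k)
  out <- B %*% Matrix::t(K2)
  unname(as.matrix(out))
}

# n x (n + klen - 1) banded matrix whose i-th row holds the kernel aligned
# with output sample i of a padded signal.
conv_band_matrix <- function(n, klen, k) {
  i <- rep(seq_len(n), each = klen)
  j <- as.vector(outer(seq_len(klen), seq_len(n) - 1L, `+`))
  Matrix::sparseMatrix(i = i, j = j, x = rep(rev(k), n),
                       dims = c(n, n + klen - 1L))
}

# Bilinear resize of a matrix to new dimensions (used to bring smoothed
# height grids back to pixel resolution).
resize_bilinear <- function(m, nrow_out, ncol_out) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- if (nrow_out == 1) 1 else seq(1, nr, length.out = nrow_out)
  ci <- if (ncol_out == 1) 1 else seq(1, nc, length.out = ncol_out)
  r0 <- pmin(floor(ri), nr - 1L); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); c1 <- c0 + 1; fc <- ci - c0
  if (nr == 1) { r0 <- r1 <- rep(1, nrow_out); fr <- rep(0, nrow_out) }
  if (nc == 1) { c0 <- c1 <- rep(1, ncol_out); fc <- rep(0, ncol_out) }
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc)
  d <- m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  e <- m[r1, c1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

# Bilinear interpolation of a matrix at explicit (possibly fractional)
# source coordinates, clamped to the grid.
interp_grid <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); fc <- ci - c0
  if (nr == 1) { r0 <- rep(1, length(ri)); fr <- rep(0, length(ri)) }
  if (nc == 1) { c0 <- rep(1, length(ci)); fc <- rep(0, length(ci)) }
  m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[pmin(r0 + 1, nr), c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, pmin(c0 + 1, nc), drop = FALSE] * outer(1 - fr, fc) +
    m[pmin(r0 + 1, nr), pmin(c0 + 1, nc), drop = FALSE] * outer(fr, fc)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
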