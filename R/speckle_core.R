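# Speckle-illumination modulation measurement: sliding-window
# autocorrelation (Wiener-Khinchin route), radial PSD, and the AC/DC
# modulation maps that feed reflectance calibration.

#' Intensity image with physical pixel size
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size object-space pixel pitch (mm).
#' @param bit_depth source quantization (informational).
#' @return an `image_grid` object.
#' @export
image_grid <- function(pixels, pixel_size, bit_depth = NA_integer_) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  stop_if_not_positive(pixel_size, "pixel_size")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 bit_depth = bit_depth),
            class = "image_grid")
}

#' Sliding-window configuration
#'
#' The window size and object pixel size set the spatial frequency
#' resolution `delta_f = 1 / (window_px * pixel_size)`; the instrument
#' defaults (85 px window at 58 um object pixels) give 0.2 mm^-1.
#' Even `window_px` requests are rounded up to the next odd value.
#'
#' @param window_px sliding window side (px); odd, rounded up if even.
#' @param step_px window step (px).
#' @param pixel_size object pixel size (mm).
#' @param ac_bin_centers AC band PSD bin centers (mm^-1).
#' @param smoothing_kernel_px Gaussian prefilter kernel size (px, odd).
#' @return a `sliding_window_config` object (includes derived `delta_f`).
#' @export
sliding_window_config <- function(window_px = 85L, step_px = 5L,
                                  pixel_size = 0.058,
                                  ac_bin_centers = c(0.2, 0.4),
                                  smoothing_kernel_px = 3L) {
  stopifnot(window_px >= 3, step_px >= 1)
  stop_if_not_positive(pixel_size, "pixel_size")
  window_px <- as.integer(window_px)
  if (window_px %% 2L == 0L) window_px <- window_px + 1L
  delta_f <- 1 / (window_px * pixel_size)
  structure(list(window_px = window_px, step_px = as.integer(step_px),
                 pixel_size = pixel_size, delta_f = delta_f,
                 ac_bin_centers = ac_bin_centers,
                 smoothing_kernel_px = as.integer(smoothing_kernel_px)),
            class = "sliding_window_config")
}

#' Gaussian prefilter for speckle images
#'
#' Suppresses ~1 px subjective speckle while preserving the larger
#' objective speckle grain that carries the optical-property signal.
#'
#' @param image an [image_grid()].
#' @param kernel_px odd kernel size in pixels (default 3).
#' @return filtered `image_grid`.
#' @export
preprocess_speckle <- function(image, kernel_px = 3L) {
  stopifnot(inherits(image, "image_grid"))
  if (kernel_px < 1 || kernel_px %% 2 == 0) {
    stop("'kernel_px' must be odd and >= 1")
  }
  if (kernel_px == 1) return(image)
  image$pixels <- gauss_blur(image$pixels, kernel_px = kernel_px)
  image
}

#' Linear autocorrelation of a zero-meaned window
#'
#' Subtracts `local_dc`, zero-pads to (2w - 1) and computes the linear
#' (non-circular) autocorrelation by the Wiener-Khinchin route
#' `ifft(|fft(v)|^2)`, shifted so zero lag sits at the center element.
#' The zero-lag value equals the window's total squared deviation.
#' Set `circular = TRUE` for the unpadded (circular) variant.
#'
#' @param window square numeric matrix.
#' @param local_dc scalar DC level to subtract (> 0).
#' @param circular if TRUE, skip zero-padding.
#' @return centered autocorrelation matrix, (2w-1) x (2w-1) (or w x w when
#'   circular), with attribute `all_zero` flagging degenerate windows.
#' @export
window_acf <- function(window, local_dc, circular = FALSE) {
  stopifnot(is.matrix(window), nrow(window) == ncol(window))
  stop_if_not_positive(local_dc, "local_dc")
  v <- window - local_dc
  all_zero <- all(abs(v) < .Machine$double.eps * max(1, abs(local_dc)))
  out <- acf_fft(v, circular = circular)
  attr(out, "all_zero") <- all_zero
  out
}

# Wiener-Khinchin autocorrelation of an already zero-meaned patch.
acf_fft <- function(v, circular = FALSE) {
  w <- nrow(v)
  if (circular) {
    V <- stats::fft(v)
    acf <- Re(stats::fft(V * Conj(V), inverse = TRUE)) / length(v)
  } else {
    np <- 2L * w - 1L
    vp <- matrix(0, np, np)
    vp[seq_len(w), seq_len(w)] <- v
    V <- stats::fft(vp)
    acf <- Re(stats::fft(V * Conj(V), inverse = TRUE)) / length(vp)
  }
  fftshift2(acf)
}

# Remove the least-squares plane a*x + b*y + c from a square patch.
# On centred unit coordinate grids the normal equations are diagonal.
detrend_plane <- function(w) {
  n <- nrow(w)
  x <- col(w) - (n + 1) / 2
  y <- row(w) - (n + 1) / 2
  sxx <- sum(x * x)
  a <- sum(w * x) / sxx
  b <- sum(w * y) / sxx
  w - mean(w) - a * x - b * y
}

#' Radially averaged autocorrelation profile
#'
#' Bins the centered 2D autocorrelation by integer-rounded lag radius and
#' averages within each bin.
#'
#' @param acf centered autocorrelation matrix (odd dimensions).
#' @param pixel_size object pixel size (mm) carried on the radius axis.
#' @param fractional if TRUE, split each lag between the two neighbouring
#'   integer radii by linear weights instead of rounding.
#' @return list with `r_px` (0, 1, 2, ... lags), `values`, `pixel_size`.
#' @export
radial_average <- function(acf, pixel_size, fractional = FALSE) {
  stopifnot(is.matrix(acf), nrow(acf) %% 2 == 1, ncol(acf) %% 2 == 1)
  cy <- (nrow(acf) + 1) / 2; cx <- (ncol(acf) + 1) / 2
  dy <- row(acf) - cy; dx <- col(acf) - cx
  r <- sqrt(dx^2 + dy^2)
  if (!fractional) {
    ri <- as.integer(round(r))
    sums <- tapply(as.vector(acf), ri, sum)
    cnts <- tapply(rep(1, length(ri)), ri, sum)
    vals <- as.numeric(sums / cnts)
    r_px <- as.integer(names(sums))
  } else {
    r0 <- floor(r); f <- r - r0
    rmax <- as.integer(max(ceiling(r)))
    sums <- numeric(rmax + 1L); cnts <- numeric(rmax + 1L)
    add <- function(idx, wgt) {
      s <- tapply(as.vector(acf) * wgt, idx, sum)
      c0 <- tapply(wgt, idx, sum)
      ii <- as.integer(names(s)) + 1L
      sums[ii] <<- sums[ii] + as.numeric(s)
      cnts[ii] <<- cnts[ii] + as.numeric(c0)
    }
    add(as.integer(r0), as.vector(1 - f))
    add(as.integer(r0 + 1), as.vector(f))
    keep <- cnts > 0
    vals <- sums[keep] / cnts[keep]
    r_px <- (seq_len(rmax + 1L) - 1L)[keep]
  }
  list(r_px = r_px, values = vals, pixel_size = pixel_size)
}

#' Radial power spectral density from a radial ACF profile
#'
#' Extends the radial profile symmetrically, takes the magnitude of its
#' discrete Fourier transform, and aggregates the transform samples into
#' bins of width `delta_f` centered at 0, `delta_f`, `2 delta_f`, ...;
#' bin k spans `f_k - delta_f/2` to `f_k + delta_f/2`.
#'
#' @param profile output of [radial_average()].
#' @param delta_f spatial frequency resolution (mm^-1).
#' @return a `psd_curve` object: list with `kr` (bin centers, mm^-1) and
#'   `values` (non-negative magnitudes summed per bin).
#' @export
psd_from_radial_acf <- function(profile, delta_f) {
  stopifnot(is.list(profile), all(is.finite(profile$values)))
  stop_if_not_positive(delta_f, "delta_f")
  p <- profile$values
  L <- length(p)
  g <- c(p, rev(p[-1]))             # even symmetric extension, length 2L-1
  spec <- abs(stats::fft(g))
  nfft <- length(g)
  f <- fft_freq(nfft, d = profile$pixel_size)
  pos <- which(f >= 0)
  bins <- as.integer(round(f[pos] / delta_f))
  sums <- tapply(spec[pos], bins, sum)
  structure(list(kr = as.integer(names(sums)) * delta_f,
                 values = as.numeric(sums), delta_f = delta_f),
            class = "psd_curve")
}

#' AC modulation band power from a PSD curve
#'
#' Sums the PSD values at the requested bin centers.  With the defaults
#' (bins centered at 0.2 and 0.4 mm^-1, `delta_f` = 0.2 mm^-1) the band
#' covers 0.1 to 0.5 mm^-1.
#'
#' @param psd a `psd_curve`.
#' @param ac_bin_centers requested bin centers (mm^-1).
#' @return scalar band power (quadratic in the sample response).
#' @export
mac_from_psd <- function(psd, ac_bin_centers = c(0.2, 0.4)) {
  stopifnot(inherits(psd, "psd_curve"))
  idx <- vapply(ac_bin_centers, function(fc) {
    i <- which(abs(psd$kr - fc) < psd$delta_f / 4)
    if (!length(i)) stop(sprintf("no PSD bin at %.3g mm^-1", fc))
    i[1]
  }, integer(1))
  sum(psd$values[idx])
}

#' DC modulation from the speckle-reduced image
#'
#' Mean intensity of a window of the planar-illumination (speckle-reduced)
#' image.
#'
#' @param dc_image an [image_grid()].
#' @param window_px window side (px).
#' @param center integer c(row, col) of the window center.
#' @return scalar mean intensity.
#' @export
mdc_from_image <- function(dc_image, window_px, center) {
  stopifnot(inherits(dc_image, "image_grid"))
  h <- (window_px - 1) %/% 2
  r <- center[1]; c <- center[2]
  if (r - h < 1 || c - h < 1 || r + h > nrow(dc_image$pixels) ||
      c + h > ncol(dc_image$pixels)) {
    stop("window exceeds image bounds")
  }
  mean(dc_image$pixels[(r - h):(r + h), (c - h):(c + h)])
}

#' Per-pixel AC/DC modulation maps
#'
#' Slides a window over the co-registered AC (speckle) and DC
#' (speckle-reduced) images.  At each placement: the DC modulation is the
#' window mean of the speckle-reduced image; the AC window is detrended
#' by its least-squares plane (the constant term is the local DC level,
#' equal to the DC modulation up to speckle sampling noise when both
#' images share one exposure; the linear terms remove the illumination
#' gradient that height and angle shading impose across the window, whose
#' leakage would otherwise contaminate the lowest AC bin) and
#' autocorrelated; the radially averaged ACF is transformed to a radial
#' PSD; the AC band power is summed over the configured bins.  The AC
#' modulation is reported on the amplitude scale, `m_ac = sqrt(band
#' power)`, so that the linear reference calibration `Rd = (m/m_ref)
#' Rd_ref_pred` maps it onto model reflectance (the PSD is quadratic in
#' the sample's frequency response).
#'
#' When `window_px_map` is supplied (height-varying scenes), each
#' placement uses its local window size, and the local object pixel size
#' is scaled by `cfg$window_px / local_window_px` so the object-space
#' frequency resolution stays fixed.  Placements whose window exceeds the
#' image bounds are masked.
#'
#' @param ac_image,dc_image co-registered [image_grid()] inputs.
#' @param cfg a [sliding_window_config()].
#' @param window_px_map optional full-resolution matrix of per-pixel
#'   window sizes (px); values are rounded to odd.
#' @param preprocess if TRUE (default) apply the Gaussian prefilter of
#'   size `cfg$smoothing_kernel_px` to the AC image.
#' @return a `modulation_maps` object: matrices `m_ac`, `m_dc`, logical
#'   `mask` (TRUE = invalid), integer vectors `rows`, `cols` of window
#'   centers in source pixels, and the config.
#' @export
modulation_maps <- function(ac_image, dc_image, cfg,
                            window_px_map = NULL, preprocess = TRUE) {
  stopifnot(inherits(ac_image, "image_grid"), inherits(dc_image, "image_grid"))
  if (!all(dim(ac_image$pixels) == dim(dc_image$pixels))) {
    stop("AC and DC images must have the same shape")
  }
  if (preprocess && cfg$smoothing_kernel_px > 1) {
    ac_image <- preprocess_speckle(ac_image, cfg$smoothing_kernel_px)
    dc_image <- preprocess_speckle(dc_image, cfg$smoothing_kernel_px)
  }
  H <- nrow(ac_image$pixels); W <- ncol(ac_image$pixels)
  w0 <- cfg$window_px
  h0 <- (w0 - 1L) %/% 2L
  rows <- seq(h0 + 1L, H - h0, by = cfg$step_px)
  cols <- seq(h0 + 1L, W - h0, by = cfg$step_px)
  m_ac <- matrix(NA_real_, length(rows), length(cols))
  m_dc <- matrix(NA_real_, length(rows), length(cols))
  mask <- matrix(TRUE, length(rows), length(cols))
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      r <- rows[ri]; c <- cols[ci]
      wp <- w0
      px <- cfg$pixel_size
      if (!is.null(window_px_map)) {
        wp <- round_to_odd(window_px_map[r, c])
        px <- cfg$pixel_size * w0 / wp   # local object pixel size
      }
      h <- (wp - 1L) %/% 2L
      if (r - h < 1 || c - h < 1 || r + h > H || c + h > W) next
      ac_win <- ac_image$pixels[(r - h):(r + h), (c - h):(c + h)]
      dc_win <- dc_image$pixels[(r - h):(r + h), (c - h):(c + h)]
      mdc <- mean(dc_win)
      if (mdc <= 0) next
      # degree-1 detrend: keeps offset and shading-gradient leakage out
      # of the AC bins
      acf <- acf_fft(detrend_plane(ac_win))
      prof <- radial_average(acf, px)
      psd <- psd_from_radial_acf(prof, 1 / (wp * px))
      mac_power <- mac_from_psd(psd, cfg$ac_bin_centers)
      m_ac[ri, ci] <- sqrt(mac_power)
      m_dc[ri, ci] <- mdc
      mask[ri, ci] <- FALSE
    }
  }
  structure(list(m_ac = m_ac, m_dc = m_dc, mask = mask,
                 rows = rows, cols = cols, cfg = cfg),
            class = "modulation_maps")
}

#' Speckle contrast
#'
#' `K = sd / mean` over the supplied image or matrix; 1 for fully
#' developed polarized speckle, ~1/sqrt(N) for the average of N
#' independent patterns.
#'
#' @param image an [image_grid()] or numeric matrix.
#' @return scalar K.
#' @export
speckle_contrast <- function(image) {
  px <- if (inherits(image, "image_grid")) image$pixels else image
  m <- mean(px)
  if (m <= 0) stop("speckle contrast undefined for zero-mean region")
  stats::sd(as.vector(px)) / m
}
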