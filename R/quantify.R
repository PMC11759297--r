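# Calibration of measured modulation against a reference phantom,
# inversion to optical-property maps, and cross-wavelength adjustment.

#' Reference phantom record
#'
#' Bundles the known properties of the calibration phantom, its measured
#' AC/DC modulation at the calibration pose (scalars or per-pixel maps;
#' per-pixel absorbs vignetting), and the model-predicted reflectances.
#' Predictions default to the forward model evaluated at the stated
#' properties (DC: `Rd(0)`; AC: band sum over the LUT's AC frequencies).
#'
#' @param props [optical_properties()] of the reference phantom.
#' @param m_ac_ref,m_dc_ref measured modulation (scalar or matrix).
#' @param model [reflectance_model()].
#' @param ac_frequencies AC band used for the prediction.
#' @param rd_ac_pred,rd_dc_pred optional externally supplied predictions.
#' @return a `reference_record` object.
#' @export
reference_record <- function(props, m_ac_ref, m_dc_ref,
                             model = reflectance_model(),
                             ac_frequencies = seq(0.1, 0.5, by = 0.1),
                             rd_ac_pred = NULL, rd_dc_pred = NULL) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(m_ac_ref <= 0, na.rm = TRUE) || any(m_dc_ref <= 0, na.rm = TRUE)) {
    stop("reference modulation values must be positive")
  }
  if (is.null(rd_dc_pred)) rd_dc_pred <- rd_at_frequency(0, props, model)
  if (is.null(rd_ac_pred)) {
    rd_ac_pred <- sum(rd_at_frequency(ac_frequencies, props, model))
  }
  structure(list(props = props, m_ac_ref = m_ac_ref, m_dc_ref = m_dc_ref,
                 rd_ac_pred = rd_ac_pred, rd_dc_pred = rd_dc_pred,
                 ac_frequencies = ac_frequencies),
            class = "reference_record")
}

#' Calibrate modulation to diffuse reflectance
#'
#' `Rd = (m_sample / m_ref) * rd_ref_pred`, applied independently per
#' channel (AC and DC).  Vectorized; `m_ref` may be a scalar or a map
#' co-shaped with `m_sample`.
#'
#' @param m_sample measured sample modulation (scalar, vector or matrix).
#' @param m_ref reference modulation (> 0).
#' @param rd_ref_pred model-predicted reference reflectance.
#' @return calibrated reflectance, same shape as `m_sample`.
#' @export
calibrate_rd <- function(m_sample, m_ref, rd_ref_pred) {
  if (any(m_ref <= 0, na.rm = TRUE)) stop("'m_ref' must be positive")
  (m_sample / m_ref) * rd_ref_pred
}

#' Optical-property maps from calibrated reflectance maps
#'
#' Inverts the LUT per pixel.  Out-of-gamut pixels are masked (never
#' extrapolated) unless `clamp = TRUE`, in which case they are clamped to
#' the nearest node and still flagged in the mask report.
#'
#' @param rd_dc_map,rd_ac_map co-shaped matrices of calibrated
#'   reflectance.
#' @param lut a `property_lut`.
#' @param clamp clamp out-of-gamut pixels instead of masking with NA.
#' @return an `optical_property_map`: `mu_a_map`, `mu_s_map`, logical
#'   `mask` (TRUE = invalid/out-of-gamut), `n_masked`, `provenance`.
#' @export
property_maps <- function(rd_dc_map, rd_ac_map, lut, clamp = FALSE) {
  stopifnot(all(dim(rd_dc_map) == dim(rd_ac_map)))
  res <- invert_lut(as.vector(rd_dc_map), as.vector(rd_ac_map), lut,
                    clamp = TRUE)
  mu_a <- matrix(res$mu_a, nrow(rd_dc_map))
  mu_s <- matrix(res$mu_s_prime, nrow(rd_dc_map))
  oog <- matrix(res$clamped, nrow(rd_dc_map))
  bad <- oog | !is.finite(mu_a)
  if (!clamp) {
    mu_a[bad] <- NA_real_
    mu_s[bad] <- NA_real_
  }
  structure(list(mu_a_map = mu_a, mu_s_map = mu_s, mask = bad,
                 n_masked = sum(bad),
                 provenance = list(model_kind = lut$model_kind,
                                   ac_frequencies = lut$ac_frequencies,
                                   clamp = clamp)),
            class = "optical_property_map")
}

#' Cross-wavelength adjustment of optical properties
#'
#' Reduced scattering follows a Rayleigh relationship
#' (`mu_s' ~ lambda^-4`), so a value measured at `lambda_from` converts
#' to `lambda_to` by the factor `(lambda_from / lambda_to)^4`.
#' Absorption depends on the chromophore spectrum and is scaled by the
#' user-supplied extinction-coefficient ratio (default 1).
#'
#' @param props [optical_properties()] measured at `lambda_from`.
#' @param lambda_from,lambda_to wavelengths (nm).
#' @param absorber_extinction_ratio extinction coefficient ratio
#'   epsilon(lambda_to) / epsilon(lambda_from).
#' @return adjusted [optical_properties()].
#' @export
wavelength_adjust <- function(props, lambda_from, lambda_to,
                              absorber_extinction_ratio = 1) {
  stopifnot(inherits(props, "optical_properties"))
  stop_if_not_positive(lambda_from, "lambda_from")
  stop_if_not_positive(lambda_to, "lambda_to")
  optical_properties(
    mu_a = props$mu_a * absorber_extinction_ratio,
    mu_s_prime = props$mu_s_prime * (lambda_from / lambda_to)^4
  )
}

#' Rayleigh scattering wavelength factor
#'
#' @param lambda_from,lambda_to wavelengths (nm).
#' @return scalar `(lambda_from / lambda_to)^4`.
#' @export
rayleigh_scatter_factor <- function(lambda_from, lambda_to) {
  (lambda_from / lambda_to)^4
}
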