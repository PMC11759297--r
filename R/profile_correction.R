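# Height-dependent virtual-reference correction and Lambertian angle
# correction of calibrated diffuse reflectance, with distance-dependent
# sliding-window sizing and low-signal masking.

#' Fit the modulation-versus-distance height calibration model
#'
#' Reference-phantom AC and DC modulation measured at several known
#' distances are interpolated with shape-preserving piecewise cubic
#' Hermite polynomials (PCHIP), yielding `m_ac_ref(z)` and `m_dc_ref(z)`.
#' Queries outside the calibrated range error by default (PCHIP
#' extrapolation is untrustworthy); `clamp = TRUE` at query time pins
#' them to the endpoint values.
#'
#' @param distances_cm strictly ascending calibration distances (cm),
#'   >= 3 values; duplicates error.
#' @param m_ac_ref,m_dc_ref field-averaged reference modulation at each
#'   distance.
#' @param calibration_distance_cm the pose used for plain (uncorrected)
#'   calibration.
#' @param window_px_at_calibration sliding-window size at that pose (px).
#' @param speckle_valid_range_cm distance range over which the projected
#'   speckle keeps high contrast; queries outside trigger a warning and
#'   masking in [window_size_for_height()].
#' @return a `height_calibration_model`.
#' @export
fit_height_model <- function(distances_cm, m_ac_ref, m_dc_ref,
                             calibration_distance_cm = 7.8,
                             window_px_at_calibration = 85L,
                             speckle_valid_range_cm = c(4, 10)) {
  stopifnot(length(distances_cm) >= 3,
            length(m_ac_ref) == length(distances_cm),
            length(m_dc_ref) == length(distances_cm))
  if (anyDuplicated(distances_cm)) stop("duplicate calibration distances")
  o <- order(distances_cm)
  distances_cm <- distances_cm[o]
  m_ac_ref <- m_ac_ref[o]; m_dc_ref <- m_dc_ref[o]
  stop_if_not_positive(m_ac_ref, "m_ac_ref")
  stop_if_not_positive(m_dc_ref, "m_dc_ref")
  structure(list(distances = distances_cm,
                 m_ac_ref_z = m_ac_ref, m_dc_ref_z = m_dc_ref,
                 calibration_distance = calibration_distance_cm,
                 window_px_at_calibration =
                   as.integer(window_px_at_calibration),
                 speckle_valid_range = speckle_valid_range_cm),
            class = "height_calibration_model")
}

# Evaluate the PCHIP interpolants of a height model at distances z (cm).
eval_height_model <- function(model, z, channel = c("ac", "dc"),
                              clamp = FALSE) {
  channel <- match.arg(channel)
  rng <- range(model$distances)
  out_of_range <- z < rng[1] | z > rng[2]
  if (any(out_of_range & !is.na(z))) {
    if (!clamp) {
      stop(sprintf("height %.3g cm outside calibrated range [%g, %g] cm",
                   z[which(out_of_range)[1]], rng[1], rng[2]))
    }
    z <- pmin(pmax(z, rng[1]), rng[2])
  }
  y <- if (channel == "ac") model$m_ac_ref_z else model$m_dc_ref_z
  res <- rep(NA_real_, length(z))
  ok <- !is.na(z)
  res[ok] <- pracma::pchip(model$distances, y, z[ok])
  res
}

#' Distance-scaled sliding-window size
#'
#' The object pixel size grows linearly with distance at fixed angular
#' FOV, so keeping the object-space frequency resolution fixed requires
#' `window_px(z) = window_px_at_calibration * calibration_distance / z`,
#' rounded to the nearest odd integer (ties toward the smaller odd
#' value).  Distances outside the speckle-contrast validity range warn
#' and return NA.
#'
#' @param z_cm distance(s) in cm, > 0.
#' @param model a `height_calibration_model`.
#' @return integer window size(s) in px (NA where invalid).
#' @export
window_size_for_height <- function(z_cm, model) {
  stop_if_not_positive(z_cm[!is.na(z_cm)], "z_cm")
  vr <- model$speckle_valid_range
  invalid <- !is.na(z_cm) & (z_cm < vr[1] | z_cm > vr[2])
  if (any(invalid)) {
    warning(sprintf(
      "%d distance(s) outside the speckle-contrast validity range [%g, %g] cm; masked",
      sum(invalid), vr[1], vr[2]))
  }
  w <- round_to_odd(model$window_px_at_calibration *
                      model$calibration_distance / z_cm)
  w[invalid] <- NA_integer_
  w
}

#' Height-corrected virtual reference maps
#'
#' Interpolates the height model at each pixel's measured distance,
#' producing the per-pixel modulation the reference phantom would have
#' shown at that distance (the "virtual calibration phantom").
#'
#' @param height_map_cm per-pixel distances (cm).
#' @param model a `height_calibration_model`.
#' @param clamp clamp out-of-range heights to the calibrated endpoints
#'   instead of masking.
#' @return list with matrices `m_ac_ref`, `m_dc_ref` and logical `mask`
#'   (TRUE = height outside the calibrated range).
#' @export
virtual_reference <- function(height_map_cm, model, clamp = FALSE) {
  rng <- range(model$distances)
  mask <- !is.finite(height_map_cm) |
    height_map_cm < rng[1] | height_map_cm > rng[2]
  z <- height_map_cm
  if (clamp) {
    z <- pmin(pmax(z, rng[1]), rng[2])
    mask <- !is.finite(height_map_cm)
  } else {
    z[mask] <- NA_real_
  }
  mac <- matrix(eval_height_model(model, as.vector(z), "ac", clamp = TRUE),
                nrow(height_map_cm))
  mdc <- matrix(eval_height_model(model, as.vector(z), "dc", clamp = TRUE),
                nrow(height_map_cm))
  mac[mask] <- NA_real_; mdc[mask] <- NA_real_
  list(m_ac_ref = mac, m_dc_ref = mdc, mask = mask)
}

#' Height-corrected diffuse reflectance
#'
#' `Rd = (m_sample / m_ref_height_corr) * rd_ref_pred` per pixel, with
#' the virtual-reference modulation in the denominator.  Identical to
#' plain calibration when the sample sits at the calibration distance.
#'
#' @param m_sample_map measured sample modulation map.
#' @param virtual_ref_map co-shaped virtual reference modulation map.
#' @param rd_ref_pred model-predicted reference reflectance (scalar).
#' @return Rd map with non-positive/missing references masked NA.
#' @export
height_correct_rd <- function(m_sample_map, virtual_ref_map, rd_ref_pred) {
  stopifnot(all(dim(m_sample_map) == dim(virtual_ref_map)))
  bad <- !is.finite(virtual_ref_map) | virtual_ref_map <= 0
  out <- (m_sample_map / virtual_ref_map) * rd_ref_pred
  out[bad] <- NA_real_
  out
}

#' Correction configuration
#'
#' @param theta_max maximum polar angle corrected (deg); steeper pixels
#'   are masked rather than corrected (the Lambertian model fails there).
#' @param low_signal_percentile percentile below which flat-fielded
#'   pixels are masked as shadowed.
#' @param apply_height,apply_angle stage toggles.
#' @return a `correction_config`.
#' @export
correction_config <- function(theta_max = 40, low_signal_percentile = 5,
                              apply_height = TRUE, apply_angle = TRUE) {
  stopifnot(theta_max > 0, theta_max < 90)
  structure(list(theta_max = theta_max,
                 low_signal_percentile = low_signal_percentile,
                 apply_height = apply_height, apply_angle = apply_angle),
            class = "correction_config")
}

#' Lambertian angle-correction factor
#'
#' `1 / cos(theta)` for `theta <= theta_max`; NA beyond (masked, not
#' corrected) and at `theta >= 90` degrees.
#'
#' @param theta_deg polar angle(s), degrees.
#' @param theta_max maximum corrected angle (deg).
#' @return numeric factor(s) >= 1, NA where masked.
#' @export
angle_correction_factor <- function(theta_deg, theta_max = 40) {
  f <- 1 / cos(theta_deg * pi / 180)
  # tiny tolerance so the boundary angle itself survives fp rounding
  f[!is.finite(theta_deg) | theta_deg > theta_max + 1e-6 |
      theta_deg >= 90] <- NA_real_
  f
}

#' Angle-corrected diffuse reflectance
#'
#' Multiplies the height-corrected Rd map by `1/cos(theta)`; pixels with
#' theta above `cfg$theta_max` (or >= 90 deg) are masked.
#'
#' @param rd_height_corr_map height-corrected Rd map.
#' @param theta_map co-shaped polar angle map (deg).
#' @param cfg a [correction_config()].
#' @return corrected Rd map.
#' @export
angle_correct_rd <- function(rd_height_corr_map, theta_map,
                             cfg = correction_config()) {
  stopifnot(all(dim(rd_height_corr_map) == dim(theta_map)))
  rd_height_corr_map * angle_correction_factor(theta_map, cfg$theta_max)
}

#' Low-signal (shadow) mask
#'
#' Masks pixels of a flat-fielded image whose intensity falls below the
#' given percentile of the image histogram.  Percentile 0 masks nothing;
#' the mask grows monotonically with the percentile.
#'
#' @param flat_fielded_image matrix or [image_grid()].
#' @param percentile threshold percentile in \[0, 100\].
#' @return logical matrix, TRUE = masked.
#' @export
low_signal_mask <- function(flat_fielded_image, percentile = 5) {
  stopifnot(percentile >= 0, percentile <= 100)
  px <- if (inherits(flat_fielded_image, "image_grid")) {
    flat_fielded_image$pixels
  } else flat_fielded_image
  if (percentile == 0) return(matrix(FALSE, nrow(px), ncol(px)))
  thr <- stats::quantile(px, percentile / 100, na.rm = TRUE, names = FALSE)
  out <- px < thr
  out[is.na(out)] <- TRUE
  out
}

#' Serialize a height calibration model to JSON
#' @param model a `height_calibration_model`; `path` file path.
#' @return `height_model_write_json` returns `path` invisibly;
#'   `height_model_read_json` returns the model.
#' @export
height_model_write_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname height_model_write_json
#' @export
height_model_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_height_model(x$distances, x$m_ac_ref_z, x$m_dc_ref_z,
                   calibration_distance_cm = x$calibration_distance,
                   window_px_at_calibration = x$window_px_at_calibration,
                   speckle_valid_range_cm = x$speckle_valid_range)
}
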