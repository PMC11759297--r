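# End-to-end orchestration: configuration defaults matching the
# laparoscopic si-SFDI instrument, object-space geometry, and the full
# AC/DC + stereo to optical-property-map pipeline.

#' Object-space pixel size from angular field of view
#'
#' Per axis: `2 z tan(AFOV/2) / N`; the scalar size is the mean of the
#' two axes.  With the instrument defaults (AFOV 33 x 39 deg over
#' 784 x 960 px) a 78 mm working distance gives 58 um pixels.
#'
#' @param distance_mm working distance (mm).
#' @param afov_deg angular field of view c(rows, cols) in degrees.
#' @param roi_px sensor region of interest c(rows, cols) in pixels.
#' @return list with `per_axis` (mm, c(row, col)) and `mean` (mm).
#' @export
object_pixel_size <- function(distance_mm, afov_deg = c(33, 39),
                              roi_px = c(784, 960)) {
  stop_if_not_positive(distance_mm, "distance_mm")
  stop_if_not_positive(afov_deg, "afov_deg")
  stop_if_not_positive(roi_px, "roi_px")
  per_axis <- 2 * distance_mm * tan(afov_deg * pi / 360) / roi_px
  list(per_axis = per_axis, mean = mean(per_axis))
}

#' Pipeline configuration
#'
#' Defaults reproduce the instrument settings: 784 x 960 px ROI with a
#' 33 x 39 deg AFOV, 7.8 cm calibration distance (58 um object pixels),
#' an 85 px sliding window stepped by 5 px (0.2 mm^-1 frequency
#' resolution), AC bins centered at 0.2 and 0.4 mm^-1, and a 3 px
#' Gaussian prefilter.  Every value is overridable and echoed in the run
#' report.
#'
#' @param afov_deg,roi_px system geometry (see [object_pixel_size()]).
#' @param calibration_distance_cm calibration pose distance (cm).
#' @param window_px,step_px,ac_bin_centers,smoothing_kernel_px sliding
#'   window processing parameters.
#' @param correction a [correction_config()].
#' @param rig a [stereo_rig()].
#' @param pixel_size object pixel size at the calibration distance (mm);
#'   NULL (default) derives it from the AFOV and ROI.  Supply it directly
#'   when processing a crop of the full sensor.
#' @param seed RNG seed recorded with the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(afov_deg = c(33, 39), roi_px = c(784, 960),
                            calibration_distance_cm = 7.8,
                            window_px = 85L, step_px = 5L,
                            ac_bin_centers = c(0.2, 0.4),
                            smoothing_kernel_px = 3L,
                            correction = correction_config(),
                            rig = stereo_rig(), pixel_size = NULL,
                            seed = 1L) {
  if (is.null(pixel_size)) {
    pixel_size <- object_pixel_size(calibration_distance_cm * 10,
                                    afov_deg, roi_px)$mean
  }
  cfg <- sliding_window_config(window_px = window_px, step_px = step_px,
                               pixel_size = pixel_size,
                               ac_bin_centers = ac_bin_centers,
                               smoothing_kernel_px = smoothing_kernel_px)
  structure(list(afov_deg = afov_deg, roi_px = roi_px,
                 calibration_distance_cm = calibration_distance_cm,
                 window = cfg, correction = correction, rig = rig,
                 seed = seed),
            class = "pipeline_config")
}

sample_at_centers <- function(map, rows, cols) {
  map[rows, cols, drop = FALSE]
}

#' Run the full si-SFDI pipeline
#'
#' Stages: Gaussian prefilter, stereo profilometry (or a supplied /
#' assumed-flat surface), per-pixel window sizing from height, AC/DC
#' modulation maps, virtual-reference height correction, Lambertian
#' angle correction, low-signal masking, LUT inversion.  With
#' `apply_height`/`apply_angle` disabled (or a flat scene at the
#' calibration pose) the corrections reduce to plain reference
#' calibration.
#'
#' @param config a [pipeline_config()].
#' @param ac,dc AC (speckle) and DC (speckle-reduced) [image_grid()]s.
#' @param reference a [reference_record()] measured at the calibration
#'   pose.
#' @param lut a `property_lut` from [build_lut()].
#' @param left,right optional stereo pair for profilometry.
#' @param surface optional precomputed `surface_map` (overrides stereo).
#' @param height_model optional `height_calibration_model`; required when
#'   `config$correction$apply_height` and the scene is not flat at the
#'   calibration pose.
#' @param clamp_gamut clamp out-of-gamut pixels instead of masking.
#' @return list with `properties` (an `optical_property_map`), `surface`,
#'   `modulation`, `rd_dc`, `rd_ac`, and a `report` of effective settings
#'   and mask counts per stage.
#' @export
run_pipeline <- function(config, ac, dc, reference, lut,
                         left = NULL, right = NULL, surface = NULL,
                         height_model = NULL, clamp_gamut = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(ac, "image_grid"), inherits(dc, "image_grid"),
            inherits(reference, "reference_record"),
            inherits(lut, "property_lut"))
  t0 <- proc.time()[["elapsed"]]
  stage_fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  cc <- config$correction

  # --- profilometry ---------------------------------------------------
  if (is.null(surface)) {
    if (!is.null(left) && !is.null(right)) {
      surface <- tryCatch(
        profile_surface(left, right, config$rig),
        error = function(e) stage_fail("profilometry", e))
    } else {
      z0 <- config$calibration_distance_cm * 10
      flat <- matrix(z0, nrow(ac$pixels), ncol(ac$pixels))
      surface <- structure(
        list(height = flat,
             normals = list(nx = flat * 0, ny = flat * 0, nz = flat * 0 - 1),
             theta = flat * 0, mask = flat > 0 & FALSE),
        class = "surface_map")
    }
  }
  height_cm <- surface$height / 10

  # --- window sizing --------------------------------------------------
  window_px_map <- NULL
  use_height <- isTRUE(cc$apply_height) && !is.null(height_model)
  if (use_height) {
    wmap <- tryCatch(
      suppressWarnings(
        matrix(window_size_for_height(as.vector(height_cm), height_model),
               nrow(height_cm))),
      error = function(e) stage_fail("window_sizing", e))
    window_px_map <- wmap
  }

  # --- modulation maps ------------------------------------------------
  mm <- tryCatch(
    modulation_maps(ac, dc, config$window, window_px_map = window_px_map),
    error = function(e) stage_fail("modulation", e))
  rows <- mm$rows; cols <- mm$cols
  theta_g <- sample_at_centers(surface$theta, rows, cols)
  height_g <- sample_at_centers(height_cm, rows, cols)

  # --- reflectance calibration (height-corrected or plain) -----------
  if (use_height) {
    vref <- tryCatch(virtual_reference(height_g, height_model),
                     error = function(e) stage_fail("virtual_reference", e))
    rd_ac <- height_correct_rd(mm$m_ac, vref$m_ac_ref, reference$rd_ac_pred)
    rd_dc <- height_correct_rd(mm$m_dc, vref$m_dc_ref, reference$rd_dc_pred)
  } else {
    m_ac_ref <- reference$m_ac_ref
    m_dc_ref <- reference$m_dc_ref
    if (is.matrix(m_ac_ref)) m_ac_ref <- sample_at_centers(m_ac_ref, rows, cols)
    if (is.matrix(m_dc_ref)) m_dc_ref <- sample_at_centers(m_dc_ref, rows, cols)
    rd_ac <- calibrate_rd(mm$m_ac, m_ac_ref, reference$rd_ac_pred)
    rd_dc <- calibrate_rd(mm$m_dc, m_dc_ref, reference$rd_dc_pred)
  }

  # --- angle correction ----------------------------------------------
  if (isTRUE(cc$apply_angle)) {
    rd_ac <- angle_correct_rd(rd_ac, theta_g, cc)
    rd_dc <- angle_correct_rd(rd_dc, theta_g, cc)
  }

  # --- low-signal masking --------------------------------------------
  ff <- tryCatch(flat_field(dc$pixels, 55), error = function(e)
    stage_fail("flat_field", e))
  shadow <- low_signal_mask(ff, cc$low_signal_percentile)
  shadow_g <- sample_at_centers(shadow, rows, cols)
  rd_ac[shadow_g] <- NA_real_
  rd_dc[shadow_g] <- NA_real_

  # --- inversion ------------------------------------------------------
  props <- tryCatch(property_maps(rd_dc, rd_ac, lut, clamp = clamp_gamut),
                    error = function(e) stage_fail("inversion", e))

  report <- list(
    config = list(afov_deg = config$afov_deg, roi_px = config$roi_px,
                  calibration_distance_cm = config$calibration_distance_cm,
                  window_px = config$window$window_px,
                  step_px = config$window$step_px,
                  pixel_size_mm = config$window$pixel_size,
                  delta_f = config$window$delta_f,
                  ac_bin_centers = config$window$ac_bin_centers,
                  smoothing_kernel_px = config$window$smoothing_kernel_px,
                  theta_max = cc$theta_max,
                  low_signal_percentile = cc$low_signal_percentile,
                  apply_height = cc$apply_height,
                  apply_angle = cc$apply_angle,
                  seed = config$seed),
    height_correction_applied = use_height,
    angle_correction_applied = isTRUE(cc$apply_angle),
    n_windows = length(rows) * length(cols),
    n_masked_modulation = sum(mm$mask),
    n_masked_shadow = sum(shadow_g),
    n_masked_gamut = props$n_masked,
    runtime_s = proc.time()[["elapsed"]] - t0)

  list(properties = props, surface = surface, modulation = mm,
       rd_dc = rd_dc, rd_ac = rd_ac, report = report)
}

#' Write a pipeline run report as JSON
#' @param result output of [run_pipeline()]; `path` output path.
#' @return `path`, invisibly.
#' @export
report_write_json <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
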