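# Shared fixtures, memoized so expensive renders are built once per test
# run.  Two synthetic systems are used:
#  * the quarter-scale system (128 px scenes, 0.116 mm object pixels,
#    43 px window) for fast unit tests, and
#  * the full-scale system (256 px scenes, 0.058 mm object pixels, 85 px
#    window, step 10) for the end-to-end acceptance suite.
# Both sample the same 0.2 mm^-1 object-space frequency resolution.

.fx_cache <- new.env(parent = emptyenv())

# Shared illumination-pattern seed for closed-loop correction tests: the
# instrument projects the same pattern at every pose (equal AFOV keeps the
# sensor-side pattern fixed), so correction loops are rendered with one
# pattern to isolate correction error from pattern-sampling noise.
SEED_PATTERN <- 4242L

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

ref_props_fx <- function() optical_properties(0.024, 0.99)
sam_props_fx <- function() optical_properties(0.013, 1.26)

quarter_px0 <- 0.116
full_px0 <- 0.058

quarter_cfg <- function(step = 5L) {
  sliding_window_config(window_px = 43L, step_px = step,
                        pixel_size = quarter_px0)
}

full_cfg <- function(step = 10L, window_px = 85L, pixel_size = full_px0) {
  sliding_window_config(window_px = window_px, step_px = step,
                        pixel_size = pixel_size)
}

render_flat_quarter <- function(props, seed, z = 78, ...) {
  render_scene(scene_spec(c(128L, 128L), props, height_map = z,
                          pixel_size0 = quarter_px0, seed = seed, ...))
}

render_flat_full <- function(props, seed, z = 78, ...) {
  render_scene(scene_spec(c(256L, 256L), props, height_map = z,
                          pixel_size0 = full_px0, seed = seed, ...))
}

lut_fx <- function() fx("lut", build_lut())

# reference modulation at the calibration pose, full-scale system, under
# the shared projected pattern
ref_mod_full <- function() {
  fx("ref_mod_full", {
    sc <- render_flat_full(ref_props_fx(), seed = SEED_PATTERN)
    mm <- modulation_maps(sc$ac, sc$dc, full_cfg())
    list(m_ac = median(mm$m_ac, na.rm = TRUE),
         m_dc = median(mm$m_dc, na.rm = TRUE))
  })
}

ref_record_full <- function() {
  rm <- ref_mod_full()
  reference_record(ref_props_fx(), rm$m_ac, rm$m_dc)
}

# reference modulation at the calibration pose, quarter-scale system
# (same projected pattern as the quarter-scale sample fixtures)
ref_mod_quarter <- function() {
  fx("ref_mod_quarter", {
    sc <- fx("sc_quarter_ref", render_flat_quarter(ref_props_fx(), seed = 31))
    mm <- modulation_maps(sc$ac, sc$dc, quarter_cfg())
    list(m_ac = median(mm$m_ac, na.rm = TRUE),
         m_dc = median(mm$m_dc, na.rm = TRUE))
  })
}

ref_record_quarter <- function() {
  rm <- ref_mod_quarter()
  reference_record(ref_props_fx(), rm$m_ac, rm$m_dc)
}

height_cal_distances_cm <- c(5.8, 6.8, 7.8, 8.8, 9.8)

# height calibration of the full-scale system: reference phantom rendered
# at the five standard distances under the shared projected pattern, each
# measured with the distance-scaled window
height_model_full <- function() {
  fx("height_model_full", {
    zs <- height_cal_distances_cm * 10
    stub <- fit_height_model(height_cal_distances_cm, rep(1, 5), rep(1, 5))
    ws <- window_size_for_height(height_cal_distances_cm, stub)
    mac <- mdc <- numeric(5)
    for (i in seq_along(zs)) {
      sc <- render_flat_full(ref_props_fx(), seed = SEED_PATTERN, z = zs[i])
      cfg <- full_cfg(window_px = ws[i], pixel_size = sc$ac$pixel_size)
      mm <- modulation_maps(sc$ac, sc$dc, cfg)
      mac[i] <- median(mm$m_ac, na.rm = TRUE)
      mdc[i] <- median(mm$m_dc, na.rm = TRUE)
    }
    fit_height_model(height_cal_distances_cm, mac, mdc)
  })
}

# flat sample phantom at the calibration pose under the shared pattern,
# with its calibrated reflectance medians (closed-loop baselines)
flat_sample_full <- function() {
  fx("flat_sample_full", {
    model <- height_model_full()
    ref <- ref_record_full()
    node <- which(model$distances == 7.8)
    sc <- render_flat_full(sam_props_fx(), seed = SEED_PATTERN)
    mm <- modulation_maps(sc$ac, sc$dc, full_cfg())
    list(rd_dc = median(calibrate_rd(mm$m_dc, model$m_dc_ref_z[node],
                                     ref$rd_dc_pred), na.rm = TRUE),
         rd_ac = median(calibrate_rd(mm$m_ac, model$m_ac_ref_z[node],
                                     ref$rd_ac_pred), na.rm = TRUE))
  })
}

# brute-force spatial-domain autocorrelation oracle (linear, zero-meaned)
direct_acf_oracle <- function(window, local_dc) {
  v <- window - local_dc
  w <- nrow(v)
  out <- matrix(0, 2 * w - 1, 2 * w - 1)
  for (dy in -(w - 1):(w - 1)) {
    for (dx in -(w - 1):(w - 1)) {
      s <- 0
      for (y in 1:w) {
        for (x in 1:w) {
          y2 <- y + dy; x2 <- x + dx
          if (y2 >= 1 && y2 <= w && x2 >= 1 && x2 <= w) {
            s <- s + v[y, x] * v[y2, x2]
          }
        }
      }
      out[dy + w, dx + w] <- s
    }
  }
  out
}

# tilted-plane height map (tilt about the vertical axis, x-z plane)
tilt_height_map <- function(shape, pixel_size, angle_deg, z0 = 78) {
  x <- (col(matrix(0, shape[1], shape[2])) - (shape[2] + 1) / 2) * pixel_size
  z0 + x * tan(angle_deg * pi / 180)
}

median_err <- function(est, truth) {
  abs(median(est, na.rm = TRUE) - truth) / truth
}
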