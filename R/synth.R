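# Synthetic-data generator: fully developed objective speckle, tissue-MTF
# filtering, laser-speckle-reducer (LSR) averaging, Lambertian cos(theta)/z^2
# scene shading, and pinhole stereo pair rendering.  Every fixture in the
# test suite is produced by this module.

#' Speckle illumination geometry
#'
#' @param wavelength_nm laser wavelength (nm).
#' @param z_mm distance from fiber exit face to object (mm).
#' @param fiber_core_radius_um fiber core radius (um).
#' @param f_number detection f-number.
#' @param magnification detection magnification.
#' @return a `speckle_geometry` object.
#' @export
speckle_geometry <- function(wavelength_nm = 639, z_mm = 78,
                             fiber_core_radius_um = 300,
                             f_number = 4, magnification = 0) {
  stop_if_not_positive(wavelength_nm, "wavelength_nm")
  stop_if_not_positive(z_mm, "z_mm")
  stop_if_not_positive(fiber_core_radius_um, "fiber_core_radius_um")
  stop_if_not_positive(f_number, "f_number")
  stopifnot(magnification >= 0)
  structure(list(wavelength_nm = wavelength_nm, z_mm = z_mm,
                 fiber_core_radius_um = fiber_core_radius_um,
                 f_number = f_number, magnification = magnification),
            class = "speckle_geometry")
}

#' Mean objective speckle diameter
#'
#' `do = 2 * lambda * z / (pi * a)`: the grain size of the interference
#' pattern at the object plane, proportional to distance and inversely
#' proportional to the fiber core radius.
#'
#' @param geom a [speckle_geometry()].
#' @return diameter in mm.
#' @export
objective_speckle_diameter <- function(geom) {
  stopifnot(inherits(geom, "speckle_geometry"))
  lambda_mm <- geom$wavelength_nm * 1e-6
  a_mm <- geom$fiber_core_radius_um * 1e-3
  2 * lambda_mm * geom$z_mm / (pi * a_mm)
}

#' Minimum subjective speckle diameter
#'
#' `ds = 2.44 * lambda * (1 + m) * F#`: the grain size formed by the
#' detection optics at the sensor, independent of object distance.
#'
#' @param geom a [speckle_geometry()].
#' @return diameter in mm.
#' @export
subjective_speckle_diameter <- function(geom) {
  stopifnot(inherits(geom, "speckle_geometry"))
  lambda_mm <- geom$wavelength_nm * 1e-6
  2.44 * lambda_mm * (1 + geom$magnification) * geom$f_number
}

#' Generate a fully developed speckle intensity field
#'
#' Draws circular complex Gaussian spectral samples (uniform random
#' phases, Rayleigh amplitudes) on a circular Fourier-domain support and
#' takes the squared magnitude of the inverse transform, giving an
#' exactly fully developed (negative-exponential intensity) field.  The
#' support radius is set analytically so that the FWHM of the intensity
#' autocorrelation equals `grain_px`: for a circular aperture of radius
#' `rho` cycles/px the field correlation is `2 J1(x)/x` with
#' `x = 2 pi rho r`, whose squared magnitude reaches 1/2 at `x = 1.6163`,
#' giving `rho = 1.6163 / (pi * grain_px)`.
#'
#' @param shape integer c(rows, cols).
#' @param grain_px target mean grain size (ACF FWHM) in pixels, >= 2.
#' @param seed RNG seed (local to the call).
#' @return numeric matrix of intensities with mean 1.
#' @export
generate_speckle_field <- function(shape, grain_px = 5, seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (grain_px < 2) stop("'grain_px' must be >= 2 (Nyquist)")
  rho <- 1.6163 / (pi * grain_px)    # cycles per pixel
  if (rho * min(shape) < 2) stop("grain too large for this image shape")
  with_seed(seed, {
    fy <- fft_freq(shape[1])
    fx <- fft_freq(shape[2])
    support <- outer(fy^2, fx^2, `+`) <= rho^2
    spec_re <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    spec_im <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    field <- stats::fft(support * complex(real = spec_re,
                                          imaginary = spec_im),
                        inverse = TRUE)
    I <- Mod(field)^2
    I / mean(I)
  })
}

#' Filter an illumination image by a tissue diffuse-reflectance MTF
#'
#' Multiplies the intensity spectrum of the illumination by the radially
#' symmetric `Rd(f; mu_a, mu_s')` of the forward model: the DC component
#' is attenuated by `Rd(0)` and higher spatial frequencies are
#' progressively suppressed (tissue low-pass).  Negative ringing is
#' clipped at zero.
#'
#' @param illum an [image_grid()] or numeric matrix of illumination
#'   intensity.
#' @param props [optical_properties()] of the sample.
#' @param model [reflectance_model()].
#' @param pixel_size object pixel size (mm); taken from `illum` when it is
#'   an `image_grid`.
#' @return remitted intensity, same class as `illum`.
#' @export
apply_tissue_response <- function(illum, props, model = reflectance_model(),
                                  pixel_size = NULL) {
  is_grid <- inherits(illum, "image_grid")
  px <- if (is_grid) illum$pixel_size else pixel_size
  stop_if_not_positive(px, "pixel_size")
  I <- if (is_grid) illum$pixels else illum
  fy <- fft_freq(nrow(I), d = px)
  fx <- fft_freq(ncol(I), d = px)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  H <- matrix(rd_at_frequency(as.vector(fr), props, model),
              nrow(I), ncol(I))
  out <- Re(stats::fft(stats::fft(I) * H, inverse = TRUE)) / length(I)
  out[out < 0] <- 0
  if (is_grid) { illum$pixels <- out; illum } else out
}

#' Simulate a laser-speckle-reducer (planar) illumination image
#'
#' Averages `n_patterns` independent speckle realizations, emulating the
#' vibrating-fiber LSR that averages many patterns within one exposure.
#' The residual contrast decreases as `1/sqrt(n_patterns)`; the mean is
#' independent of n.  Pass `props` to additionally filter the average
#' through the tissue MTF.
#'
#' @param shape integer c(rows, cols).
#' @param grain_px speckle grain size (px).
#' @param n_patterns number of averaged patterns (>= 1).
#' @param seed RNG seed.
#' @param props,model,pixel_size optional tissue filtering (see
#'   [apply_tissue_response()]).
#' @return numeric matrix.
#' @export
simulate_lsr_dc <- function(shape, grain_px = 5, n_patterns = 256,
                            seed = NULL, props = NULL,
                            model = reflectance_model(),
                            pixel_size = NULL) {
  stopifnot(n_patterns >= 1)
  acc <- with_seed(seed, {
    a <- matrix(0, shape[1], shape[2])
    for (i in seq_len(n_patterns)) {
      a <- a + generate_speckle_field(shape, grain_px)
    }
    a / n_patterns
  })
  if (!is.null(props)) {
    acc <- apply_tissue_response(acc, props, model, pixel_size)
  }
  acc
}

#' Synthetic scene specification
#'
#' Describes a 3D sample observed by the simulated instrument.  Heights
#' are distances from the (left) camera along the optical axis, in mm;
#' the object pixel size scales linearly with distance at fixed angular
#' field of view, so `pixel_size(z) = pixel_size0 * z / calibration
#' distance`, while the speckle grain stays fixed on the sensor (equal
#' illumination and detection AFOV).
#'
#' @param shape c(rows, cols) of the rendered images.
#' @param props [optical_properties()] of the (background) sample.
#' @param height_map matrix of distances (mm), or a scalar for a flat
#'   fronto-parallel sample.
#' @param regions optional list of `list(mask = <logical matrix>, props =
#'   <optical_properties>)` overriding `props` inside each mask.
#' @param calibration_distance_mm reference pose distance (mm).
#' @param pixel_size0 object pixel size at the calibration distance (mm).
#' @param grain_px sensor-side speckle grain (px).
#' @param n_patterns LSR patterns averaged for the DC image.
#' @param focal_px stereo focal length (px); NULL (default) derives it
#'   from the pixel scale, `calibration_distance_mm / pixel_size0`, so
#'   the pinhole and object-pixel models agree. `baseline_mm` stereo
#'   baseline.
#' @param illumination_tilt_deg oblique source angle in the x-z plane
#'   (0 = coincident with the camera axis, the corrector's assumption).
#' @param noise list with `read_sd` (Gaussian read noise as a fraction of
#'   full scale) and `bit_depth` (quantization), or NULL for noiseless
#'   float output.
#' @param exposure list with `ac_mean`, `dc_mean`: exposure scale applied
#'   to the remitted intensity (sensor fraction per unit illumination at
#'   the calibration pose).  The defaults are equal, as in an instrument
#'   that acquires both images with the same exposure time: the AC image
#'   mean then equals the DC modulation, which the windowed ACF relies
#'   on.
#' @param texture_contrast speckle contrast of the RGB stereo texture.
#' @param seed RNG seed for all stochastic stages.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(shape, props, height_map = 78,
                       regions = NULL,
                       calibration_distance_mm = 78,
                       pixel_size0 = 0.058,
                       grain_px = 5, n_patterns = 256,
                       focal_px = NULL, baseline_mm = 5,
                       illumination_tilt_deg = 0,
                       noise = list(read_sd = 0.01, bit_depth = 8L),
                       exposure = list(ac_mean = 0.3, dc_mean = 0.3),
                       texture_contrast = 0.5,
                       seed = 1L) {
  stopifnot(length(shape) == 2, inherits(props, "optical_properties"))
  if (is.matrix(height_map)) {
    stopifnot(all(dim(height_map) == shape), all(height_map > 0))
  } else {
    stopifnot(length(height_map) == 1, height_map > 0)
    height_map <- matrix(height_map, shape[1], shape[2])
  }
  if (is.null(focal_px)) focal_px <- calibration_distance_mm / pixel_size0
  structure(list(shape = as.integer(shape), props = props,
                 height_map = height_map, regions = regions,
                 calibration_distance_mm = calibration_distance_mm,
                 pixel_size0 = pixel_size0, grain_px = grain_px,
                 n_patterns = n_patterns, focal_px = focal_px,
                 baseline_mm = baseline_mm,
                 illumination_tilt_deg = illumination_tilt_deg,
                 noise = noise, exposure = exposure,
                 texture_contrast = texture_contrast, seed = seed),
            class = "scene_spec")
}

# Ground-truth normals and polar angle from the height map by central
# differences in object-space coordinates.
surface_truth <- function(height_map, pixel_size_mm,
                          illumination_tilt_deg = 0) {
  H <- nrow(height_map); W <- ncol(height_map)
  dzdx <- matrix(0, H, W); dzdy <- matrix(0, H, W)
  dzdx[, 2:(W - 1)] <- (height_map[, 3:W] - height_map[, 1:(W - 2)]) /
    (2 * pixel_size_mm)
  dzdx[, 1] <- dzdx[, 2]; dzdx[, W] <- dzdx[, W - 1]
  dzdy[2:(H - 1), ] <- (height_map[3:H, ] - height_map[1:(H - 2), ]) /
    (2 * pixel_size_mm)
  dzdy[1, ] <- dzdy[2, ]; dzdy[H, ] <- dzdy[H - 1, ]
  nrm <- sqrt(1 + dzdx^2 + dzdy^2)
  # normal toward the camera: (df/dx, df/dy, -1)/|.|; optical axis +z
  nx <- dzdx / nrm; ny <- dzdy / nrm; nz <- -1 / nrm
  theta <- acos(pmin(1 / nrm, 1)) * 180 / pi
  # shading angle against the (possibly oblique) illumination direction
  it <- illumination_tilt_deg * pi / 180
  illum <- c(sin(it), 0, cos(it))    # from source toward scene (+z)
  cos_illum <- pmax(-(nx * illum[1] + ny * illum[2] + nz * illum[3]), 0)
  list(normals = list(nx = nx, ny = ny, nz = nz),
       theta = theta, cos_illum = cos_illum)
}

quantize_sensor <- function(img, noise) {
  img <- pmax(img, 0)
  if (is.null(noise)) return(pmin(img, 1))
  if (!is.null(noise$read_sd) && noise$read_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise$read_sd),
                        nrow(img), ncol(img))
  }
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(noise$bit_depth)) {
    maxv <- 2^noise$bit_depth - 1
    img <- round(img * maxv) / maxv
  }
  img
}

# Tissue-filter an illumination field, honouring per-region properties.
filter_by_regions <- function(illum, spec, model, pixel_size) {
  out <- apply_tissue_response(illum, spec$props, model, pixel_size)
  if (!is.null(spec$regions)) {
    for (rg in spec$regions) {
      filt <- apply_tissue_response(illum, rg$props, model, pixel_size)
      out[rg$mask] <- filt[rg$mask]
    }
  }
  out
}

#' Render a synthetic scene
#'
#' Produces the four raw images the pipeline consumes plus the ground
#' truth surface.  The AC image is one fully developed speckle field, the
#' DC image the LSR average of `n_patterns` fields; both are filtered by
#' the tissue diffuse-reflectance MTF at the scene's object pixel size,
#' shaded by the Lambertian factor `cos(theta) * (z_cal / z)^2` relative
#' to the calibration pose, then read-noise-corrupted and quantized.  The
#' stereo pair is an RGB speckle texture warped by the pinhole disparity
#' `d = f * B / z`.
#'
#' @param spec a [scene_spec()].
#' @param model [reflectance_model()] used as the tissue response.
#' @return list with `ac`, `dc` ([image_grid()]), `left`, `right`
#'   (H x W x 3 arrays), `truth` (height/normals/theta/shading and the
#'   scene spec echoes).
#' @export
render_scene <- function(spec, model = reflectance_model()) {
  stopifnot(inherits(spec, "scene_spec"))
  z0 <- spec$calibration_distance_mm
  zbar <- mean(spec$height_map)
  px <- spec$pixel_size0 * zbar / z0   # object pixel size at scene depth
  truth <- surface_truth(spec$height_map, px, spec$illumination_tilt_deg)
  shading <- truth$cos_illum * (z0 / spec$height_map)^2
  sh <- spec$shape
  with_seed(spec$seed, {
    ac_illum <- generate_speckle_field(sh, spec$grain_px)
    ac <- filter_by_regions(ac_illum, spec, model, px) * shading
    dc_illum <- simulate_lsr_dc(sh, spec$grain_px, spec$n_patterns)
    dc <- filter_by_regions(dc_illum, spec, model, px) * shading
    ac <- quantize_sensor(ac * spec$exposure$ac_mean, spec$noise)
    dc <- quantize_sensor(dc * spec$exposure$dc_mean, spec$noise)
    # RGB stereo texture: three independent speckle channels of moderate
    # contrast riding on the shaded illumination
    disparity <- spec$focal_px * spec$baseline_mm / spec$height_map
    left <- array(0, c(sh[1], sh[2], 3))
    right <- array(0, c(sh[1], sh[2], 3))
    xs <- seq_len(sh[2])
    for (ch in 1:3) {
      tex <- 1 + spec$texture_contrast *
        (generate_speckle_field(sh, spec$grain_px) - 1)
      Lch <- tex * shading * spec$exposure$dc_mean
      Rch <- matrix(0, sh[1], sh[2])
      for (r in seq_len(sh[1])) {
        Rch[r, ] <- stats::approx(xs, Lch[r, ], xout = xs + disparity[r, ],
                                  rule = 2)$y
      }
      left[, , ch] <- quantize_sensor(Lch, spec$noise)
      right[, , ch] <- quantize_sensor(Rch, spec$noise)
    }
    list(ac = image_grid(ac, px, bit_depth = spec$noise$bit_depth %||% NA),
         dc = image_grid(dc, px, bit_depth = spec$noise$bit_depth %||% NA),
         left = left, right = right,
         truth = list(height = spec$height_map, normals = truth$normals,
                      theta = truth$theta, shading = shading,
                      disparity = disparity, pixel_size = px),
         spec = spec)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hemisphere-on-plane height map
#'
#' A spherical cap of the given base diameter and height centered on a
#' flat background plane, expressed as camera distances (the cap rises
#' toward the camera).
#'
#' @param shape c(rows, cols).
#' @param pixel_size object pixel size (mm).
#' @param base_distance_mm distance of the flat background (mm).
#' @param diameter_mm cap base diameter (mm); `height_mm` cap height.
#' @return height map matrix (mm).
#' @export
hemisphere_height_map <- function(shape, pixel_size, base_distance_mm = 78,
                                  diameter_mm = 19, height_mm = 10) {
  a <- diameter_mm / 2
  R <- (a^2 + height_mm^2) / (2 * height_mm)  # sphere radius of the cap
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  yy <- (row(matrix(0, shape[1], shape[2])) - cy) * pixel_size
  xx <- (col(matrix(0, shape[1], shape[2])) - cx) * pixel_size
  r2 <- xx^2 + yy^2
  cap <- r2 <= a^2
  lift <- matrix(0, shape[1], shape[2])
  lift[cap] <- sqrt(pmax(0, R^2 - r2[cap])) - (R - height_mm)
  base_distance_mm - lift
}
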