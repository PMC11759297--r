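# Synthetic-data generator: speckle physics, tissue filtering, rendering.

test_that("objective speckle diameter follows 2*lambda*z/(pi*a)", {
  g <- speckle_geometry(wavelength_nm = 639, z_mm = 78,
                        fiber_core_radius_um = 300)
  expect_equal(objective_speckle_diameter(g), 0.105772, tolerance = 1e-4)
  g2 <- speckle_geometry(639, 156, 300)
  expect_equal(objective_speckle_diameter(g2),
               2 * objective_speckle_diameter(g))
  g3 <- speckle_geometry(639, 78, 600)
  expect_equal(objective_speckle_diameter(g3),
               objective_speckle_diameter(g) / 2)
})

test_that("subjective speckle diameter follows 2.44*lambda*(1+m)*F#", {
  g <- speckle_geometry(639, 78, 300, f_number = 4, magnification = 0)
  expect_equal(subjective_speckle_diameter(g), 2.44 * 639e-6 * 4)
  expect_equal(subjective_speckle_diameter(g) * 1e3, 6.24, tolerance = 1e-2)
  # independent of z, reduces to 2.44 lambda F# at m = 0
  g2 <- speckle_geometry(639, 200, 300, f_number = 4)
  expect_equal(subjective_speckle_diameter(g2), subjective_speckle_diameter(g))
})

test_that("speckle fields are seed-reproducible with controlled grain", {
  f1 <- generate_speckle_field(c(64, 64), 4, seed = 7)
  f2 <- generate_speckle_field(c(64, 64), 4, seed = 7)
  expect_identical(f1, f2)
  f3 <- generate_speckle_field(c(64, 64), 4, seed = 8)
  expect_false(identical(f1, f3))
  expect_error(generate_speckle_field(c(64, 64), 1.5), "Nyquist")
  expect_error(generate_speckle_field(c(16, 16), 200), "too large")
  # ACF FWHM close to the requested grain (within 20%)
  fw <- sapply(1:6, function(s) {
    f <- generate_speckle_field(c(256, 256), 5, seed = s)
    a <- window_acf(f[1:85, 1:85], mean(f))
    v <- radial_average(a, 1)$values
    v <- v / v[1]
    2 * approx(v[1:10], 0:9, xout = 0.5)$y
  })
  expect_lt(abs(mean(fw) / 5 - 1), 0.2)
})

test_that("single-field intensity is exponential (fully developed)", {
  f <- generate_speckle_field(c(512, 512), 5, seed = 3)
  x <- as.vector(f)[seq_len(1e5)]
  ks <- suppressWarnings(ks.test(x, "pexp", 1))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("tissue filtering attenuates DC by Rd(0) and blurs high frequencies", {
  f <- generate_speckle_field(c(128, 128), 5, seed = 12)
  p_lo <- optical_properties(0.024, 0.7)
  p_hi <- optical_properties(0.024, 1.5)
  out_lo <- apply_tissue_response(f, p_lo, pixel_size = quarter_px0)
  out_hi <- apply_tissue_response(f, p_hi, pixel_size = quarter_px0)
  # more scattering -> brighter DC and a wider MTF (relatively sharper
  # remitted speckle); less scattering -> stronger blur
  expect_equal(mean(out_lo), mean(f) * rd_at_frequency(0, p_lo),
               tolerance = 0.01)
  expect_gt(var(as.vector(out_hi / mean(out_hi))),
            var(as.vector(out_lo / mean(out_lo))))
  # more absorption -> darker output
  out_abs <- apply_tissue_response(f, optical_properties(0.08, 0.7),
                                   pixel_size = quarter_px0)
  expect_lt(mean(out_abs), mean(out_lo))
  # identity filter stub leaves the input untouched
  ident <- reflectance_model("imported_table",
                             table = list(fx = c(0, 100), mu_a = c(0.001, 1),
                                          mu_s_prime = c(0.1, 10),
                                          rd = array(1, c(2, 2, 2))))
  expect_equal(apply_tissue_response(f, p_lo, ident,
                                     pixel_size = quarter_px0), f,
               tolerance = 1e-10)
})

test_that("LSR averaging reduces contrast as 1/sqrt(n) at constant mean", {
  one <- simulate_lsr_dc(c(128, 128), 5, 1, seed = 14)
  expect_equal(one, generate_speckle_field(c(128, 128), 5, seed = 14))
  for (n in c(4, 16, 64)) {
    K <- mean(sapply(1:3, function(s)
      speckle_contrast(simulate_lsr_dc(c(128, 128), 5, n, seed = 20 + s))))
    expect_equal(K, 1 / sqrt(n), tolerance = 0.1 / sqrt(n))
  }
  m64 <- mean(simulate_lsr_dc(c(128, 128), 5, 64, seed = 15))
  expect_equal(m64, 1, tolerance = 0.05)   # mean independent of n
})

test_that("rendered scenes shade as cos(theta)/z^2 relative to calibration", {
  flat <- render_flat_quarter(ref_props_fx(), seed = 16, noise = NULL)
  expect_true(all(flat$truth$shading == 1))
  expect_true(all(flat$truth$theta == 0))
  far <- render_flat_quarter(ref_props_fx(), seed = 16, z = 156, noise = NULL)
  expect_equal(mean(far$dc$pixels) / mean(flat$dc$pixels), 0.25,
               tolerance = 0.05)
  expect_equal(far$dc$pixel_size, 2 * flat$dc$pixel_size)
})

test_that("projected speckle grain in object units scales linearly with distance", {
  # equal illumination and detection AFOV: the sensor-side pattern is
  # fixed, so the object-side grain grows in proportion to distance.
  # Measured through an identity tissue response to isolate the
  # illumination statistics.
  ident <- reflectance_model("imported_table",
                             table = list(fx = c(0, 100), mu_a = c(1e-4, 1),
                                          mu_s_prime = c(0.1, 10),
                                          rd = array(1, c(2, 2, 2))))
  zs <- c(58, 68, 78, 88, 98)
  widths <- sapply(seq_along(zs), function(i) {
    sc <- render_scene(scene_spec(c(128, 128), ref_props_fx(),
                                  height_map = zs[i],
                                  pixel_size0 = quarter_px0, noise = NULL,
                                  seed = 70),
                       model = ident)
    f <- sc$ac$pixels
    a <- window_acf(f, mean(f))
    v <- radial_average(a, sc$ac$pixel_size)$values
    v <- v / v[1]
    r <- which(v < 0.5)[1]
    2 * approx(v[(r - 1):r], (r - 2):(r - 1), xout = 0.5)$y *
      sc$ac$pixel_size
  })
  fit <- lm(widths ~ zs)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[2], 0)
})

test_that("hemisphere cap reaches polar angles beyond 40 degrees at the rim", {
  hm <- hemisphere_height_map(c(256, 256), full_px0, base_distance_mm = 78,
                              diameter_mm = 19, height_mm = 10)
  expect_equal(min(hm), 68, tolerance = 0.01)    # apex 1 cm above the base
  sc <- render_scene(scene_spec(c(256, 256), sam_props_fx(), height_map = hm,
                                pixel_size0 = full_px0, noise = NULL,
                                seed = 17))
  expect_gt(max(sc$truth$theta), 40)
  expect_lt(max(sc$truth$theta[120:136, 120:136]), 10)  # near the apex
})

test_that("an oblique source shades front tilts asymmetrically", {
  # 15 deg source in the x-z plane: a surface tilted toward the source
  # is brighter than the same tilt away from it; the corrector never
  # models this, mirroring the instrument's front-tilt asymmetry
  zp <- tilt_height_map(c(64, 64), quarter_px0, 20)
  zm <- tilt_height_map(c(64, 64), quarter_px0, -20)
  sh <- function(z) mean(sisfdi:::surface_truth(z, quarter_px0, 15)$cos_illum)
  s0 <- function(z) mean(sisfdi:::surface_truth(z, quarter_px0, 0)$cos_illum)
  expect_equal(s0(zp), s0(zm), tolerance = 1e-10)   # coincident: symmetric
  expect_gt(abs(sh(zp) - sh(zm)), 0.05)             # oblique: asymmetric
})

test_that("stereo pair carries the ground-truth disparity warp", {
  sc <- fx("sc_quarter_ref", render_flat_quarter(ref_props_fx(), seed = 31))
  d <- sc$truth$disparity
  expect_equal(unique(round(as.vector(d), 6)),
               round(sc$spec$focal_px * 5 / 78, 6))
  expect_equal(dim(sc$left), c(128, 128, 3))
  # a point at left column j + d appears at right column j
  ch <- sc$left[, , 2]
  shifted <- sc$right[, , 2]
  dpx <- round(d[1, 1])
  expect_gt(cor(as.vector(shifted[, 1:(128 - dpx)]),
                as.vector(ch[, (dpx + 1):128])), 0.95)
})

test_that("renders are reproducible and quantized to the sensor bit depth", {
  a <- render_flat_quarter(ref_props_fx(), seed = 18)
  b <- render_flat_quarter(ref_props_fx(), seed = 18)
  expect_identical(a$ac$pixels, b$ac$pixels)
  expect_identical(a$left, b$left)
  lev <- unique(as.vector(a$dc$pixels))
  expect_true(all(abs(lev * 255 - round(lev * 255)) < 1e-9))
})
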