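# Sliding-window autocorrelation, radial PSD, and modulation extraction.

test_that("Gaussian prefilter preserves constants, rejects even kernels", {
  img <- image_grid(matrix(3.5, 32, 32), 0.058)
  out <- preprocess_speckle(img, 3L)
  expect_equal(out$pixels[5:28, 5:28], img$pixels[5:28, 5:28])
  expect_identical(preprocess_speckle(img, 1L), img)
  expect_error(preprocess_speckle(img, 4L), "odd")
})

test_that("3 px kernel suppresses 1 px speckle far more than 5 px speckle", {
  fine <- generate_speckle_field(c(128, 128), 2, seed = 1)
  coarse <- generate_speckle_field(c(128, 128), 5, seed = 1)
  ratio <- function(f) {
    g <- preprocess_speckle(image_grid(f, 0.058), 3L)$pixels
    var(as.vector(g)) / var(as.vector(f))
  }
  expect_lt(ratio(fine), ratio(coarse))
  expect_lt(ratio(fine), 0.5)
})

test_that("Fourier-route windowed ACF equals the direct shift-and-sum oracle", {
  set.seed(11)
  for (w in c(4, 8, 13)) {
    win <- matrix(runif(w * w), w, w)
    dc <- mean(win)
    fast <- window_acf(win, dc)
    slow <- direct_acf_oracle(win, dc)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-10)
    # zero lag equals total squared deviation (Parseval)
    expect_equal(fast[w, w], sum((win - dc)^2))
  }
})

test_that("ACF of a constant window is zero and flagged", {
  win <- matrix(2, 9, 9)
  a <- window_acf(win, 2)
  expect_true(all(abs(a) < 1e-12))
  expect_true(attr(a, "all_zero"))
})

test_that("radial average reproduces an isotropic Gaussian profile", {
  n <- 41; ctr <- 21; sig <- 4
  r2 <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2
  acf <- exp(-r2 / (2 * sig^2))
  prof <- radial_average(acf, 0.058)
  expect_equal(prof$values[1], 1)                      # zero lag
  rr <- prof$r_px[prof$r_px <= 12]
  expect_equal(prof$values[seq_along(rr)], exp(-rr^2 / (2 * sig^2)),
               tolerance = 0.03)
})

test_that("white-noise ACF radially averages to ~0 off zero lag", {
  set.seed(3)
  vals <- replicate(30, {
    w <- matrix(1 + rnorm(15^2, sd = 0.2), 15, 15)
    a <- window_acf(w, mean(w))
    p <- radial_average(a, 1)
    mean(abs(p$values[p$r_px >= 1 & p$r_px <= 10])) / p$values[1]
  })
  expect_lt(mean(vals), 0.1)
})

test_that("PSD binning follows the fk +/- delta_f/2 convention", {
  # delta-like ACF profile -> flat spectrum across bins
  prof <- list(r_px = 0:20, values = c(1, rep(0, 20)), pixel_size = 0.058)
  psd <- psd_from_radial_acf(prof, delta_f = 0.2)
  expect_equal(psd$kr[1], 0)
  expect_true(all(diff(psd$kr) > 0))
  # a delta ACF has a flat spectrum: every DFT sample has unit magnitude,
  # so each bin's value equals its sample count (within one sample)
  expect_true(all(psd$values >= 1))
  # broader ACF pushes mass to lower bins
  wide <- list(r_px = 0:20, values = exp(-(0:20)^2 / 50), pixel_size = 0.058)
  narrow <- list(r_px = 0:20, values = exp(-(0:20)^2 / 8), pixel_size = 0.058)
  pw <- psd_from_radial_acf(wide, 0.2)
  pn <- psd_from_radial_acf(narrow, 0.2)
  frac_low <- function(p) sum(p$values[p$kr <= 0.2]) / sum(p$values)
  expect_gt(frac_low(pw), frac_low(pn))
})

test_that("MAC sums exactly the requested bins and errors on missing bins", {
  prof <- list(r_px = 0:42, values = exp(-(0:42) / 6), pixel_size = 0.116)
  psd <- psd_from_radial_acf(prof, 0.2)
  expect_equal(mac_from_psd(psd, c(0.2, 0.4)),
               psd$values[which.min(abs(psd$kr - 0.2))] +
                 psd$values[which.min(abs(psd$kr - 0.4))])
  zero <- psd
  zero$values[] <- 0
  expect_equal(mac_from_psd(zero), 0)
  expect_error(mac_from_psd(psd, 7.7), "no PSD bin")
})

test_that("MDC is the window mean and respects bounds", {
  img <- image_grid(matrix(4.2, 64, 64), 0.058)
  expect_equal(mdc_from_image(img, 21, c(32, 32)), 4.2)
  expect_equal(mdc_from_image(img, 21, c(11, 54)), 4.2)  # center-invariant
  expect_error(mdc_from_image(img, 21, c(5, 32)), "bounds")
  # law of large numbers: LSR average tends to the field mean
  dc64 <- simulate_lsr_dc(c(64, 64), 5, 64, seed = 9)
  expect_equal(mdc_from_image(image_grid(dc64, 0.058), 33, c(32, 32)), 1,
               tolerance = 0.1)
})

test_that("modulation map grid dimensions follow the sliding-window count", {
  sc <- fx("sc_quarter_ref", render_flat_quarter(ref_props_fx(), seed = 31))
  cfg <- quarter_cfg(step = 7L)
  mm <- modulation_maps(sc$ac, sc$dc, cfg)
  expected <- floor((128 - 43) / 7) + 1
  expect_equal(dim(mm$m_ac), c(expected, expected))
  expect_equal(dim(mm$m_dc), dim(mm$m_ac))
  expect_true(all(mm$m_dc > 0, na.rm = TRUE))
  bad <- image_grid(matrix(1, 64, 64), quarter_px0)
  expect_error(modulation_maps(sc$ac, bad, cfg), "shape")
})

test_that("homogeneous sample yields a MAC map as uniform as mode counting allows", {
  sc <- fx("sc_quarter_ref", render_flat_quarter(ref_props_fx(), seed = 31))
  mm <- modulation_maps(sc$ac, sc$dc, quarter_cfg())
  cv <- sd(mm$m_ac, na.rm = TRUE) / mean(mm$m_ac, na.rm = TRUE)
  # the AC band holds ~19 Fourier modes per window (annulus 0.1-0.5 mm^-1
  # over a 4.99 mm window), so the amplitude CV floor is about
  # sqrt(1 / (2 * 19)) ~ 16%; the map must be consistent with that floor,
  # not with any real spatial structure
  n_modes <- pi * ((0.5 * 4.99)^2 - (0.1 * 4.99)^2)
  expect_lt(cv, 0.25)
  expect_equal(cv, sqrt(1 / (2 * n_modes)), tolerance = 0.5)
})

test_that("lower scattering blurs the speckle and narrows the PSD band ratio", {
  # a lower mu_s' means a longer transport length: photons emerge farther
  # from entry, the remitted speckle is blurrier, and the AC band carries
  # relatively less power than the DC
  lo <- render_flat_quarter(optical_properties(0.024, 0.7), seed = 33)
  hi <- render_flat_quarter(optical_properties(0.024, 1.5), seed = 33)
  cfg <- quarter_cfg()
  r <- function(sc) {
    mm <- modulation_maps(sc$ac, sc$dc, cfg)
    median(mm$m_ac / mm$m_dc, na.rm = TRUE)
  }
  expect_lt(r(lo), r(hi))
})

test_that("two half-planes with different scattering separate in MAC as the model predicts", {
  mask <- col(matrix(0, 128, 128)) > 64
  spec <- scene_spec(c(128, 128), optical_properties(0.024, 0.7),
                     regions = list(list(mask = mask,
                                         props = optical_properties(0.024, 1.5))),
                     pixel_size0 = quarter_px0, seed = 35)
  sc <- render_scene(spec)
  mm <- modulation_maps(sc$ac, sc$dc, quarter_cfg())
  half <- ncol(mm$m_ac) %/% 2
  left_ratio <- median(mm$m_ac[, 1:(half - 1)] / mm$m_dc[, 1:(half - 1)],
                       na.rm = TRUE)
  right_ratio <- median(mm$m_ac[, (half + 2):ncol(mm$m_ac)] /
                          mm$m_dc[, (half + 2):ncol(mm$m_ac)], na.rm = TRUE)
  # the forward model predicts a higher AC/DC band ratio for higher
  # scattering (wider MTF); the measured halves must order the same way
  p_lo <- optical_properties(0.024, 0.7); p_hi <- optical_properties(0.024, 1.5)
  band <- seq(0.1, 0.5, 0.1)
  model_lo <- sum(rd_at_frequency(band, p_lo)) / rd_at_frequency(0, p_lo)
  model_hi <- sum(rd_at_frequency(band, p_hi)) / rd_at_frequency(0, p_hi)
  expect_gt(model_hi, model_lo)
  expect_gt(right_ratio, left_ratio)
})

test_that("MAC is seed-invariant and gain-invariant through calibration", {
  # scene-median MAC across independent pattern realizations; wide-field
  # scenes so the mode-counting noise floor sits below the 5% bound
  cfg <- full_cfg()
  macs <- sapply(1:6, function(s) {
    sc <- render_scene(scene_spec(c(384L, 384L), ref_props_fx(),
                                  pixel_size0 = full_px0, n_patterns = 64,
                                  seed = 101L * s))
    median(modulation_maps(sc$ac, sc$dc, cfg)$m_ac, na.rm = TRUE)
  })
  expect_lt(sd(macs) / mean(macs), 0.05)
  # a global gain g on both sample and reference cancels in Rd
  cfg <- quarter_cfg(step = 10L)
  sc <- fx("sc_quarter_ref", render_flat_quarter(ref_props_fx(), seed = 31))
  mm1 <- modulation_maps(sc$ac, sc$dc, cfg)
  acg <- sc$ac; acg$pixels <- acg$pixels * 2.7
  dcg <- sc$dc; dcg$pixels <- dcg$pixels * 2.7
  mm2 <- modulation_maps(acg, dcg, cfg)
  rd1 <- calibrate_rd(mm1$m_ac, median(mm1$m_ac, na.rm = TRUE), 0.5)
  rd2 <- calibrate_rd(mm2$m_ac, median(mm2$m_ac, na.rm = TRUE), 0.5)
  expect_equal(rd1, rd2, tolerance = 1e-10)
})

test_that("speckle contrast behaves as sigma over mean", {
  expect_equal(speckle_contrast(matrix(5, 16, 16)), 0)
  expect_error(speckle_contrast(matrix(0, 4, 4)), "zero-mean")
  K <- mean(sapply(1:20, function(s)
    speckle_contrast(generate_speckle_field(c(128, 128), 4, seed = s))))
  expect_equal(K, 1, tolerance = 0.05)
})
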