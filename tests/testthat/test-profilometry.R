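# Flat-field, stereo matching, reprojection, cloud cleaning, normals.

test_that("flat-field normalizes uniform images and removes slow ramps", {
  u <- flat_field(matrix(7, 64, 64), sigma_px = 10)
  expect_equal(mean(u[20:44, 20:44]), 1, tolerance = 1e-6)
  # multiplicative ramp times texture: interior low-frequency content
  # reduced by at least 10x under the default sigma
  ramp <- outer(seq(0.5, 2, length.out = 256), seq(1, 1.6, length.out = 256))
  tex <- generate_speckle_field(c(256, 256), 4, seed = 5)
  ff <- flat_field(ramp * tex, sigma_px = 55)
  inner <- 60:196
  low <- function(m) {
    sd(as.vector(sisfdi:::gauss_blur(m, sigma = 40)[inner, inner]))
  }
  expect_gt(low(ramp * tex) / low(ff), 10)
  expect_error(flat_field(matrix(1, 8, 8), -1), "positive")
})

test_that("identical images give zero disparity", {
  set.seed(6)
  tex <- generate_speckle_field(c(96, 96), 4, seed = 6)
  rig <- stereo_rig()
  m <- match_stereo(tex, tex, rig, levels = 2, z_range_mm = c(3000, 1e5))
  expect_lt(abs(median(m$disparity, na.rm = TRUE)), 0.1)
})

test_that("fronto-parallel plane yields uniform disparity f*B/z", {
  rig <- stereo_rig()
  sc <- fx("sc_stereo_flat78",
           render_flat_full(ref_props_fx(), seed = 61, noise = NULL))
  g <- function(x) (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  m <- match_stereo(flat_field(g(sc$left), 55), flat_field(g(sc$right), 55),
                    rig)
  d_true <- rig$focal_px * rig$baseline_mm / 78
  interior <- m$disparity[40:216, 40:216]
  interior[m$mask[40:216, 40:216]] <- NA
  expect_equal(median(interior, na.rm = TRUE), d_true, tolerance = 0.005)
  expect_lt(IQR(interior, na.rm = TRUE), 0.5)
})

test_that("a tilted plane produces a linear disparity ramp along the tilt axis", {
  rig <- stereo_rig()
  zmap <- tilt_height_map(c(256, 256), full_px0, 30)
  sc <- render_scene(scene_spec(c(256, 256), ref_props_fx(),
                                height_map = zmap, pixel_size0 = full_px0,
                                noise = NULL, seed = 62))
  g <- function(x) (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  m <- match_stereo(flat_field(g(sc$left), 55), flat_field(g(sc$right), 55),
                    rig)
  row_d <- m$disparity[128, ]
  ok <- which(is.finite(row_d))
  fit <- lm(row_d[ok] ~ ok)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(fit$coefficients[2], 0)   # larger z to the right, smaller d
})

test_that("reprojection inverts the pinhole model exactly", {
  rig <- stereo_rig()
  d <- matrix(rig$focal_px * rig$baseline_mm / 80, 32, 32)
  cl <- reproject(d, rig)
  expect_equal(cl$Z, matrix(80, 32, 32))
  cl2 <- reproject(d / 2, rig)
  expect_equal(cl2$Z, matrix(160, 32, 32))   # halving disparity doubles depth
  dneg <- d; dneg[1, 1] <- -1; dneg[1, 2] <- NA
  cl3 <- reproject(dneg, rig)
  expect_true(cl3$mask[1, 1] && cl3$mask[1, 2])
  expect_true(is.na(cl3$Z[1, 1]))
})

test_that("cloud cleaning preserves planes exactly and suppresses noise", {
  rig <- stereo_rig()
  n <- 96
  plane <- outer(seq(70, 80, length.out = n), seq(0, 5, length.out = n), `+`)
  mk_cloud <- function(Z) {
    pp <- c((n + 1) / 2, (n + 1) / 2)
    list(X = (col(Z) - pp[2]) * Z / rig$focal_px,
         Y = (row(Z) - pp[1]) * Z / rig$focal_px, Z = Z,
         mask = matrix(FALSE, n, n))
  }
  cleaned <- clean_cloud(mk_cloud(plane), rig)
  expect_equal(dim(cleaned$height), c(n, n))
  expect_lt(max(abs(cleaned$height - plane)[10:86, 10:86]), 0.02)
  # plane + 1 mm Gaussian noise: residual well under 0.25 mm
  res <- sapply(1:5, function(s) {
    set.seed(s)
    noisy <- plane + matrix(rnorm(n * n, 0, 1), n, n)
    sd((clean_cloud(mk_cloud(noisy), rig)$height - plane)[10:86, 10:86])
  })
  expect_lt(mean(res), 0.25)
  # too-sparse input errors
  sparse <- mk_cloud(plane)
  sparse$Z[] <- NA
  expect_error(clean_cloud(sparse, rig), "sparse")
})

test_that("Savitzky-Golay defaults are order 1, frame 31", {
  expect_identical(formals(clean_cloud)$sg_order, 1L)
  expect_identical(formals(clean_cloud)$sg_frame, 31L)
  expect_identical(formals(estimate_normals)$k, 6L)
})

test_that("normals recover plane orientation", {
  rig <- stereo_rig()
  n <- 96
  pp <- c((n + 1) / 2, (n + 1) / 2)
  mk_surface <- function(Z) {
    list(height = Z,
         X = (col(Z) - pp[2]) * Z / rig$focal_px,
         Y = (row(Z) - pp[1]) * Z / rig$focal_px)
  }
  # fronto-parallel: theta = 0 everywhere
  s0 <- estimate_normals(mk_surface(matrix(78, n, n)))
  expect_lt(max(s0$theta, na.rm = TRUE), 0.5)
  expect_equal(max(abs(sqrt(s0$normals$nx^2 + s0$normals$ny^2 +
                              s0$normals$nz^2) - 1)), 0, tolerance = 1e-9)
  # 30 degree tilt about the vertical axis: the metric plane
  # Z = 78 + X tan(30) with X = (c - cx) Z / f solves to
  # Z = 78 / (1 - (c - cx) tan(30) / f)
  u <- col(matrix(0, n, n)) - pp[2]
  Z <- 78 / (1 - u * tan(pi / 6) / rig$focal_px)
  s30 <- estimate_normals(mk_surface(Z))
  expect_equal(median(s30$theta, na.rm = TRUE), 30, tolerance = 1)
  expect_true(all(s30$theta < 90, na.rm = TRUE))
})

test_that("stereo end-to-end: depth within 0.5 mm, angles within 2 deg", {
  rig <- stereo_rig()
  g <- function(x) (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  sc <- fx("sc_stereo_flat78",
           render_flat_full(ref_props_fx(), seed = 61, noise = NULL))
  s <- profile_surface(sc$left, sc$right, rig)
  ok <- !s$mask
  expect_lt(abs(median(s$height[ok]) - 78), 0.5)
  expect_lt(median(s$theta[ok], na.rm = TRUE), 2)
  zmap <- tilt_height_map(c(256, 256), full_px0, 20)
  sc2 <- render_scene(scene_spec(c(256, 256), ref_props_fx(),
                                 height_map = zmap, pixel_size0 = full_px0,
                                 noise = NULL, seed = 63))
  s2 <- profile_surface(sc2$left, sc2$right, rig)
  expect_lt(abs(median(s2$theta[!s2$mask], na.rm = TRUE) - 20), 2)
})

test_that("rig JSON round-trips", {
  rig <- stereo_rig(focal_px = 1234, baseline_mm = 4.5,
                    principal_point = c(100, 120))
  path <- tempfile(fileext = ".json")
  rig_write_json(rig, path)
  rig2 <- rig_read_json(path)
  expect_equal(rig2$focal_px, 1234)
  expect_equal(rig2$baseline_mm, 4.5)
  expect_equal(rig2$principal_point, c(100, 120))
  unlink(path)
})
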