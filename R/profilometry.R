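# Active-stereo surface estimation: flat-field correction, coarse-to-fine
# normalized-cross-correlation disparity matching, reprojection to a metric
# point cloud, cloud smoothing, and local plane-fit surface normals.

#' Stereo rig description
#'
#' Rectified pinhole stereo: identical focal length (px) for both cameras,
#' principal point, and a horizontal baseline.  Depth along the left
#' camera's optical axis is `Z = focal_px * baseline_mm / disparity`.
#'
#' @param focal_px focal length in pixels.
#' @param baseline_mm stereo baseline (mm).
#' @param principal_point c(row, col) of the principal point; defaults to
#'   the image center at matching time.
#' @param distortion radial distortion coefficients (images are assumed
#'   rectified; recorded for provenance).
#' @return a `stereo_rig` object.
#' @export
stereo_rig <- function(focal_px = 78 / 0.058, baseline_mm = 5,
                       principal_point = NULL, distortion = c(0, 0)) {
  stop_if_not_positive(focal_px, "focal_px")
  stop_if_not_positive(baseline_mm, "baseline_mm")
  structure(list(focal_px = focal_px, baseline_mm = baseline_mm,
                 principal_point = principal_point,
                 distortion = distortion),
            class = "stereo_rig")
}

#' Write / read a stereo rig as JSON
#' @param rig a [stereo_rig()]; `path` file path.
#' @return `rig_write_json` returns `path` invisibly; `rig_read_json` a
#'   `stereo_rig`.
#' @export
rig_write_json <- function(rig, path) {
  jsonlite::write_json(unclass(rig), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname rig_write_json
#' @export
rig_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stereo_rig(focal_px = x$focal_px, baseline_mm = x$baseline_mm,
             principal_point = x$principal_point,
             distortion = x$distortion)
}

#' Flat-field correction
#'
#' Divides the image by a heavy Gaussian blur of itself, removing slowly
#' varying illumination while preserving texture; the output mean is ~1
#' over the valid region.  Pixels where the blur vanishes are masked NA.
#'
#' @param image an [image_grid()] or numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels (default 55).
#' @return same class as `image`, flat-field corrected.
#' @export
flat_field <- function(image, sigma_px = 55) {
  stop_if_not_positive(sigma_px, "sigma_px")
  px <- if (inherits(image, "image_grid")) image$pixels else image
  bl <- gauss_blur(px, sigma = sigma_px)
  out <- px / bl
  out[!is.finite(out) | bl <= .Machine$double.eps] <- NA_real_
  if (inherits(image, "image_grid")) { image$pixels <- out; image } else out
}

# mean over a (2h+1) box via integral images (truncated at the image
# edge and normalized by the actual cell count); NA-free input assumed
box_mean <- function(m, h) {
  cs <- apply(rbind(0, m), 2, cumsum)
  top <- pmax(row(m) - h - 1L, 0L) + 1L
  bot <- pmin(row(m) + h, nrow(m)) + 1L
  vs <- matrix(cs[cbind(as.vector(bot), as.vector(col(m)))] -
                 cs[cbind(as.vector(top), as.vector(col(m)))],
               nrow(m), ncol(m))
  cnt_v <- matrix(bot - top, nrow(m), ncol(m))
  cs2 <- t(apply(cbind(0, vs), 1, cumsum))
  left <- pmax(col(m) - h - 1L, 0L) + 1L
  right <- pmin(col(m) + h, ncol(m)) + 1L
  hs <- matrix(cs2[cbind(as.vector(row(m)), as.vector(right))] -
                 cs2[cbind(as.vector(row(m)), as.vector(left))],
               nrow(m), ncol(m))
  cnt2 <- t(apply(cbind(0, cnt_v), 1, cumsum))
  cnt <- matrix(cnt2[cbind(as.vector(row(m)), as.vector(right))] -
                  cnt2[cbind(as.vector(row(m)), as.vector(left))],
                nrow(m), ncol(m))
  hs / cnt
}

# zero-mean NCC between left and right-shifted-by-d, block half-size h
ncc_at <- function(L, R, d, h) {
  W <- ncol(L)
  Rs <- matrix(NA_real_, nrow(L), W)
  if (d >= 0) {
    if (d < W) Rs[, (d + 1):W] <- R[, 1:(W - d)]
  } else {
    if (-d < W) Rs[, 1:(W + d)] <- R[, (1 - d):W]
  }
  valid <- !is.na(Rs)
  Rs[!valid] <- 0
  Lv <- L
  mL <- box_mean(Lv, h); mR <- box_mean(Rs, h)
  cLR <- box_mean(Lv * Rs, h) - mL * mR
  vL <- box_mean(Lv * Lv, h) - mL^2
  vR <- box_mean(Rs * Rs, h) - mR^2
  den <- sqrt(pmax(vL, 0) * pmax(vR, 0))
  ncc <- cLR / pmax(den, 1e-12)
  ncc[den <= 1e-12] <- -1
  ncc[!valid] <- -1
  ncc
}

mean_downsample2 <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
            m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)])
}

#' Coarse-to-fine NCC stereo matching
#'
#' Normalized cross-correlation block matching over an image pyramid: a
#' full disparity search at the coarsest level, +/-2 px refinement at each
#' finer level, and a final parabolic subpixel fit.  Confidence is the
#' NCC peak: pixels with peak below `min_ncc`, or whose coarse-level
#' secondary peak (at least 2 px from the primary) exceeds `peak_ratio *
#' primary`, are masked.  Inputs are assumed rectified; RGB arrays are
#' averaged to grayscale.
#'
#' @param left,right [image_grid()], matrix, or H x W x 3 array.
#' @param rig a [stereo_rig()].
#' @param levels pyramid levels (>= 1).
#' @param block_px odd NCC block size at every level.
#' @param z_range_mm plausible depth range defining the disparity search.
#' @param min_ncc,peak_ratio confidence thresholds.
#' @return list with `disparity` (px, NA where masked), `ncc` (peak
#'   value), `mask` (TRUE = invalid).
#' @export
match_stereo <- function(left, right, rig, levels = 3L, block_px = 11L,
                         z_range_mm = c(40, 150), min_ncc = 0.8,
                         peak_ratio = 0.8) {
  as_gray <- function(x) {
    if (inherits(x, "image_grid")) x <- x$pixels
    if (length(dim(x)) == 3) x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    x
  }
  L <- as_gray(left); R <- as_gray(right)
  stopifnot(all(dim(L) == dim(R)), block_px %% 2 == 1)
  fB <- rig$focal_px * rig$baseline_mm
  dmin <- floor(fB / max(z_range_mm)) - 1L
  dmax <- ceiling(fB / min(z_range_mm)) + 1L
  h <- (block_px - 1L) %/% 2L

  pyrL <- list(L); pyrR <- list(R)
  for (l in seq_len(levels - 1L)) {
    pyrL[[l + 1L]] <- mean_downsample2(pyrL[[l]])
    pyrR[[l + 1L]] <- mean_downsample2(pyrR[[l]])
  }

  disp <- NULL; ratio_mask <- NULL
  for (l in seq(levels, 1L)) {
    Ll <- pyrL[[l]]; Rl <- pyrR[[l]]
    sc <- 2^(l - 1L)
    if (is.null(disp)) {
      drange <- seq(floor(dmin / sc), ceiling(dmax / sc))
      d0 <- NULL
    } else {
      d0 <- 2 * resize_bilinear(disp, nrow(Ll), ncol(Ll))
      drange <- seq(floor(min(d0, na.rm = TRUE)) - 2L,
                    ceiling(max(d0, na.rm = TRUE)) + 2L)
    }
    best <- matrix(-Inf, nrow(Ll), ncol(Ll))
    bestd <- matrix(NA_real_, nrow(Ll), ncol(Ll))
    best_m1 <- matrix(NA_real_, nrow(Ll), ncol(Ll))   # ncc at bestd - 1
    best_p1 <- matrix(NA_real_, nrow(Ll), ncol(Ll))   # ncc at bestd + 1
    second <- matrix(-Inf, nrow(Ll), ncol(Ll))
    prev <- matrix(NA_real_, nrow(Ll), ncol(Ll))
    for (d in drange) {
      ncc <- ncc_at(Ll, Rl, d, h)
      ok <- if (is.null(d0)) TRUE else abs(d - d0) <= 2.5
      upd <- (ncc > best) & ok
      # secondary peak bookkeeping (>= 2 px from the primary)
      sec_upd <- (ncc > second) & !upd & ok &
        (is.na(bestd) | abs(d - bestd) >= 2)
      second[sec_upd] <- ncc[sec_upd]
      demote <- upd & is.finite(best) & abs(d - bestd) >= 2
      second[demote] <- best[demote]
      best_m1[upd] <- prev[upd]
      best[upd] <- ncc[upd]
      bestd[upd] <- d
      nxt <- !upd & !is.na(bestd) & (bestd == d - 1)
      best_p1[nxt] <- ncc[nxt]
      prev <- ncc
    }
    if (is.null(ratio_mask)) {
      ratio_mask <- is.finite(second) & (second > peak_ratio * best)
    }
    # subpixel parabola where both neighbours exist
    delta <- matrix(0, nrow(Ll), ncol(Ll))
    haveN <- !is.na(best_m1) & !is.na(best_p1)
    den <- best_m1 - 2 * best + best_p1
    good <- haveN & (den < -1e-12)
    delta[good] <- 0.5 * (best_m1[good] - best_p1[good]) / den[good]
    delta[abs(delta) > 1] <- 0
    disp <- bestd + delta
    disp[!is.finite(best)] <- NA_real_
    if (l == 1L) {
      mask <- is.na(disp) | best < min_ncc |
        resize_bilinear(ratio_mask * 1, nrow(Ll), ncol(Ll)) > 0.5
      disp[mask] <- NA_real_
      return(list(disparity = disp, ncc = best, mask = mask))
    }
  }
}

#' Reproject a disparity map to a metric point cloud
#'
#' `Z = f B / d` in the left-camera frame; `X`, `Y` follow from the
#' pinhole model.  Zero, negative, or missing disparities are masked.
#'
#' @param disparity disparity map (px).
#' @param rig a [stereo_rig()].
#' @return organized point cloud: list of matrices `X`, `Y`, `Z` (mm) and
#'   logical `mask` (TRUE = invalid).
#' @export
reproject <- function(disparity, rig) {
  bad <- !is.finite(disparity) | disparity <= 0
  Z <- rig$focal_px * rig$baseline_mm / disparity
  Z[bad] <- NA_real_
  pp <- rig$principal_point %||%
    c((nrow(disparity) + 1) / 2, (ncol(disparity) + 1) / 2)
  X <- (col(disparity) - pp[2]) * Z / rig$focal_px
  Y <- (row(disparity) - pp[1]) * Z / rig$focal_px
  list(X = X, Y = Y, Z = Z, mask = bad)
}

fill_na_1d <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(is.finite(v))
  if (length(ok) < 2) return(rep(if (length(ok)) v[ok] else NA_real_,
                                 length(v)))
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' Clean an organized point cloud into a smooth height map
#'
#' Three denoising stages on the depth channel: 2x2 spatial average
#' downsampling, Savitzky-Golay smoothing (default order 1, frame 31)
#' applied along rows then columns, and a smoothness-penalized surface
#' fit `(W + lambda L'L) z = W z_obs` (L = 5-point Laplacian, W = data
#' weights, zero on missing cells).  The fitted grid is bilinearly
#' upsampled back to pixel resolution.  All three stages leave planar
#' surfaces unchanged.
#'
#' @param cloud organized cloud from [reproject()].
#' @param rig the [stereo_rig()] (to rebuild X/Y at full resolution).
#' @param sg_order,sg_frame Savitzky-Golay polynomial order and frame.
#' @param lambda smoothness weight of the surface fit.
#' @return list with full-resolution `height` (= Z, mm), `X`, `Y`, `mask`.
#' @export
clean_cloud <- function(cloud, rig, sg_order = 1L, sg_frame = 31L,
                        lambda = 5) {
  Z <- cloud$Z
  if (mean(is.finite(Z)) < 0.2) stop("point cloud too sparse to clean")
  Zd <- mean_downsample2_na(Z)
  nr <- nrow(Zd); nc <- ncol(Zd)
  if (min(nr, nc) < sg_frame) {
    stop("grid smaller than the Savitzky-Golay frame; cloud too sparse")
  }
  obs <- is.finite(Zd)
  Zf <- Zd
  for (r in seq_len(nr)) Zf[r, ] <- fill_na_1d(Zf[r, ])
  for (c in seq_len(nc)) Zf[, c] <- fill_na_1d(Zf[, c])
  for (r in seq_len(nr)) {
    Zf[r, ] <- signal::sgolayfilt(Zf[r, ], p = sg_order, n = sg_frame)
  }
  for (c in seq_len(nc)) {
    Zf[, c] <- signal::sgolayfilt(Zf[, c], p = sg_order, n = sg_frame)
  }
  Zs <- gridfit_surface(Zf, obs, lambda)
  # downsampled cell i sits at original row 2i - 0.5; interpolate back on
  # those coordinates so planes are reproduced without a half-pixel skew
  height <- interp_grid(Zs, (seq_len(nrow(Z)) + 0.5) / 2,
                        (seq_len(ncol(Z)) + 0.5) / 2)
  pp <- rig$principal_point %||% c((nrow(Z) + 1) / 2, (ncol(Z) + 1) / 2)
  X <- (col(Z) - pp[2]) * height / rig$focal_px
  Y <- (row(Z) - pp[1]) * height / rig$focal_px
  # cells with no observed disparity are interpolated for continuity but
  # flagged invalid
  mask <- resize_bilinear(1 - obs, nrow(Z), ncol(Z)) > 0.5
  list(height = height, X = X, Y = Y, mask = mask)
}

mean_downsample2_na <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  s <- array(c(m[seq(1, nr, 2), seq(1, nc, 2)], m[seq(2, nr, 2), seq(1, nc, 2)],
               m[seq(1, nr, 2), seq(2, nc, 2)], m[seq(2, nr, 2), seq(2, nc, 2)]),
             c(nr / 2, nc / 2, 4))
  cnt <- apply(is.finite(s), c(1, 2), sum)
  s[!is.finite(s)] <- 0
  out <- apply(s, c(1, 2), sum) / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Regularized least-squares gridding: data-fidelity on observed cells,
# Laplacian smoothness everywhere.  Planes lie in the Laplacian null
# space, so they are reproduced exactly.
gridfit_surface <- function(Zf, obs, lambda) {
  nr <- nrow(Zf); nc <- ncol(Zf)
  n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  ii <- c(); jj <- c(); xx <- c()
  rmid <- 2:(nr - 1); cmid <- 2:(nc - 1)
  ctr <- as.vector(outer(rmid, (cmid - 1L) * nr, `+`))
  ii <- rep(seq_along(ctr), 5)
  jj <- c(ctr, ctr - 1L, ctr + 1L, ctr - nr, ctr + nr)
  xx <- c(rep(-4, length(ctr)), rep(1, 4 * length(ctr)))
  Lp <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(length(ctr), n))
  # unobserved cells carry a tiny weight toward the gap-filled field so
  # corner cells outside every Laplacian stencil stay determined
  w <- ifelse(as.vector(obs), 1, 1e-6)
  Wd <- Matrix::Diagonal(n, w)
  A <- Wd + lambda * Matrix::crossprod(Lp)
  b <- w * as.vector(Zf)
  z <- Matrix::solve(A, b)
  matrix(as.numeric(z), nr, nc)
}

#' Surface normals and polar angle from a cleaned surface
#'
#' Fits a local plane at every pixel through the point itself and its
#' `k` nearest (in 3D) of the 8 grid neighbours, by least squares in
#' `z = a x + b y + c`; the unit normal is `(a, b, -1)/|.|`, oriented
#' toward the camera, and the polar angle theta is the angle between the
#' normal and the optical axis.  Degenerate neighbourhoods are masked.
#'
#' @param surface output of [clean_cloud()] (or any list with `X`, `Y`,
#'   `height` matrices).
#' @param k neighbour count used in the fit (3..8, default 6).
#' @return a `surface_map`: `height` (mm), `normals` (list nx/ny/nz),
#'   `theta` (deg), `mask`.
#' @export
estimate_normals <- function(surface, k = 6L) {
  stopifnot(k >= 3, k <= 8)
  X <- surface$X; Y <- surface$Y; Z <- surface$height
  nr <- nrow(Z); nc <- ncol(Z)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  dX <- vector("list", 8); dY <- vector("list", 8); dZ <- vector("list", 8)
  D <- vector("list", 8)
  for (i in 1:8) {
    o <- offs[[i]]
    dX[[i]] <- shift_mat(X, o[1], o[2]) - X
    dY[[i]] <- shift_mat(Y, o[1], o[2]) - Y
    dZ[[i]] <- shift_mat(Z, o[1], o[2]) - Z
    D[[i]] <- sqrt(dX[[i]]^2 + dY[[i]]^2 + dZ[[i]]^2)
    D[[i]][!is.finite(D[[i]])] <- Inf
  }
  # keep the k nearest of the 8 neighbours: drop the (8 - k) farthest
  drop_n <- 8L - as.integer(k)
  W <- lapply(D, function(d) matrix(1, nr, nc))
  if (drop_n > 0) {
    Darr <- array(unlist(D), c(nr, nc, 8))
    for (pass in seq_len(drop_n)) {
      cur <- array(unlist(W), c(nr, nc, 8))
      masked <- ifelse(cur > 0, Darr, -Inf)
      mx <- apply(masked, c(1, 2), which.max)
      for (i in 1:8) W[[i]][mx == i] <- 0
    }
  }
  Sw <- matrix(0, nr, nc)
  Sx <- Sy <- Sz <- Sxx <- Syy <- Sxy <- Sxz <- Syz <- matrix(0, nr, nc)
  for (i in 1:8) {
    w <- W[[i]]; w[!is.finite(D[[i]])] <- 0
    x <- ifelse(w > 0, dX[[i]], 0); y <- ifelse(w > 0, dY[[i]], 0)
    z <- ifelse(w > 0, dZ[[i]], 0)
    Sw <- Sw + w
    Sx <- Sx + x; Sy <- Sy + y; Sz <- Sz + z
    Sxx <- Sxx + x * x; Syy <- Syy + y * y; Sxy <- Sxy + x * y
    Sxz <- Sxz + x * z; Syz <- Syz + y * z
  }
  Sw <- Sw + 1   # the centre point contributes (0,0,0)
  # normal equations for z = a x + b y + c over centred coordinates
  det <- Sxx * (Syy * Sw - Sy * Sy) - Sxy * (Sxy * Sw - Sy * Sx) +
    Sx * (Sxy * Sy - Syy * Sx)
  scale2 <- pmax(Sxx + Syy, .Machine$double.eps)^1.5 * pmax(Sw, 1)
  degenerate <- abs(det) < 1e-10 * scale2
  a <- (Sxz * (Syy * Sw - Sy * Sy) - Sxy * (Syz * Sw - Sy * Sz) +
          Sx * (Syz * Sy - Syy * Sz)) / det
  b <- (Sxx * (Syz * Sw - Sz * Sy) - Sxz * (Sxy * Sw - Sy * Sx) +
          Sx * (Sxy * Sz - Syz * Sx)) / det
  nrm <- sqrt(a^2 + b^2 + 1)
  nx <- a / nrm; ny <- b / nrm; nz <- -1 / nrm
  theta <- acos(pmin(1 / nrm, 1)) * 180 / pi
  bad <- degenerate | !is.finite(theta)
  if (!is.null(surface$mask)) bad <- bad | surface$mask
  theta[bad] <- NA_real_
  structure(list(height = Z,
                 normals = list(nx = nx, ny = ny, nz = nz),
                 theta = theta, mask = bad),
            class = "surface_map")
}

#' Full profilometry chain: stereo pair to surface map
#'
#' Flat-fields both images, matches, reprojects, cleans, and estimates
#' normals.
#'
#' @param left,right stereo images (matrix or H x W x 3 array).
#' @param rig a [stereo_rig()].
#' @param flat_sigma flat-field Gaussian sd (px).
#' @param k normal-estimation neighbour count.
#' @param ... passed to [match_stereo()].
#' @return a `surface_map` (see [estimate_normals()]).
#' @export
profile_surface <- function(left, right, rig, flat_sigma = 55, k = 6L, ...) {
  as_gray <- function(x) {
    if (inherits(x, "image_grid")) x <- x$pixels
    if (length(dim(x)) == 3) x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    x
  }
  Lf <- flat_field(as_gray(left), flat_sigma)
  Rf <- flat_field(as_gray(right), flat_sigma)
  m <- match_stereo(Lf, Rf, rig, ...)
  cloud <- reproject(m$disparity, rig)
  surf <- clean_cloud(cloud, rig)
  estimate_normals(surf, k = k)
}
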