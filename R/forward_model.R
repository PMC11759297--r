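# Forward model: spatial-frequency-resolved diffuse reflectance of a
# semi-infinite turbid medium, and the lookup table (LUT) that maps the
# calibrated (Rd_DC, Rd_AC) pair back to optical properties.

#' Optical properties of a turbid medium
#'
#' @param mu_a absorption coefficient (mm^-1), strictly positive.
#' @param mu_s_prime reduced scattering coefficient (mm^-1), strictly
#'   positive.
#' @return an `optical_properties` object (list with `mu_a`, `mu_s_prime`).
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  stop_if_not_positive(mu_a, "mu_a")
  stop_if_not_positive(mu_s_prime, "mu_s_prime")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime),
            class = "optical_properties")
}

#' Diffuse-reflectance forward model
#'
#' The default model is the standard diffusion approximation of
#' spatial-frequency-domain reflectance for a semi-infinite homogeneous
#' medium with an extrapolated (partial-current) boundary:
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)
#'   (\mu_{eff}'/\mu_{tr} + 3A)}}
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'}, \eqn{a' = \mu_s'/\mu_{tr}},
#' \eqn{\mu_{eff}' = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}} and the
#' proportionality constant \eqn{A = (1 - R_{eff})/(2(1 + R_{eff}))} from
#' the Groenhuis polynomial fit for the effective internal reflection
#' coefficient at refractive index ratio n.
#'
#' An `imported_table` model wraps an externally computed
#' \eqn{R_d(f_x; \mu_a, \mu_s')} table (e.g. from published Monte Carlo
#' simulations) and interpolates it trilinearly.
#'
#' @param kind `"diffusion_approximation"` or `"imported_table"`.
#' @param refractive_index_ratio relative refractive index of the medium
#'   (tissue-like default 1.4).
#' @param table for `imported_table`: list with ascending vectors `fx`,
#'   `mu_a`, `mu_s_prime` and array `rd` of dim (fx, mu_a, mu_s_prime).
#' @return a `reflectance_model` object.
#' @export
reflectance_model <- function(kind = c("diffusion_approximation",
                                       "imported_table"),
                              refractive_index_ratio = 1.4,
                              table = NULL) {
  kind <- match.arg(kind)
  stop_if_not_positive(refractive_index_ratio, "refractive_index_ratio")
  if (kind == "imported_table") {
    if (is.null(table)) stop("imported_table model requires 'table'")
    stopifnot(is.list(table),
              all(c("fx", "mu_a", "mu_s_prime", "rd") %in% names(table)),
              !is.unsorted(table$fx), !is.unsorted(table$mu_a),
              !is.unsorted(table$mu_s_prime),
              identical(dim(table$rd),
                        c(length(table$fx), length(table$mu_a),
                          length(table$mu_s_prime))))
  }
  structure(list(kind = kind,
                 refractive_index_ratio = refractive_index_ratio,
                 table = table),
            class = "reflectance_model")
}

# Groenhuis effective reflection coefficient and boundary constant A.
boundary_constant_A <- function(n) {
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 - reff) / (2 * (1 + reff))
}

#' Diffuse reflectance at a spatial frequency
#'
#' @param fx spatial frequency (mm^-1), vectorized, >= 0.
#' @param props [optical_properties()].
#' @param model [reflectance_model()]; default diffusion approximation with
#'   n = 1.4.
#' @return diffuse reflectance fraction(s) in (0, 1).
#' @export
rd_at_frequency <- function(fx, props, model = reflectance_model()) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(!is.finite(fx)) || any(fx < 0)) {
    stop("'fx' must be finite and >= 0")
  }
  if (model$kind == "imported_table") {
    return(rd_from_table(fx, props, model$table))
  }
  mu_a <- props$mu_a
  mu_sp <- props$mu_s_prime
  mu_tr <- mu_a + mu_sp
  a_prime <- mu_sp / mu_tr
  A <- boundary_constant_A(model$refractive_index_ratio)
  mu_eff_p <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2)
  x <- mu_eff_p / mu_tr
  (3 * A * a_prime) / ((x + 1) * (x + 3 * A))
}

# Trilinear interpolation into an imported Rd table.
rd_from_table <- function(fx, props, tab) {
  interp1_idx <- function(grid, v) {
    if (v < grid[1] || v > grid[length(grid)]) {
      stop("query outside imported table range")
    }
    i <- findInterval(v, grid, rightmost.closed = TRUE)
    i <- min(i, length(grid) - 1L)
    w <- (v - grid[i]) / (grid[i + 1] - grid[i])
    list(i = i, w = w)
  }
  ia <- interp1_idx(tab$mu_a, props$mu_a)
  is_ <- interp1_idx(tab$mu_s_prime, props$mu_s_prime)
  vapply(fx, function(f) {
    if_ <- interp1_idx(tab$fx, f)
    acc <- 0
    for (df in 0:1) for (da in 0:1) for (ds in 0:1) {
      w <- (if (df) if_$w else 1 - if_$w) *
           (if (da) ia$w else 1 - ia$w) *
           (if (ds) is_$w else 1 - is_$w)
      acc <- acc + w * tab$rd[if_$i + df, ia$i + da, is_$i + ds]
    }
    acc
  }, numeric(1))
}

#' Build an optical-property lookup table
#'
#' Tabulates the forward model on a (mu_a, mu_s') grid.  The DC entry is
#' `Rd(0)`; the AC entry is the sum of `Rd(f)` over the AC band
#' frequencies (default 0.1 to 0.5 mm^-1 in 0.1 mm^-1 increments),
#' mirroring how the AC modulation band is summed from the PSD.
#'
#' @param mu_a_grid,mu_s_grid ascending grids (mm^-1), >= 4 points each.
#' @param model [reflectance_model()].
#' @param ac_frequencies AC band frequencies (mm^-1).
#' @return a `property_lut` object with matrices `rd_dc`, `rd_ac` indexed
#'   `[mu_a, mu_s]`.
#' @export
build_lut <- function(mu_a_grid = default_mu_a_grid(),
                      mu_s_grid = default_mu_s_grid(),
                      model = reflectance_model(),
                      ac_frequencies = seq(0.1, 0.5, by = 0.1)) {
  check_grid <- function(g, name) {
    if (length(g) < 4 || is.unsorted(g, strictly = TRUE)) {
      stop(sprintf("'%s' must be strictly ascending with >= 4 points", name))
    }
    stop_if_not_positive(g, name)
  }
  check_grid(mu_a_grid, "mu_a_grid")
  check_grid(mu_s_grid, "mu_s_grid")
  stop_if_not_positive(ac_frequencies, "ac_frequencies")
  rd_dc <- matrix(NA_real_, length(mu_a_grid), length(mu_s_grid))
  rd_ac <- matrix(NA_real_, length(mu_a_grid), length(mu_s_grid))
  for (j in seq_along(mu_s_grid)) {
    for (i in seq_along(mu_a_grid)) {
      p <- optical_properties(mu_a_grid[i], mu_s_grid[j])
      rd_dc[i, j] <- rd_at_frequency(0, p, model)
      rd_ac[i, j] <- sum(rd_at_frequency(ac_frequencies, p, model))
    }
  }
  structure(list(mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid,
                 rd_dc = rd_dc, rd_ac = rd_ac,
                 ac_frequencies = ac_frequencies,
                 model_kind = model$kind,
                 refractive_index_ratio = model$refractive_index_ratio),
            class = "property_lut")
}

#' Default LUT grids
#'
#' Log-spaced grids covering the tissue-phantom range: mu_a in
#' \[0.002, 0.12\] mm^-1 and mu_s' in \[0.3, 3.0\] mm^-1, 60 points each.
#' @return numeric vector.
#' @export
default_mu_a_grid <- function() exp(seq(log(0.002), log(0.12), length.out = 60))

#' @rdname default_mu_a_grid
#' @export
default_mu_s_grid <- function() exp(seq(log(0.3), log(3.0), length.out = 60))

#' Invert a lookup table at measured reflectance values
#'
#' Finds the optical properties whose forward image matches the query
#' `(rd_dc, rd_ac)` pair by piecewise-linear (barycentric) interpolation on
#' the triangulated forward grid image.  Queries outside the attainable
#' gamut raise an error unless `clamp = TRUE`, in which case they are
#' mapped to the nearest grid node in reflectance space and flagged.
#'
#' @param rd_dc,rd_ac calibrated diffuse reflectance values (vectorized,
#'   equal length).
#' @param lut a `property_lut` from [build_lut()].
#' @param clamp if TRUE, out-of-gamut queries return the nearest-node
#'   properties instead of erroring.
#' @return list with numeric vectors `mu_a`, `mu_s_prime` and logical
#'   `clamped`.
#' @export
invert_lut <- function(rd_dc, rd_ac, lut, clamp = FALSE) {
  stopifnot(inherits(lut, "property_lut"), length(rd_dc) == length(rd_ac))
  n <- length(rd_dc)
  na_g <- length(lut$mu_a_grid); ns_g <- length(lut$mu_s_grid)
  # scale the two reflectance axes to comparable units before nearest-node
  # searches so neither dominates the distance
  sx <- diff(range(lut$rd_dc)); sy <- diff(range(lut$rd_ac))
  px <- as.vector(lut$rd_dc) / sx
  py <- as.vector(lut$rd_ac) / sy
  qx <- rd_dc / sx; qy <- rd_ac / sy
  mu_a_out <- rep(NA_real_, n); mu_s_out <- rep(NA_real_, n)
  clamped <- rep(FALSE, n)

  # triangles adjacent to node (i, j): the 2 triangles of each of the up to
  # 4 surrounding cells
  tri_interp <- function(i1, j1, i2, j2, i3, j3, qxv, qyv) {
    x1 <- lut$rd_dc[i1, j1] / sx; y1 <- lut$rd_ac[i1, j1] / sy
    x2 <- lut$rd_dc[i2, j2] / sx; y2 <- lut$rd_ac[i2, j2] / sy
    x3 <- lut$rd_dc[i3, j3] / sx; y3 <- lut$rd_ac[i3, j3] / sy
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) return(NULL)
    l1 <- ((y2 - y3) * (qxv - x3) + (x3 - x2) * (qyv - y3)) / det
    l2 <- ((y3 - y1) * (qxv - x3) + (x1 - x3) * (qyv - y3)) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    if (l1 < tol || l2 < tol || l3 < tol) return(NULL)
    # interpolate in log property space (grids are log-spaced)
    la <- l1 * log(lut$mu_a_grid[i1]) + l2 * log(lut$mu_a_grid[i2]) +
      l3 * log(lut$mu_a_grid[i3])
    ls <- l1 * log(lut$mu_s_grid[j1]) + l2 * log(lut$mu_s_grid[j2]) +
      l3 * log(lut$mu_s_grid[j3])
    c(exp(la), exp(ls))
  }

  cell_tris <- function(i, j) {
    # two triangles of cell with lower-left node (i, j)
    list(c(i, j, i + 1L, j, i, j + 1L),
         c(i + 1L, j, i + 1L, j + 1L, i, j + 1L))
  }

  solve_query <- function(qxv, qyv) {
    d2 <- (px - qxv)^2 + (py - qyv)^2
    ord <- order(d2)
    # try cells around the nearest few nodes first, then fall back to a
    # full scan before declaring out of gamut
    seen <- new.env(parent = emptyenv())
    try_cells <- function(cells) {
      for (cell in cells) {
        key <- paste(cell[1], cell[2])
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        for (tr in cell_tris(cell[1], cell[2])) {
          r <- tri_interp(tr[1], tr[2], tr[3], tr[4], tr[5], tr[6],
                          qxv, qyv)
          if (!is.null(r)) return(r)
        }
      }
      NULL
    }
    for (nodek in ord[seq_len(min(8L, length(ord)))]) {
      i <- (nodek - 1L) %% na_g + 1L
      j <- (nodek - 1L) %/% na_g + 1L
      cells <- list()
      for (ci in max(1L, i - 1L):min(na_g - 1L, i)) {
        for (cj in max(1L, j - 1L):min(ns_g - 1L, j)) {
          cells[[length(cells) + 1L]] <- c(ci, cj)
        }
      }
      r <- try_cells(cells)
      if (!is.null(r)) return(r)
    }
    # exhaustive fallback
    cells <- list()
    for (ci in seq_len(na_g - 1L)) for (cj in seq_len(ns_g - 1L)) {
      cells[[length(cells) + 1L]] <- c(ci, cj)
    }
    try_cells(cells)
  }

  for (k in seq_len(n)) {
    if (!is.finite(qx[k]) || !is.finite(qy[k])) next
    r <- solve_query(qx[k], qy[k])
    if (is.null(r)) {
      if (!clamp) {
        stop(sprintf(paste0("query (rd_dc = %.4g, rd_ac = %.4g) is outside ",
                            "the LUT gamut; use clamp = TRUE to map to the ",
                            "nearest node"), rd_dc[k], rd_ac[k]))
      }
      d2 <- (px - qx[k])^2 + (py - qy[k])^2
      nodek <- which.min(d2)
      i <- (nodek - 1L) %% na_g + 1L
      j <- (nodek - 1L) %/% na_g + 1L
      mu_a_out[k] <- lut$mu_a_grid[i]
      mu_s_out[k] <- lut$mu_s_grid[j]
      clamped[k] <- TRUE
    } else {
      mu_a_out[k] <- r[1]
      mu_s_out[k] <- r[2]
    }
  }
  list(mu_a = mu_a_out, mu_s_prime = mu_s_out, clamped = clamped)
}

#' Write / read a lookup table as plain text
#'
#' The table itself is a CSV with columns `mu_a`, `mu_s_prime`, `rd_dc`,
#' `rd_ac`; a JSON sidecar (`<path>.json`) records the model kind, the
#' refractive index ratio and the AC band frequencies.
#'
#' @param lut a `property_lut`.
#' @param path CSV output path.
#' @return `lut_write_csv` returns `path` invisibly; `lut_read_csv`
#'   returns a `property_lut`.
#' @export
lut_write_csv <- function(lut, path) {
  stopifnot(inherits(lut, "property_lut"))
  grid <- expand.grid(mu_a = lut$mu_a_grid, mu_s_prime = lut$mu_s_grid)
  df <- data.frame(mu_a = grid$mu_a, mu_s_prime = grid$mu_s_prime,
                   rd_dc = as.vector(lut$rd_dc),
                   rd_ac = as.vector(lut$rd_ac))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model_kind = lut$model_kind,
               refractive_index_ratio = lut$refractive_index_ratio,
               ac_frequencies = lut$ac_frequencies)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lut_write_csv
#' @export
lut_read_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mu_a_grid <- sort(unique(df$mu_a))
  mu_s_grid <- sort(unique(df$mu_s_prime))
  o <- order(df$mu_s_prime, df$mu_a)
  structure(list(mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid,
                 rd_dc = matrix(df$rd_dc[o], length(mu_a_grid)),
                 rd_ac = matrix(df$rd_ac[o], length(mu_a_grid)),
                 ac_frequencies = as.numeric(meta$ac_frequencies),
                 model_kind = meta$model_kind,
                 refractive_index_ratio = meta$refractive_index_ratio),
            class = "property_lut")
}
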