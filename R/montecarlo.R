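# Desk-scale photon Monte Carlo for a semi-infinite homogeneous medium.
# This is a validation tool for the diffusion-approximation forward model,
# not part of the measurement pipeline: Henyey-Greenstein (or isotropic)
# scattering, weighted absorption, Fresnel internal reflection at the
# mismatched boundary, Russian roulette termination.  Vectorized over
# photons so 1e6 photons run in seconds to minutes.

#' Monte Carlo spatially resolved diffuse reflectance
#'
#' Simulates a pencil beam normally incident on a semi-infinite slab with
#' relative refractive index `n` and returns the diffuse reflectance at
#' the requested spatial frequencies,
#' \eqn{R_d(f_x) = \sum_i w_i \cos(2\pi f_x x_i) / N}, where \eqn{(x_i,
#' w_i)} are exit positions and weights.  Specular reflection at entry is
#' removed before launch, matching the diffusion model's convention.
#'
#' @param props [optical_properties()]; `mu_s_prime` is converted to the
#'   scattering coefficient `mu_s = mu_s_prime / (1 - g)`.
#' @param fx spatial frequencies (mm^-1).
#' @param n_photons number of photons (default 1e6).
#' @param n relative refractive index (default 1.4).
#' @param g Henyey-Greenstein anisotropy (0 = isotropic; tissue ~0.9).
#'   Spatially resolved remission at sub-transport scales is
#'   phase-function dependent, so high spatial frequencies are probed
#'   more faithfully with a realistic g.
#' @param seed RNG seed (local to the call).
#' @param chunk photons per vectorized batch.
#' @return numeric vector of Rd values, one per `fx`.
#' @export
mc_reflectance <- function(props, fx = 0, n_photons = 1e6, n = 1.4,
                           g = 0, seed = NULL, chunk = 250000L) {
  stopifnot(inherits(props, "optical_properties"), g >= 0, g < 1)
  with_seed(seed, {
    mu_a <- props$mu_a
    mu_s <- props$mu_s_prime / (1 - g)
    mu_t <- mu_a + mu_s
    albedo <- mu_s / mu_t
    crit_cos <- sqrt(max(0, 1 - (1 / n)^2))  # cos of critical angle
    acc <- numeric(length(fx))
    launched <- 0L
    while (launched < n_photons) {
      m <- min(chunk, n_photons - launched)
      launched <- launched + m
      # state: position (x, z), direction (ux, uy, uz), weight
      x <- numeric(m); z <- numeric(m)
      ux <- numeric(m); uy <- numeric(m); uz <- rep(1, m)
      w <- rep(1, m)
      alive <- rep(TRUE, m)
      while (any(alive)) {
        idx <- which(alive)
        s <- -log(stats::runif(length(idx))) / mu_t
        zi <- z[idx]; uzi <- uz[idx]
        # does the step cross the surface z = 0 going up?
        hits <- uzi < 0 & (zi + s * uzi) < 0
        if (any(hits)) {
          h <- idx[hits]
          sb <- -z[h] / uz[h]           # distance to boundary
          xb <- x[h] + sb * ux[h]
          # Fresnel transmission for unpolarized light at internal angle
          ci <- -uz[h]                  # cos incident (internal)
          exits <- ci > crit_cos
          if (any(exits)) {
            he <- h[exits]
            cie <- ci[exits]
            st2 <- n^2 * (1 - cie^2)    # sin^2 of transmitted angle
            ct <- sqrt(pmax(0, 1 - st2))
            rs <- ((n * cie - ct) / (n * cie + ct))^2
            rp <- ((n * ct - cie) / (n * ct + cie))^2
            R <- 0.5 * (rs + rp)
            out <- stats::runif(length(he)) > R
            if (any(out)) {
              ho <- he[out]
              wexit <- w[ho]
              xe <- xb[exits][out]
              for (k in seq_along(fx)) {
                acc[k] <- acc[k] + sum(wexit * cos(2 * pi * fx[k] * xe))
              }
              alive[ho] <- FALSE
            }
          }
          # photons that stayed inside (total internal reflection or
          # Fresnel-reflected): mirror at the boundary
          hin <- h[alive[h]]
          if (length(hin)) {
            sb_in <- -z[hin] / uz[hin]
            srem <- s[match(hin, idx)] - sb_in
            x[hin] <- x[hin] + s[match(hin, idx)] * ux[hin]
            z[hin] <- srem * (-uz[hin])     # reflected continuation
            uz[hin] <- -uz[hin]
          }
        }
        nh <- idx[!hits]
        if (length(nh)) {
          snh <- s[match(nh, idx)]
          x[nh] <- x[nh] + snh * ux[nh]
          z[nh] <- z[nh] + snh * uz[nh]
        }
        # absorb and scatter isotropically at the interaction site
        sc <- which(alive)
        if (!length(sc)) break
        w[sc] <- w[sc] * albedo
        phi <- 2 * pi * stats::runif(length(sc))
        if (g == 0) {
          cz <- 2 * stats::runif(length(sc)) - 1
          sz <- sqrt(pmax(0, 1 - cz^2))
          ux[sc] <- sz * cos(phi); uy[sc] <- sz * sin(phi); uz[sc] <- cz
        } else {
          # Henyey-Greenstein deflection about the current direction
          u <- stats::runif(length(sc))
          ct <- (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * u))^2) / (2 * g)
          ct <- pmin(1, pmax(-1, ct))
          st <- sqrt(1 - ct^2)
          uxs <- ux[sc]; uys <- uy[sc]; uzs <- uz[sc]
          near_pole <- abs(uzs) > 0.99999
          den <- sqrt(pmax(1 - uzs^2, 1e-20))
          nux <- st * (uxs * uzs * cos(phi) - uys * sin(phi)) / den +
            uxs * ct
          nuy <- st * (uys * uzs * cos(phi) + uxs * sin(phi)) / den +
            uys * ct
          nuz <- -den * st * cos(phi) + uzs * ct
          nux[near_pole] <- (st * cos(phi))[near_pole]
          nuy[near_pole] <- (st * sin(phi))[near_pole]
          nuz[near_pole] <- (sign(uzs) * ct)[near_pole]
          nn <- sqrt(nux^2 + nuy^2 + nuz^2)
          ux[sc] <- nux / nn; uy[sc] <- nuy / nn; uz[sc] <- nuz / nn
        }
        # Russian roulette on low weights
        low <- sc[w[sc] < 1e-4]
        if (length(low)) {
          keep <- stats::runif(length(low)) < 0.1
          w[low[keep]] <- w[low[keep]] * 10
          alive[low[!keep]] <- FALSE
        }
      }
    }
    acc / n_photons
  })
}
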