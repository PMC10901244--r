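# CW diffusion forward solver for semi-infinite N-layered media.
#
# The fluence is expanded over the roots of J0 in a cylinder of radius
# R + z_b (finite Hankel transform); for each transverse eigenvalue s the
# remaining 1D two-point problem in depth is solved by a downward
# admittance recursion through the stack, written in tanh form so that it
# stays finite for arbitrarily large s. The detected signal is the outward
# flux at the surface (Fick's law).

.ln_cache <- new.env(parent = emptyenv())

.bessel_roots <- function(n) {
  have <- .ln_cache$roots
  if (!is.null(have) && length(have$alpha) >= n)
    return(list(alpha = have$alpha[1:n], j1sq = have$j1sq[1:n]))
  k <- seq_len(max(n, 512L))
  x <- (k - 0.25) * pi                     # McMahon first guess
  for (i in 1:4) x <- x + besselJ(x, 0) / besselJ(x, 1)
  out <- list(alpha = x, j1sq = besselJ(x, 1)^2)
  .ln_cache$roots <- out
  list(alpha = out$alpha[1:n], j1sq = out$j1sq[1:n])
}

# J0(s_n * rho) for a given effective radius; memoised, these depend only
# on geometry and are reused across the thousands of absorption updates a
# time series implies.
.j0_factors <- function(rprime, rho, n) {
  key <- sprintf("%.10g|%.10g|%d", rprime, rho, n)
  hit <- .ln_cache[[key]]
  if (!is.null(hit)) return(hit)
  br <- .bessel_roots(n)
  s <- br$alpha / rprime
  out <- list(s = s, w = besselJ(s * rho, 0) / (pi * rprime^2 * br$j1sq))
  assign(key, out, envir = .ln_cache)
  out
}

#' Effective reflection coefficient of a refractive-index-mismatched surface
#'
#' Angular integrals of the unpolarised Fresnel reflectance (fluence and
#' flux moments) combined into the effective coefficient used by the
#' extrapolated-boundary condition, \eqn{R_{eff} = (R_\phi + R_j)/(2 -
#' R_\phi + R_j)}.
#'
#' @param n_in refractive index of the turbid medium.
#' @param n_out refractive index of the outer medium (default 1, air).
#' @return A number in \[0, 1); exactly 0 for matched indices.
#' @export
#' @examples
#' effective_reflection(1.33, 1.0)
effective_reflection <- function(n_in, n_out = 1.0) {
  if (!is.numeric(n_in) || !is.numeric(n_out) || n_in <= 0 || n_out <= 0)
    stop("refractive indices must be positive")
  if (abs(n_in - n_out) < 1e-12) return(0)
  m <- n_out / n_in
  rf <- function(theta) {           # unpolarised Fresnel, from inside
    st <- sin(theta); ct <- cos(theta)
    r <- numeric(length(theta))
    tir <- st >= m                  # total internal reflection
    r[tir] <- 1
    if (any(!tir)) {
      sto <- st[!tir] / m           # Snell; angle in outer medium
      cto <- sqrt(pmax(0, 1 - sto^2))
      ci <- ct[!tir]
      rs <- ((n_in * ci - n_out * cto) / (n_in * ci + n_out * cto))^2
      rp <- ((n_in * cto - n_out * ci) / (n_in * cto + n_out * ci))^2
      r[!tir] <- (rs + rp) / 2
    }
    r
  }
  rphi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                           0, pi / 2, rel.tol = 1e-10)$value
  rj <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                         0, pi / 2, rel.tol = 1e-10)$value
  (rphi + rj) / (2 - rphi + rj)
}

# extrapolation length z_b = 2 D (1 + Reff) / (1 - Reff)
.zb <- function(D, n_in, n_out) {
  reff <- effective_reflection(n_in, n_out)
  2 * D * (1 + reff) / (1 - reff)
}

#' Closed-form CW reflectance of a homogeneous semi-infinite medium
#'
#' Isotropic point source at depth `z0 = 1/musp`, extrapolated boundary at
#' `-z_b`, detector modelled as the outward flux at the surface. Serves as
#' the homogeneous limit of [layered_reflectance()].
#'
#' @param mua absorption coefficient, mm^-1 (>= 0).
#' @param musp reduced scattering coefficient, mm^-1 (> 0).
#' @param n_in,n_out refractive indices inside/outside.
#' @param rho source-detector distance, mm (> 0).
#' @return Reflectance (proportional units, per unit source power), mm^-2.
#' @export
#' @examples
#' semi_infinite_reflectance(0.018, 1.9, 1.33, 1.0, 30)
semi_infinite_reflectance <- function(mua, musp, n_in = 1.33, n_out = 1.0, rho) {
  if (!is.numeric(musp) || musp <= 0) stop("'musp' must be positive")
  if (!is.numeric(rho) || any(rho <= 0)) stop("'rho' must be positive")
  if (!is.numeric(mua) || mua < 0) stop("'mua' must be nonnegative")
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  zb <- .zb(D, n_in, n_out)
  mueff <- sqrt(mua / D)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

# depth-domain kernel of the layered Green's function: for transverse
# eigenvalues s (vector), the outward surface flux per unit source.
.flux_kernel <- function(s, mua, musp, d, D, z0, zb) {
  nl <- length(mua)
  g1 <- sqrt((mua[1] + D[1] * s^2) / D[1])
  if (nl == 1L) {
    # outward flux of source + (negative) image: slopes add at the surface
    e1 <- exp(-g1 * z0)
    e2 <- exp(-g1 * (z0 + 2 * zb))
    return((e1 + e2) / 2)
  }
  # admittance looking down from the top of layer 2
  gN <- sqrt((mua[nl] + D[nl] * s^2) / D[nl])
  Y <- D[nl] * gN
  if (nl > 2L) for (j in (nl - 1L):2L) {
    gj <- sqrt((mua[j] + D[j] * s^2) / D[j])
    tj <- tanh(gj * d[j])
    Dg <- D[j] * gj
    Y <- Dg * (Dg * tj + Y) / (Dg + Y * tj)
  }
  d1 <- d[1]
  a <- g1 * zb; b <- g1 * (d1 - z0); cc <- a + b + g1 * z0
  # cosh(a)cosh(b)/cosh(c) and cosh(a)sinh(b)/cosh(c), overflow-free
  base <- exp(-g1 * z0) / (2 * (1 + exp(-2 * cc)))
  c1 <- base * (1 + exp(-2 * a)) * (1 + exp(-2 * b))
  c2 <- base * (1 + exp(-2 * a)) * (1 - exp(-2 * b))
  q <- Y / D[1]
  g1 * (c1 + q / g1 * c2) / (g1 + q * tanh(cc))
}

#' CW reflectance of a semi-infinite N-layered medium
#'
#' Finite-Hankel (Bessel-root) expansion of the layered diffusion
#' Green's function; per-layer 1D solutions are coupled by continuity of
#' fluence and normal flux at the interfaces, and the detector reading is
#' the outward flux at the surface. The series is summed until the largest
#' term in a trailing block falls below `tol` times the partial sum.
#'
#' @param medium a [layered_medium()].
#' @param rho source-detector distance, mm; must be below the cylinder
#'   radius.
#' @param tol relative tolerance on the series tail.
#' @param max_terms term budget of the Bessel-root expansion.
#' @return An object of class `forward_solution`: list with `reflectance`,
#'   `rho`, `n_terms`, `residual`.
#' @export
#' @examples
#' layered_reflectance(head_model(), rho = 31.3)
layered_reflectance <- function(medium, rho, tol = 1e-8, max_terms = 4000L) {
  stopifnot(inherits(medium, "layered_medium"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a single positive distance (mm)")
  if (rho >= medium$cylinder_radius)
    stop("'rho' must be smaller than the cylinder radius")
  nl <- length(medium$mua)
  if (nl > 1L && medium$z0 >= medium$thickness[1])
    stop("the isotropic source depth 1/musp[1] must lie inside the first layer")
  zb <- .zb(medium$D[1], medium$n[1], medium$n_out)
  rprime <- medium$cylinder_radius + zb
  max_terms <- as.integer(max_terms)
  fac <- .j0_factors(rprime, rho, max_terms)
  # chunked summation: stop once the largest term of a chunk is below
  # tol * |partial sum| (chunks span many J0 oscillations at any rho)
  chunk <- 500L
  S <- 0
  n0 <- 1L
  residual <- Inf
  n_used <- 0L
  while (n0 <= max_terms) {
    idx <- n0:min(n0 + chunk - 1L, max_terms)
    terms <- .flux_kernel(fac$s[idx], medium$mua, medium$musp,
                          medium$thickness, medium$D, medium$z0, zb) *
      fac$w[idx]
    S <- S + sum(terms)
    n_used <- idx[length(idx)]
    residual <- max(abs(terms)) / abs(S)
    if (residual <= tol) break
    n0 <- n0 + chunk
  }
  if (residual > tol)
    stop(sprintf(paste0("Bessel-root expansion did not converge within %d ",
                        "terms (residual %.3g)"), max_terms, residual))
  structure(list(reflectance = S, rho = rho,
                 n_terms = n_used, residual = residual),
            class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("CW reflectance %.6e at rho = %g mm (%d terms, residual %.2e)\n",
              x$reflectance, x$rho, x$n_terms, x$residual))
  invisible(x)
}

#' Per-layer mean partial pathlengths
#'
#' The mean partial pathlength of layer j is the sensitivity of the
#' natural-log attenuation to that layer's absorption,
#' \eqn{L_j = \partial A / \partial \mu_{a,j}} with \eqn{A = -\ln R},
#' evaluated at the baseline absorption by central finite differences on
#' the layered forward solution. Their sum is the total mean pathlength of
#' detected photons.
#'
#' @param medium a [layered_medium()].
#' @param rho source-detector distance, mm.
#' @param rel_step relative finite-difference step (absolute floor 1e-6
#'   mm^-1).
#' @param ... passed to [layered_reflectance()].
#' @return Numeric vector of pathlengths (mm), one per layer, with the
#'   medium's labels as names.
#' @export
#' @examples
#' mppl(head_model(), rho = 31.3)
mppl <- function(medium, rho, rel_step = 1e-4, ...) {
  nl <- length(medium$mua)
  L <- numeric(nl)
  for (j in seq_len(nl)) {
    h <- max(rel_step * medium$mua[j], 1e-6)
    up <- set_mua(medium, medium$mua[j] + h, j)
    dn <- set_mua(medium, max(medium$mua[j] - h, 0), j)
    h2 <- up$mua[j] - dn$mua[j]
    A_up <- -log(layered_reflectance(up, rho, ...)$reflectance)
    A_dn <- -log(layered_reflectance(dn, rho, ...)$reflectance)
    L[j] <- (A_up - A_dn) / h2
  }
  if (any(L < -1e-6))
    stop("negative mean partial pathlength beyond numerical tolerance")
  names(L) <- ifelse(is.na(medium$labels), paste0("layer", seq_len(nl)),
                     medium$labels)
  L
}

#' Assemble the pathlength matrix for the two-role layered inversion
#'
#' Mean partial pathlengths of the scalp (U) and gray-matter (L) roles at
#' each working wavelength and source-detector separation, computed at the
#' baseline optical properties. Baseline absorption of the active layers is
#' given at the isosbestic wavelength and re-expressed per wavelength
#' through the extinction table (solve for baseline concentrations, map
#' back at each wavelength); the remaining layers keep their nominal
#' absorption at both wavelengths.
#'
#' @param medium a `layered_medium` (2 or 5 layers).
#' @param rhos source-detector separations, mm (typically short and long).
#' @param wavelengths working wavelengths, nm.
#' @param table an [extinction_table()].
#' @param ... passed to [mppl()].
#' @return An array `L[role, wavelength, rho]` with dimnames, class
#'   `mppl_matrix`.
#' @export
#' @examples
#' mppl_matrix(head_model(), rhos = c(8.3, 31.3))
mppl_matrix <- function(medium, rhos, wavelengths = c(690, 830),
                        table = default_extinction_table(), ...) {
  roles <- roles_head_model(medium)
  out <- array(NA_real_,
               dim = c(2L, length(wavelengths), length(rhos)),
               dimnames = list(role = c("U", "L"),
                               wavelength = as.character(wavelengths),
                               rho = as.character(rhos)))
  for (iw in seq_along(wavelengths)) {
    m <- medium
    for (r in c("U", "L")) {
      j <- roles[[r]]
      conc <- mua_to_conc(medium$mua[j], table)
      m <- set_mua(m, conc_to_mua(conc[["hbo"]], conc[["hbr"]],
                                  wavelengths[iw], table), j)
    }
    for (ir in seq_along(rhos)) {
      L <- mppl(m, rhos[ir], ...)
      out[, iw, ir] <- L[roles]
    }
  }
  class(out) <- c("mppl_matrix", class(out))
  out
}
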