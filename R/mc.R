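#' Monte Carlo reference for a two-layer slab medium
#'
#' Photon-transport simulation (isotropic-scattering random walk with
#' continuous absorption weighting and Fresnel top boundary) returning the
#' diffuse reflectance and the per-layer mean partial pathlengths of
#' photons detected in a 1 mm annulus around `rho`, with standard errors.
#' This is the independent reference against which the analytical layered
#' diffusion solver is validated; it makes no use of the diffusion
#' approximation.
#'
#' @param medium a 2-layer [layered_medium()].
#' @param rho source-detector distance(s), mm; several annuli can be
#'   tallied in one pass.
#' @param n_photons number of photon packets (>= 1e5).
#' @param seed integer RNG seed (own generator; does not touch R's RNG).
#' @param half_width annulus half-width, mm.
#' @param max_steps cap on the number of scattering events per photon;
#'   photons exceeding it are dropped (they no longer count as escaped).
#'   Matters only for (nearly) non-absorbing media, where the walk-length
#'   distribution is heavy-tailed.
#' @return List with `reflectance`, `se_reflectance` (one entry per
#'   `rho`), `L`, `se_L` (length(rho) x 2 matrices of per-layer
#'   pathlengths, mm), `n_detected`, `escaped_weight_fraction`.
#' @export
#' @examples
#' m <- layered_medium(list(optical_layer(0.018, 1.9, 10),
#'                          optical_layer(0.036, 2.2)))
#' mc_slab(m, rho = 20, n_photons = 1e5, seed = 1)
mc_slab <- function(medium, rho, n_photons, seed, half_width = 0.5,
                    max_steps = 2e6) {
  stopifnot(inherits(medium, "layered_medium"))
  if (length(medium$mua) != 2L)
    stop("'medium' must have exactly 2 layers")
  if (n_photons < 1e5) stop("'n_photons' must be at least 1e5")
  out <- .mc_slab_cpp(medium$mua[1], medium$musp[1],
                      medium$mua[2], medium$musp[2],
                      medium$thickness[1], medium$n[1], medium$n_out,
                      rho, half_width, n_photons, as.integer(seed),
                      max_steps)
  if (all(out$n_detected == 0))
    stop("no photons detected in any annulus; increase n_photons")
  dimnames(out$L) <- dimnames(out$se_L) <-
    list(as.character(rho), c("L1", "L2"))
  names(out$reflectance) <- names(out$se_reflectance) <-
    names(out$n_detected) <- as.character(rho)
  out
}
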