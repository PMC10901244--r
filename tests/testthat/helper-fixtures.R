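# Media and small protocols shared across tests; everything is built in
# code so the suite carries no stored fixtures.

slab2 <- function(mua = c(0.018, 0.036), musp = c(1.9, 2.2), d1 = 10) {
  layered_medium(list(optical_layer(mua[1], musp[1], d1),
                      optical_layer(mua[2], musp[2])))
}

homogeneous_stack <- function(n_layers = 5, mua = 0.018, musp = 1.9) {
  d <- c(rep(4, n_layers - 1), Inf)
  layered_medium(lapply(seq_len(n_layers), function(j)
    optical_layer(mua, musp, d[j])))
}

# coarse protocol + linear-mode data for inversion tests (1 block, 1 Hz)
tiny_linear_data <- function(situation = 1) {
  hm <- head_model()
  cs <- concentration_timeseries(
    situation_protocol(situation, sample_rate = 1, n_blocks = 1))
  list(medium = hm, series = cs,
       aseries = forward_attenuation(cs, hm, probe_layout(),
                                     mode = "linear"))
}

# independent quadrature of the continuous-Hankel representation of the
# homogeneous surface flux (the oracle for the closed form)
hankel_quadrature_reflectance <- function(mua, musp, n_in, n_out, rho) {
  D <- 1 / (3 * musp); z0 <- 1 / musp
  reff <- effective_reflection(n_in, n_out)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  f <- function(s) {
    g <- sqrt((mua + D * s^2) / D)
    (exp(-g * z0) + exp(-g * (z0 + 2 * zb))) / 2 *
      besselJ(s * rho, 0) * s / (2 * pi)
  }
  tot <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  brk <- seq(1, 60, by = 0.5)   # piecewise over the oscillatory tail
  for (i in seq_len(length(brk) - 1L))
    tot <- tot + stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-10,
                                  stop.on.error = FALSE)$value
  tot
}
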