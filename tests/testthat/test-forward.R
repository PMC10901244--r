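test_that("effective reflection coefficient behaves like the Fresnel moments", {
  expect_identical(effective_reflection(1.0, 1.0), 0)
  expect_identical(effective_reflection(1.33, 1.33), 0)
  # independent Simpson quadrature of the same angular moments, split at
  # the critical angle where the integrand has a kink
  # the Fresnel moments have a sqrt cusp at the critical angle, which
  # degrades Simpson to ~h^1.5; a fine grid keeps the oracle at ~1e-7
  simpson1 <- function(f, a, b, n = 20000) {
    x <- seq(a, b, length.out = n + 1)
    h <- (b - a) / n
    h / 3 * sum(f(x) * c(1, rep(c(4, 2), n / 2 - 1), 4, 1))
  }
  n_in <- 1.33; n_out <- 1
  thc <- asin(n_out / n_in)
  simpson <- function(f, a, b) simpson1(f, a, thc) + simpson1(f, thc, b)
  rf <- function(theta) {
    m <- n_out / n_in; st <- sin(theta); ct <- cos(theta)
    r <- numeric(length(theta)); tir <- st >= m; r[tir] <- 1
    if (any(!tir)) {
      sto <- st[!tir] / m; cto <- sqrt(pmax(0, 1 - sto^2)); ci <- ct[!tir]
      rs <- ((n_in * ci - n_out * cto) / (n_in * ci + n_out * cto))^2
      rp <- ((n_in * cto - n_out * ci) / (n_in * cto + n_out * ci))^2
      r[!tir] <- (rs + rp) / 2
    }
    r
  }
  rphi <- simpson(function(th) 2 * sin(th) * cos(th) * rf(th), 0, pi / 2)
  rj <- simpson(function(th) 3 * sin(th) * cos(th)^2 * rf(th), 0, pi / 2)
  expect_equal(effective_reflection(1.33, 1.0), (rphi + rj) / (2 - rphi + rj),
               tolerance = 1e-5)
  # stronger mismatch reflects more
  expect_gt(effective_reflection(1.4, 1.0), effective_reflection(1.33, 1.0))
  expect_error(effective_reflection(-1, 1), "positive")
})

test_that("semi-infinite closed form is finite, monotone, and matches the
           Hankel-integral representation", {
  # zero absorption: finite and maximal over mua
  r0 <- semi_infinite_reflectance(0, 1.0, 1.33, 1.0, 30)
  expect_true(is.finite(r0) && r0 > 0)
  expect_gt(r0, semi_infinite_reflectance(0.01, 1.0, 1.33, 1.0, 30))
  # monotone decay with distance
  expect_gt(semi_infinite_reflectance(0.01, 1.0, 1.33, 1.0, 20),
            semi_infinite_reflectance(0.01, 1.0, 1.33, 1.0, 30))
  # value pinned by adaptive quadrature of the continuous transform
  # (frozen from hankel_quadrature_reflectance(0.018, 1.9, 1.33, 1, 31.3))
  expect_equal(semi_infinite_reflectance(0.018, 1.9, 1.33, 1.0, 31.3),
               3.4735954066e-09, tolerance = 1e-6)
  expect_equal(semi_infinite_reflectance(0.018, 1.9, 1.33, 1.0, 31.3),
               hankel_quadrature_reflectance(0.018, 1.9, 1.33, 1.0, 31.3),
               tolerance = 1e-6)
  expect_error(semi_infinite_reflectance(0.01, -1, 1.33, 1, 30), "musp")
  expect_error(semi_infinite_reflectance(0.01, 1, 1.33, 1, -5), "rho")
})

test_that("layered solver reduces to the homogeneous closed form", {
  m5 <- homogeneous_stack(5)
  for (rho in c(5, 10, 20, 30, 40)) {
    expect_equal(layered_reflectance(m5, rho)$reflectance,
                 semi_infinite_reflectance(0.018, 1.9, 1.33, 1.0, rho),
                 tolerance = 1e-3)
  }
  # a single semi-infinite "stack" goes through the same path
  m1 <- layered_medium(list(optical_layer(0.018, 1.9)))
  expect_equal(layered_reflectance(m1, 30)$reflectance,
               semi_infinite_reflectance(0.018, 1.9, 1.33, 1.0, 30),
               tolerance = 1e-3)
})

test_that("five-layer head reflectance is positive, converged and monotone
           in each layer's absorption", {
  hm <- head_model()
  sol <- layered_reflectance(hm, 31.3)
  expect_gt(sol$reflectance, 0)
  expect_lt(sol$residual, 1e-8)
  # absorption only removes light: raising any single layer's mua lowers
  # the detected signal, and the zero-absorption medium bounds it above
  for (j in 1:5) {
    darker <- set_mua(hm, 2 * hm$mua[j], j)
    expect_lt(layered_reflectance(darker, 31.3)$reflectance, sol$reflectance)
  }
  clear <- set_mua(hm, rep(0, 5))
  expect_gt(layered_reflectance(clear, 31.3)$reflectance, sol$reflectance)
})

test_that("solver rejects invalid geometry and reports non-convergence", {
  hm <- head_model()
  expect_error(layered_reflectance(hm, 200), "cylinder radius")
  expect_error(layered_reflectance(hm, -3), "positive")
  expect_error(layered_reflectance(hm, 31.3, max_terms = 50), "converge")
  # source depth must lie in the first layer
  thin <- layered_medium(list(optical_layer(0.01, 1.9, 0.2),
                              optical_layer(0.02, 2.0)))
  expect_error(layered_reflectance(thin, 20), "first layer")
})

test_that("pathlength sum rule holds against an all-layer derivative", {
  # homogeneous limit: sum of MPPLs equals the closed-form total derivative
  m5 <- homogeneous_stack(5)
  h <- 1e-5
  num <- -(log(semi_infinite_reflectance(0.018 + h, 1.9, 1.33, 1, 30)) -
             log(semi_infinite_reflectance(0.018 - h, 1.9, 1.33, 1, 30))) /
    (2 * h)
  expect_equal(sum(mppl(m5, 30)), num, tolerance = 5e-3)
  # heterogeneous: perturb every layer of the head model simultaneously
  hm <- head_model()
  up <- set_mua(hm, hm$mua + h)
  dn <- set_mua(hm, hm$mua - h)
  num5 <- -(log(layered_reflectance(up, 31.3)$reflectance) -
              log(layered_reflectance(dn, 31.3)$reflectance)) / (2 * h)
  expect_equal(sum(mppl(hm, 31.3)), num5, tolerance = 5e-3)
})

test_that("pathlengths are nonnegative and deep sensitivity grows with
           separation", {
  hm <- head_model()
  L_long <- mppl(hm, 31.3)
  L_short <- mppl(hm, 8.3)
  expect_true(all(L_long >= -1e-6))
  expect_true(all(L_short >= -1e-6))
  expect_lt(L_short[["GM"]], L_long[["GM"]])
  # property: random stacks keep every pathlength nonnegative
  set.seed(42)
  for (i in 1:4) {
    m <- layered_medium(list(
      optical_layer(runif(1, 0.005, 0.03), runif(1, 1.2, 2.5), runif(1, 6, 12)),
      optical_layer(runif(1, 0.005, 0.03), runif(1, 0.8, 2.5), runif(1, 2, 5)),
      optical_layer(runif(1, 0.005, 0.05), runif(1, 1.0, 4.0))))
    # strongly absorbing draws need a deeper series tail
    expect_true(all(mppl(m, 25, max_terms = 10000L) >= -1e-6))
  }
})

test_that("collapsing an internal layer recovers the thinner stack", {
  hm <- head_model()
  collapsed <- set_thickness(hm, 1e-3, 3L)       # CSF -> 1 um
  without <- layered_medium(list(
    optical_layer(0.018, 1.9, 10, label = "SC"),
    optical_layer(0.016, 1.6, 3, label = "SK"),
    optical_layer(0.036, 2.2, 2, label = "GM"),
    optical_layer(0.014, 4.1, label = "WM")))
  expect_equal(layered_reflectance(collapsed, 31.3)$reflectance,
               layered_reflectance(without, 31.3)$reflectance,
               tolerance = 5e-3)
  expect_lt(mppl(collapsed, 31.3)[["CSF"]], 0.01)
})

test_that("finite-difference pathlengths pass a step-halving self-check", {
  hm <- head_model()
  L1 <- mppl(hm, 31.3, rel_step = 2e-4)
  L2 <- mppl(hm, 31.3, rel_step = 1e-4)
  expect_equal(unname(L1), unname(L2), tolerance = 1e-4)
})

test_that("mppl_matrix carries both roles at each wavelength and distance", {
  hm <- head_model()
  M <- mppl_matrix(hm, rhos = c(8.3, 31.3))
  expect_equal(dim(M), c(2L, 2L, 2L))
  expect_true(all(M >= 0))
  # the two wavelengths share baselines quoted at the isosbestic point,
  # so their pathlength matrices coincide
  expect_equal(M[, 1, ], M[, 2, ], tolerance = 1e-10)
  # scalp dominates at the short distance
  expect_gt(M["U", 1, "8.3"], 100 * M["L", 1, "8.3"])
})
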