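test_that("homogeneous inversion is the exact algebraic inverse of its
           forward model", {
  tab <- default_extinction_table()
  E <- layernirs:::.eps_matrix(tab)
  truth <- c(5, -2)
  A <- matrix(rep(E %*% truth * 6 * 30, each = 4), nrow = 4, byrow = FALSE)
  X <- homogeneous_mbll(A, rho = 30, dpf = 6, table = tab)
  expect_equal(unname(X[1, ]), truth, tolerance = 1e-12)
  # null input
  X0 <- homogeneous_mbll(matrix(0, 3, 2), rho = 30)
  expect_equal(unname(X0), matrix(0, 3, 2))
  expect_error(homogeneous_mbll(matrix(0, 3, 2), rho = 30, dpf = -1), "dpf")
})

test_that("short-channel regression removes shared signal and keeps
           orthogonal signal", {
  x <- sin(seq(0, 20, by = 0.05))
  sc <- short_channel_correct(3 * x, x)
  expect_equal(sc$K, 3, tolerance = 1e-12)
  expect_equal(max(abs(sc$corrected)), 0, tolerance = 1e-12)
  # orthogonal channels: K = 0, long channel untouched
  s <- rep(c(1, -1), 50)
  l <- rep(c(1, 1, -1, -1), 25)   # orthogonal to s
  expect_equal(sum(s * l), 0)
  sc2 <- short_channel_correct(l, s)
  expect_equal(sc2$K, 0)
  expect_equal(sc2$corrected, l)
  expect_warning(sc3 <- short_channel_correct(l, rep(0, 100)), "all-zero")
  expect_equal(sc3$K, 0)
  expect_error(short_channel_correct(1:5, 1:4), "length")
})

test_that("layered inversion is linear and exact under an inverse crime", {
  dat <- tiny_linear_data(1)
  fit <- reconstruct_hb(dat$aseries, "layered", medium = dat$medium)
  tr <- delta_truth(dat$series)
  for (k in c("dhbo_U", "dhbo_L", "dhbr_U", "dhbr_L"))
    expect_lt(max(abs(fit$delta[[k]] - tr[[k]])), 1e-9)
  expect_lt(fit$condition, 1e10)
  expect_false(fit$flagged)
  # zero attenuation reconstructs to zero in both roles
  M <- fit$mppl
  z <- layered_invert(matrix(0, 5, 4), M)
  expect_equal(unname(z$delta), matrix(0, 5, 4))
  # superposition: reconstruction of a sum is the sum of reconstructions
  A1 <- fit$A; A2 <- 0.3 * fit$A + 0.01
  s12 <- layered_invert(A1 + A2, M)$delta
  expect_equal(s12, layered_invert(A1, M)$delta + layered_invert(A2, M)$delta,
               tolerance = 1e-9)
})

test_that("degenerate separations are flagged as rank-deficient", {
  hm <- head_model()
  M <- mppl_matrix(hm, rhos = c(31.3, 31.3))
  inv <- layered_invert(matrix(0, 2, 4), M, cond_cap = 1e10)
  expect_true(inv$flagged)
})

test_that("five-into-two layer merge follows the stated policies", {
  hm <- head_model()
  gm <- two_layer_merge(hm, "gm")
  expect_equal(length(gm$mua), 2L)
  expect_equal(gm$mua, c(0.018, 0.036))
  expect_equal(gm$musp, c(1.9, 2.2))
  expect_false(is.finite(gm$thickness[2]))
  w <- two_layer_merge(hm, "weighted")
  expect_equal(w$mua[2], (3 * 0.016 + 3 * 0.002 + 2 * 0.036) / 8)
  # merged medium feeds the pathlength machinery
  L <- mppl(gm, 20)
  expect_length(L, 2L)
  expect_true(all(L >= 0))
})

test_that("reconstruction object exposes the usual modelling verbs", {
  dat <- tiny_linear_data(1)
  fit <- reconstruct_hb(dat$aseries, "layered", medium = dat$medium)
  expect_s3_class(fit, "hb_recon")
  pk <- coef(fit)
  expect_named(pk, c("dhbo_U", "dhbo_L", "dhbr_U", "dhbr_L"))
  expect_equal(pk[["dhbo_L"]], 58.78, tolerance = 0.005 / 58)
  # fitted + residuals reproduce the inverted attenuation
  expect_equal(dim(fitted(fit)), dim(fit$A))
  expect_lt(max(abs(residuals(fit))), 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.hb_recon")
  expect_output(print(fit), "layered")
  # homogeneous route has its own fitted model
  fh <- reconstruct_hb(dat$aseries, "homogeneous")
  expect_equal(dim(fitted(fh)), dim(fh$A))
  expect_equal(unname(fitted(fh)), unname(fh$A), tolerance = 1e-9)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, truth = dat$series))
})
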