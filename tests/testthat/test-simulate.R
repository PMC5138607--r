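test_that("simplicial mixing matrices satisfy the model assumptions", {
  A <- make_simplicial_mixing(3, 3, seed = 1)
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-9)
  expect_true(all(A >= 0))
  expect_equal(qr(A)$rank, 3L)
  expect_true(all(check_simplicial(A)))

  # under-determined: 4 columns in the 3-d orthant, none inside the cone of
  # the other three (positive NNLS residuals)
  A4 <- make_simplicial_mixing(3, 4, seed = 2, min_pairwise_angle_deg = 20)
  expect_true(all(check_simplicial(A4)))
  for (k in 1:4) {
    r2 <- pracma::lsqnonneg(A4[, -k], A4[, k])$resid.norm
    expect_gt(sqrt(r2), 1e-8)
  }

  # a 2-D cone has exactly two extreme rays: four simplicial columns are
  # geometrically impossible and the sampler must say so
  expect_error(
    make_simplicial_mixing(2, 4, seed = 3, min_pairwise_angle_deg = 20,
                           max_attempts = 50),
    "no simplicial matrix"
  )
})

test_that("row sums stay exactly unit across seeds", {
  for (s in 1:10) {
    A <- make_simplicial_mixing(sample(3:5, 1), 3, seed = s)
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-9)
  }
})

test_that("source draws have the prescribed marginal structure", {
  cfg <- cam_sim_config(K = 3, N = 1e5, exp_fraction = 0.5, seed = 5)
  S <- draw_sources(cfg)
  expect_true(all(S >= 0))
  expect_equal(dim(S), c(3, 1e5))
  n_exp <- 5e4
  # unit-rate exponential block: coordinate means near 1
  expect_equal(unname(rowMeans(S[, 1:n_exp])), rep(1, 3), tolerance = 0.05)
  # |Gaussian| block with mean 1, unit variance: folded-normal mean
  fold_mean <- sqrt(2 / pi) * exp(-0.5) + 1 * (1 - 2 * pnorm(-1))
  expect_equal(unname(rowMeans(S[, (n_exp + 1):1e5])), rep(fold_mean, 3),
               tolerance = 0.05)
  # half-normal special case: mu = 0, identity covariance
  cfg0 <- cam_sim_config(K = 3, N = 1e5, gauss_mean = rep(0, 3),
                         gauss_cov = diag(3), seed = 6)
  S0 <- draw_sources(cfg0)
  expect_equal(unname(rowMeans(S0[, (n_exp + 1):1e5])), rep(sqrt(2 / pi), 3),
               tolerance = 0.05)
})

test_that("near well-grounded points exist on every axis for exponential sources", {
  # P(dominance > 0.99) is about 1e-4 per sample and source for unit-rate
  # exponentials, so 2e5 samples give ~20 expected hits per source
  cfg <- cam_sim_config(K = 3, N = 2e5, exp_fraction = 1, seed = 8)
  S <- draw_sources(cfg)
  dom <- S / rep(colSums(S), each = 3)
  expect_true(all(apply(dom, 1, max) > 0.99))
})

test_that("noise is rescaled to the requested SNR exactly", {
  withr::with_seed(9, {
    sig <- matrix(abs(rnorm(3 * 50)), 3, 50)
    out <- add_noise_at_snr(sig, 10, seed = 4)
    expect_equal(sum(sig^2) / sum(out$E^2), 10, tolerance = 1e-12)
    expect_equal(out$X, sig + out$E)
    expect_equal(compute_snr_db(sig, out$E), 10, tolerance = 1e-9)
    # infinite SNR: no noise at all
    out_inf <- add_noise_at_snr(sig, Inf)
    expect_identical(out_inf$X, sig)
    expect_true(all(out_inf$E == 0))
  })
})

test_that("the composite simulation is deterministic and self-consistent", {
  cfg <- cam_sim_config(N = 200, seed = 33)
  sim1 <- cam_simulate(cfg)
  sim2 <- cam_simulate(cfg)
  expect_identical(sim1, sim2)
  expect_equal(sim1$X, sim1$A_true %*% sim1$S_true + sim1$E,
               ignore_attr = TRUE)
  expect_equal(compute_snr_db(sim1$A_true %*% sim1$S_true, sim1$E), 12.4,
               tolerance = 1e-9)
  expect_true(all(sim1$S_true >= 0))
})

test_that("config validation rejects inconsistent simulation settings", {
  expect_error(cam_sim_config(exp_fraction = 0), "exp_fraction")
  expect_error(cam_sim_config(gauss_cov = matrix(c(1, 2, 2, 1), 2),
                              K = 2, exp_rates = c(1, 1),
                              gauss_mean = c(1, 1)), "positive definite")
  expect_error(cam_sim_config(snr_db = NA), "snr_db")
  expect_error(cam_sim_config(exp_rates = c(1, -1, 1)), "exp_rates")
})
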