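test_that("the full model setup matches the stated defaults", {
  setup <- build_full_model(3, 256, 3.22)
  expect_equal(ncol(setup$basis), 64)
  off <- setup$priors$index_map$block == "A" &
    setup$priors$index_map$row != setup$priors$index_map$col
  expect_true(all(setup$priors$variance[off] == 2))

  setup4 <- build_full_model(4, 256, 3.22)
  off4 <- setup4$priors$index_map$block == "A" &
    setup4$priors$index_map$row != setup4$priors$index_map$col
  expect_equal(sum(off4), 12)

  emp <- prior_config("empirical")
  expect_equal(emp$noise_logprec_mean, 4)
  expect_equal(prior_config("simulated")$noise_logprec_mean, 6)
  expect_error(build_full_model(3, 8, 1), "16")
})

test_that("prediction is zero without input and responds to coupling", {
  setup <- build_full_model(3, 64, 3.22)
  theta <- setup$priors$mean   # all C weights zero
  pred <- predict_bold(theta, setup$basis, 3.22)
  expect_equal(max(abs(pred$data)), 0)
  # perturbing a coupling entry changes the prediction once inputs exist
  theta2 <- theta
  theta2[9 + seq_len(3)] <- 0.01   # first basis column drives every node
  p0 <- predict_bold(theta2, setup$basis, 3.22)
  theta3 <- theta2
  theta3[2] <- theta3[2] + 0.1     # A[2,1]
  p1 <- predict_bold(theta3, setup$basis, 3.22)
  expect_gt(max(abs(p1$data - p0$data)), 0)
})

test_that("prediction under true parameters reproduces the clean signal", {
  f <- chain3_fit()
  omega <- f$sim$truth$omega
  U <- unclass(f$setup$basis)
  C <- t(U) %*% omega                      # least-squares basis weights
  g <- log(f$sim$truth$hemo$par[, c("kappa", "tau")] /
           hemo_defaults(3)$par[, c("kappa", "tau")])
  theta <- pack_theta(f$sim$truth$A, t(C), g[, 1], g[, 2])
  # the basis truncates the fluctuations and the clean signal carries
  # hemodynamic state noise the prediction cannot represent, so the
  # correlation is slightly below 1
  pred <- predict_bold(theta, f$setup$basis, 3.22, nsub = 8)
  for (j in 1:3)
    expect_gt(cor(pred$data[, j], f$sim$truth$clean[, j]), 0.97)
})

test_that("the Gaussian KL matches an independent closed form", {
  expect_equal(gaussian_kl(1, 2, 1, 2), 0)
  set.seed(7)
  for (k in c(1, 3)) {
    m1 <- rnorm(k); m0 <- rnorm(k)
    R1 <- matrix(rnorm(k * k), k); S1 <- crossprod(R1) + diag(k)
    R0 <- matrix(rnorm(k * k), k); S0 <- crossprod(R0) + diag(k)
    direct <- 0.5 * (sum(diag(solve(S0) %*% S1)) +
                     t(m1 - m0) %*% solve(S0) %*% (m1 - m0) - k +
                     log(det(S0) / det(S1)))
    expect_equal(gaussian_kl(m1, S1, m0, S0), as.numeric(direct),
                 tolerance = 1e-8)
  }
})

test_that("noise-only data shrink every coupling towards zero", {
  set.seed(21)
  T <- 128
  ts <- node_timeseries(matrix(rnorm(T * 3, 0, exp(-2)), T, 3), 3.22)
  setup <- build_full_model(3, T, 3.22)
  post <- invert_full(ts, setup$priors, setup$basis)
  off <- post$index_map$block == "A" & post$index_map$row != post$index_map$col
  expect_true(all(abs(post$mean[off]) < sqrt(2) / 2))
})

test_that("free energy is monotone and the covariance is PSD", {
  f <- chain3_fit()
  expect_true(all(diff(f$post$trace) > -1e-6))
  ev <- eigen(f$post$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_true(is.finite(f$post$free_energy))
})

test_that("recovered couplings have the right signs and cover the truth", {
  f <- chain4_fit()
  post <- f$post
  off <- which(post$index_map$block == "A" &
               post$index_map$row != post$index_map$col)
  truth <- f$fix$A[cbind(post$index_map$row[off], post$index_map$col[off])]
  mu <- post$mean[off]
  sd <- sqrt(diag(post$covariance))[off]
  pres <- truth != 0
  expect_true(all(sign(mu[pres]) == sign(truth[pres])))
  covered <- abs(mu[pres] - truth[pres]) < qnorm(0.95) * sd[pres]
  expect_gte(sum(covered), 5)   # at least 5 of the 6 true couplings
})

test_that("the free-energy bound reacts to data and model as it should", {
  f <- chain3_fit()
  F0 <- free_energy(f$post, f$post$priors, f$sim$ts, f$setup$basis)
  expect_equal(F0, f$post$free_energy, tolerance = 1e-2)
  # doubling the observation noise in the data lowers the bound
  noisy <- f$sim$ts
  set.seed(2)
  noisy$data <- noisy$data + matrix(rnorm(length(noisy$data), 0, exp(-2)),
                                    nrow(noisy$data))
  expect_lt(free_energy(f$post, f$post$priors, noisy, f$setup$basis), F0)
})

test_that("explicit inversion prefers the true sparsity over no edges", {
  f <- chain3_fit()
  cfg <- prior_config()
  pri_true <- priors_from_adjacency(f$fix$adjacency, n_inputs = 64,
                                    config = cfg,
                                    c_shape = dct_shape(256, 64))
  pri_none <- priors_from_adjacency(adjacency(diag(3)), n_inputs = 64,
                                    config = cfg,
                                    c_shape = dct_shape(256, 64))
  fit_true <- invert_full(f$sim$ts, pri_true, f$setup$basis,
                          init = f$post$mean)
  fit_none <- invert_full(f$sim$ts, pri_none, f$setup$basis,
                          init = f$post$mean)
  expect_gt(fit_true$free_energy, fit_none$free_energy)
})
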