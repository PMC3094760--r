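test_that("neuronal flow is the linear network field", {
  A <- example_coupling("chain3")$A
  expect_equal(neuronal_flow(rep(0, 3), A), rep(0, 3))
  expect_equal(neuronal_flow(c(1, 0, 0), A), c(-0.5, 0.3, 0))
  x1 <- rnorm(3); x2 <- rnorm(3)
  expect_equal(neuronal_flow(x1 + x2, A),
               neuronal_flow(x1, A) + neuronal_flow(x2, A))
  C <- matrix(1, 3, 2)
  expect_equal(neuronal_flow(rep(0, 3), A, C, c(1, 2)), rep(3, 3))
  expect_error(neuronal_flow(rep(0, 2), A), "dimension")
  expect_error(neuronal_flow(rep(0, 3), A, C, 1), "dimension")
})

test_that("balloon flow has the resting fixed point and input gating", {
  rest <- list(s = 0, lf = 0, lv = 0, lq = 0)
  expect_equal(unname(hemodynamic_flow(rest, 0)), rep(0, 4))
  d <- hemodynamic_flow(rest, 0.1)
  expect_equal(unname(d), c(0.1, 0, 0, 0))
  expect_error(hemodynamic_flow(rest, 0, c(kappa = 0.64, gamma = 0.32,
                                           tau = -1, alpha = 0.32,
                                           rho = 0.32, epsilon = 1)),
               "invalid")
})

test_that("a transient input produces a flow overshoot then undershoot", {
  h <- hemo_defaults(1)
  st <- c(s = 0, lf = 0, lv = 0, lq = 0)
  dt <- 0.01
  lf <- numeric(6000)
  for (k in seq_len(6000)) {
    x <- if (k * dt <= 1) 1 else 0
    st <- st + dt * hemodynamic_flow(as.list(st), x, h)
    lf[k] <- st[["lf"]]
  }
  peak <- which.max(lf)
  expect_gt(exp(lf[peak]), 1)              # flow rises above baseline
  expect_lt(min(exp(lf[peak:6000])), 1)    # post-stimulus undershoot
  expect_lt(abs(lf[6000]), 0.02)           # re-equilibration
})

test_that("the BOLD observation equation has the expected signs", {
  expect_equal(bold_observation(list(s = 0, lf = 0, lv = 0, lq = 0)), 0)
  expect_gt(bold_observation(list(s = 0, lf = 0, lv = 0, lq = -0.1)), 0)
})

test_that("the cosine basis is orthogonal with a quarter-length default", {
  U <- dct_basis(256)
  expect_equal(ncol(U), 64)
  expect_equal(crossprod(unclass(U)), diag(64), tolerance = 1e-12)
  expect_true(all(abs(diff(U[, 1])) < 1e-12))  # constant component first
  expect_equal(ncol(dct_basis(100)), 25)
})

test_that("integration sits exactly at rest under zero input", {
  A <- example_coupling("chain3")$A
  out <- integrate_dcm(A, 32, 3.22, omega = matrix(0, 32, 3),
                       want_states = TRUE)
  expect_equal(out$signal$data, matrix(0, 32, 3), ignore_attr = TRUE)
  expect_equal(max(abs(out$states)), 0)
})

test_that("the neuronal subsystem matches a matrix-exponential oracle", {
  A <- example_coupling("chain3")$A
  omega <- smooth_fluctuations(64, 3, seed = 2) * 0.01
  out <- integrate_dcm(A, 64, 2, omega = omega, neuronal_only = TRUE)
  E <- as.matrix(Matrix::expm(A * 2))
  Phi <- solve(A, E - diag(3))
  x <- rep(0, 3)
  X <- matrix(0, 64, 3)
  for (k in 1:64) {
    X[k, ] <- x
    x <- as.vector(E %*% x + Phi %*% omega[k, ])
  }
  expect_lt(max(abs(out$signal$data - X)) / max(abs(X)), 1e-6)
})

test_that("halving the integration sub-step barely changes the signal", {
  A <- example_coupling("chain3")$A
  omega <- smooth_fluctuations(64, 3, seed = 5) * 0.015
  a <- integrate_dcm(A, 64, 3.22, omega = omega, nsub = 8)$signal$data
  b <- integrate_dcm(A, 64, 3.22, omega = omega, nsub = 16)$signal$data
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-4)
})

test_that("an unstable coupling matrix is flagged", {
  A <- matrix(c(0.1, 0, 0, -0.5), 2, 2)
  expect_warning(integrate_dcm(A, 16, 1, omega = matrix(0, 16, 2)),
                 "abscissa")
})

test_that("mixed-sign chain coupling anti-correlates node 3 with 1 and 2", {
  fix <- example_coupling("chain3")
  for (s in c(3, 13)) {
    sim <- simulate_dataset(fix$A, fix$adjacency,
                            config = mc_config(n_nodes = 3), seed = s)
    expect_lt(cor(sim$truth$clean[, 1], sim$truth$clean[, 3]), 0)
    expect_lt(cor(sim$truth$clean[, 2], sim$truth$clean[, 3]), 0)
  }
})

test_that("simulated signals peak near one percent", {
  fix <- example_coupling("chain3")
  mx <- vapply(c(3, 13, 23), function(s)
    max(abs(simulate_dataset(fix$A, fix$adjacency,
                             config = mc_config(n_nodes = 3),
                             seed = s)$truth$clean)), 0)
  expect_true(all(mx > 0.5 & mx < 2))
})

test_that("the series container validates its invariants", {
  expect_error(node_timeseries(matrix(0, 1, 2), 1), "2 time samples")
  expect_error(node_timeseries(matrix(0, 4, 2), -1), "positive")
  expect_error(node_timeseries(matrix(NA_real_, 4, 2), 1), "missing")
  ts <- node_timeseries(matrix(rnorm(8), 4, 2), 3.22)
  expect_equal(ts$labels, c("node1", "node2"))
})
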