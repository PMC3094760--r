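test_that("smooth fluctuations have the stated amplitude and memory", {
  om <- smooth_fluctuations(65536, 1, ac_width = 2, log_precision = 4,
                            seed = 1)
  expect_lt(abs(sd(om) - exp(-2)) / exp(-2), 0.03)
  r2 <- acf(om[, 1], lag.max = 2, plot = FALSE)$acf[3]
  expect_lt(abs(r2 - exp(-0.5)), 0.03)
  # determinism and independence of streams
  expect_identical(om, smooth_fluctuations(65536, 1, 2, 4, seed = 1))
  expect_false(identical(om, smooth_fluctuations(65536, 1, 2, 4, seed = 2)))
  expect_error(smooth_fluctuations(64, 1, ac_width = 0), "positive")
})

test_that("random networks follow the sampling protocol", {
  cfg <- mc_config()
  selfs <- numeric(2500 * 4)
  bad_mag <- bad_sign <- bad_zero <- 0L
  for (s in 1:2500) {
    net <- sample_random_network(cfg, seed = s)
    m <- unclass(net$adjacency)
    for (i in 1:3) for (j in (i + 1):4) {
      if (m[i, j] == 1) {
        mags <- abs(c(net$A[i, j], net$A[j, i]))
        if (any(mags < 0.25 | mags > 0.5)) bad_mag <- bad_mag + 1L
        if (sign(net$A[i, j]) != sign(net$A[j, i])) bad_sign <- bad_sign + 1L
      } else if (net$A[i, j] != 0 || net$A[j, i] != 0) {
        bad_zero <- bad_zero + 1L
      }
    }
    selfs[4 * s - 3:0] <- diag(net$A)
  }
  expect_identical(c(bad_mag, bad_sign, bad_zero), c(0L, 0L, 0L))
  expect_lt(abs(mean(selfs) + 0.5), 0.02)   # 10,000 self draws
  expect_lt(abs(sd(selfs) - 0.5), 0.02)
})

test_that("simulated datasets respect the discard rule and record truth", {
  sim <- simulate_dataset(config = mc_config(), seed = 42)
  expect_lt(max(abs(sim$truth$clean)), 2)
  expect_s3_class(sim$truth$adjacency, "dcm_adjacency")
  expect_equal(dim(sim$truth$A), c(4, 4))
  expect_equal(unclass(sim$truth$adjacency),
               (sim$truth$A != 0) * 1, ignore_attr = TRUE)
  # duration of the standard protocol
  expect_equal(nrow(sim$ts$data) * sim$ts$dt, 824.32)
  # reproducibility
  sim2 <- simulate_dataset(config = mc_config(), seed = 42)
  expect_identical(sim$ts$data, sim2$ts$data)
})

test_that("accepted runs sit at the intended signal-to-noise ratio", {
  snr <- vapply(1:3, function(s) {
    sim <- simulate_dataset(config = mc_config(), seed = 100 + s)
    sd(sim$truth$clean) / exp(-2)
  }, 0)
  expect_true(all(abs(snr - 2.6) / 2.6 < 0.3))
})

test_that("the printed chain fixtures are stable", {
  for (nm in c("chain3", "chain4")) {
    A <- example_coupling(nm)$A
    expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)
  }
  expect_equal(example_coupling("chain3")$A[1, 2], 0.4)
  expect_equal(example_coupling("chain4")$A[3, 2], -0.3)
})

test_that("phase shuffling preserves spectra and destroys coupling", {
  # constant series pass through unchanged
  ts0 <- node_timeseries(matrix(2.5, 16, 1), 1)
  expect_equal(phase_shuffle(ts0, seed = 1)$data, ts0$data,
               tolerance = 1e-12)
  # per-column amplitude spectrum and mean preserved
  sim <- simulate_dataset(config = mc_config(), seed = 5)
  sh <- phase_shuffle(sim$ts, seed = 9)
  for (j in 1:4) {
    expect_lt(max(abs(Mod(fft(sh$data[, j])) - Mod(fft(sim$ts$data[, j])))) /
              max(Mod(fft(sim$ts$data[, j]))), 1e-10)
    expect_equal(mean(sh$data[, j]), mean(sim$ts$data[, j]),
                 tolerance = 1e-10)
  }
  # strongly coupled broadband columns decorrelate on average over seeds
  sim2 <- simulate_dataset(example_coupling("chain3")$A,
                           config = mc_config(n_nodes = 3), seed = 8)
  ts2 <- node_timeseries(sim2$ts$data[, 2:3], sim2$ts$dt)
  expect_gt(abs(cor(ts2$data[, 1], ts2$data[, 2])), 0.5)
  rs <- vapply(1:100, function(s) {
    p <- phase_shuffle(ts2, seed = s)
    cor(p$data[, 1], p$data[, 2])
  }, 0)
  expect_lt(mean(abs(rs)), 0.2)
})
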