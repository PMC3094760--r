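# run code under a temporary RNG state; NULL seed leaves the stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Smooth Gaussian fluctuations
#'
#' Stationary Gaussian series with a Gaussian autocorrelation function,
#' obtained by convolving independent Gaussian variables with a Gaussian
#' kernel. A kernel of standard deviation \code{ac_width / sqrt(2)} bins
#' yields the target autocorrelation \code{rho(tau) = exp(-tau^2 /
#' (2 ac_width^2))}; the series is scaled so its stationary standard
#' deviation is \code{exp(-log_precision / 2)} (precision is inverse
#' variance). Columns are independent.
#'
#' @param T number of samples
#' @param n number of columns (nodes)
#' @param ac_width standard deviation of the autocorrelation function, in
#'   time bins
#' @param log_precision log inverse variance of the fluctuation amplitude
#' @param seed optional integer seed (the caller's RNG state is restored)
#' @return T x n matrix
#' @export
smooth_fluctuations <- function(T, n = 1, ac_width = 2, log_precision = 4,
                                seed = NULL) {
  if (ac_width <= 0) stop("ac_width must be positive")
  with_seed(seed, {
    sk <- ac_width / sqrt(2)
    K <- max(1L, ceiling(6 * sk))
    kern <- dnorm(seq(-K, K), sd = sk)
    kern <- kern / sqrt(sum(kern^2))      # unit stationary variance
    sd_target <- exp(-log_precision / 2)
    z <- matrix(rnorm((T + 2 * K) * n), T + 2 * K, n)
    out <- apply(z, 2, function(col)
      convolve(col, kern, type = "filter"))
    sd_target * matrix(out, T, n)
  })
}

#' Printed example coupling matrices
#'
#' Small reciprocally connected chains used throughout as test fixtures:
#' \code{"chain3"} is a three-node chain with mixed-sign couplings that
#' produces anti-correlated responses between the third node and the first
#' two; \code{"chain4"} is a four-node chain (pairs 1-2, 2-3, 3-4 present,
#' 1-3, 1-4, 2-4 absent). Both have negative spectral abscissa.
#'
#' @param name \code{"chain3"} or \code{"chain4"}
#' @return list with the coupling matrix \code{A} and its
#'   \code{\link{adjacency}}
#' @export
example_coupling <- function(name = c("chain3", "chain4")) {
  name <- match.arg(name)
  A <- switch(name,
    chain3 = matrix(c(-0.5, 0.3, 0,
                      0.4, -0.5, -0.2,
                      0, -0.3, -0.4), 3, 3),
    chain4 = matrix(c(-0.5, 0.3, 0, 0,
                      0.3, -0.5, -0.3, 0,
                      0, -0.3, -0.5, 0.3,
                      0, 0, 0.3, -0.5), 4, 4))
  list(A = A, adjacency = adjacency((A != 0) * 1))
}

#' Monte Carlo protocol configuration
#'
#' Conditions of the network-recovery simulations: four-node graphs drawn
#' uniformly from the bidirectional space; present coupling magnitudes
#' uniform on (1/4, 1/2) with the sign of each reciprocal pair flipped at
#' random; self-connections Gaussian with mean -1/2 and variance 1/4;
#' 256 samples at TR 3.22 s; neuronal fluctuations with autocorrelation
#' width 2 bins and log-precision 4; hemodynamic state noise with width 0.5
#' bins and log-precision 16; white observation noise with log-precision 4
#' (SD exp(-2)); hemodynamic decay/transit scaled per region by a Gaussian
#' deviate with log-precision 6; candidate networks discarded (and redrawn)
#' if the noiseless signal exceeds 2 percent.
#'
#' @param n_nodes,n_runs,T,dt protocol sizes
#' @param coupling_range magnitude bounds (low, high) of present couplings
#' @param self_mean,self_var moments (mean, variance) of self-connections
#' @param discard_threshold maximum |noiseless signal| allowed, in percent
#' @param neuronal_ac,neuronal_logprec neuronal fluctuation spectrum
#' @param target_signal_sd calibration target for the noiseless signal
#'   standard deviation (percent); the neuronal drive is rescaled per
#'   candidate so the emitted signal sits at the intended level (set to
#'   NULL to use the raw \code{neuronal_logprec} amplitude)
#' @param hemo_ac,hemo_logprec hemodynamic state-noise spectrum
#' @param obs_logprec observation-noise log-precision
#' @param hemo_perturb_logprec log-precision of the per-region scaling of
#'   decay and transit
#' @param retry_cap maximum redraws under the discard rule
#' @return list of class \code{dcm_mc_config}
#' @export
mc_config <- function(n_nodes = 4, n_runs = 200, T = 256, dt = 3.22,
                      coupling_range = c(0.25, 0.5),
                      self_mean = -0.5, self_var = 0.25,
                      discard_threshold = 2,
                      neuronal_ac = 2, neuronal_logprec = 4,
                      target_signal_sd = 0.35,
                      hemo_ac = 0.5, hemo_logprec = 16,
                      obs_logprec = 4, hemo_perturb_logprec = 6,
                      retry_cap = 100) {
  if (coupling_range[1] <= 0 || coupling_range[2] <= coupling_range[1])
    stop("need 0 < low < high in coupling_range")
  if (discard_threshold <= 0) stop("discard_threshold must be positive")
  structure(as.list(environment()), class = "dcm_mc_config")
}

#' Sample a random network under the Monte Carlo protocol
#'
#' Draws an adjacency uniformly from the bidirectional model space, then for
#' each present reciprocal pair draws both directed magnitudes uniformly
#' from \code{coupling_range} and flips the pair's common sign with
#' probability 1/2; absent pairs are exactly zero; self-connections are
#' Gaussian with the configured mean and variance.
#'
#' @param config a \code{\link{mc_config}}
#' @param seed optional integer seed
#' @return list with \code{A} and \code{adjacency}
#' @export
sample_random_network <- function(config = mc_config(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_nodes
    pairs <- pair_index(n)
    m <- diag(n)
    A <- matrix(0, n, n)
    diag(A) <- rnorm(n, config$self_mean, sqrt(config$self_var))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (runif(1) < 0.5) {
        m[i, j] <- m[j, i] <- 1
        sgn <- if (runif(1) < 0.5) 1 else -1
        A[i, j] <- sgn * runif(1, config$coupling_range[1],
                               config$coupling_range[2])
        A[j, i] <- sgn * runif(1, config$coupling_range[1],
                               config$coupling_range[2])
      }
    }
    list(A = A, adjacency = adjacency(m))
  })
}

#' Simulate a noisy BOLD dataset
#'
#' Integrates the generative model under smooth neuronal fluctuations and
#' small hemodynamic state noise, perturbs each region's decay and transit
#' parameters by a random log-scaling, and adds white observation noise.
#' The amplitude of the neuronal drive is calibrated per candidate so the
#' noiseless signal standard deviation matches
#' \code{config$target_signal_sd} (different networks amplify the same
#' drive very differently, and the protocol fixes the emitted signal level,
#' not the drive level). Candidates whose noiseless signal still exceeds
#' the discard threshold are rejected; if \code{A} is NULL a fresh network
#' is drawn on every attempt, otherwise fresh fluctuations are drawn for
#' the fixed \code{A}.
#'
#' @param A coupling matrix, or NULL to sample one per attempt
#' @param adj adjacency of \code{A} (derived from the sparsity of \code{A}
#'   when omitted)
#' @param config a \code{\link{mc_config}}
#' @param seed optional integer seed
#' @return list with \code{ts} (noisy \code{\link{node_timeseries}}) and
#'   \code{truth} (A, adjacency, noiseless signal, hemodynamic scalings,
#'   attempts used)
#' @export
simulate_dataset <- function(A = NULL, adj = NULL, config = mc_config(),
                             seed = NULL) {
  with_seed(seed, {
    n <- config$n_nodes
    fixed <- !is.null(A)
    if (fixed) n <- nrow(A)
    for (attempt in seq_len(config$retry_cap)) {
      if (!fixed) {
        net <- sample_random_network(config)
        A_try <- net$A; adj_try <- net$adjacency
      } else {
        A_try <- A
        adj_try <- if (is.null(adj)) adjacency((A != 0) * 1) else adj
      }
      if (max(Re(eigen(A_try, only.values = TRUE)$values)) >= 0) next
      omega <- smooth_fluctuations(config$T, n, config$neuronal_ac,
                                   config$neuronal_logprec)
      hnoise <- smooth_fluctuations(config$T, 4 * n, config$hemo_ac,
                                    config$hemo_logprec)
      g <- rnorm(2 * n, 0, exp(-config$hemo_perturb_logprec / 2))
      hemo <- hemo_defaults(n)
      hemo$par[, "kappa"] <- hemo$par[, "kappa"] * exp(g[seq_len(n)])
      hemo$par[, "tau"] <- hemo$par[, "tau"] * exp(g[n + seq_len(n)])
      if (!is.null(config$target_signal_sd)) {
        # calibrate the drive so the emitted signal sits at the target
        # level; start from a scale that is safe for any stable network
        omega <- omega * (0.002 / exp(-config$neuronal_logprec / 2))
        trial <- tryCatch(
          integrate_dcm(A_try, config$T, config$dt, omega = omega,
                        hemo = hemo),
          error = function(e) NULL)
        if (is.null(trial)) next
        omega <- omega * config$target_signal_sd / sd(trial$signal$data)
      }
      sim <- tryCatch(
        integrate_dcm(A_try, config$T, config$dt, omega = omega,
                      hemo = hemo, hemo_noise = hnoise),
        error = function(e) NULL)
      if (is.null(sim)) next
      clean <- sim$signal$data
      if (max(abs(clean)) > config$discard_threshold) next
      noise <- matrix(rnorm(config$T * n, 0, exp(-config$obs_logprec / 2)),
                      config$T, n)
      return(list(
        ts = node_timeseries(clean + noise, config$dt),
        truth = list(A = A_try, adjacency = adj_try, clean = clean,
                     omega = omega, hemo = hemo, attempts = attempt)))
    }
    stop("retry cap exceeded: no candidate stayed below the ",
         config$discard_threshold, "% discard threshold")
  })
}

#' Phase-shuffled surrogate series
#'
#' Fourier transforms each column, replaces the phases of all non-DC,
#' non-Nyquist bins with independent uniform draws (conjugate symmetry
#' enforced; for even length the Nyquist bin keeps a random sign), and
#' inverts the transform. The per-column amplitude spectrum, and hence the
#' power spectrum and mean, are preserved exactly, while dependence between
#' columns is destroyed.
#'
#' @param ts a \code{\link{node_timeseries}}
#' @param seed optional integer seed
#' @return a \code{\link{node_timeseries}} of the same shape
#' @export
phase_shuffle <- function(ts, seed = NULL) {
  with_seed(seed, {
    x <- ts$data
    T <- nrow(x)
    if (T < 4) stop("need at least 4 samples")
    nh <- floor((T - 1) / 2)
    out <- apply(x, 2, function(col) {
      X <- fft(col)
      ph <- runif(nh, 0, 2 * pi)
      Y <- X
      Y[1 + seq_len(nh)] <- Mod(X[1 + seq_len(nh)]) * exp(1i * ph)
      Y[T + 1 - seq_len(nh)] <- Conj(Y[1 + seq_len(nh)])
      if (T %% 2 == 0)
        Y[T / 2 + 1] <- Mod(X[T / 2 + 1]) * sample(c(-1, 1), 1)
      Re(fft(Y, inverse = TRUE)) / T
    })
    node_timeseries(out, ts$dt, ts$labels)
  })
}
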