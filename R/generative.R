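#' Default hemodynamic parameters
#'
#' Per-region balloon-model parameters: signal decay \code{kappa} (Hz),
#' autoregulatory feedback \code{gamma} (Hz), mean transit time \code{tau}
#' (s), vessel stiffness \code{alpha} (dimensionless, in (0,1)), resting
#' oxygen extraction fraction \code{rho} (in (0,1)) and neurovascular signal
#' gain \code{epsilon}. BOLD coefficients follow the classical set:
#' \code{V0 = 0.04} (resting venous volume fraction, reported in percent
#' signal so the observation uses \code{100 * V0}), \code{k1 = 7 rho},
#' \code{k2 = 2}, \code{k3 = 2 rho - 0.2}.
#'
#' @param n_nodes number of regions
#' @param kappa,gamma,tau,alpha,rho,epsilon scalars or length-n vectors
#' @param V0 resting venous volume fraction
#' @return list of class \code{dcm_hemo} with an \code{n x 6} parameter
#'   matrix \code{par} (kappa, gamma, tau, alpha, rho, epsilon) and an
#'   \code{n x 4} observation-coefficient matrix \code{obs}
#'   (\code{100 V0, k1, k2, k3})
#' @export
hemo_defaults <- function(n_nodes = 1, kappa = 0.64, gamma = 0.32,
                          tau = 2.0, alpha = 0.32, rho = 0.32,
                          epsilon = 1, V0 = 0.04) {
  par <- cbind(kappa = rep_len(kappa, n_nodes),
               gamma = rep_len(gamma, n_nodes),
               tau = rep_len(tau, n_nodes),
               alpha = rep_len(alpha, n_nodes),
               rho = rep_len(rho, n_nodes),
               epsilon = rep_len(epsilon, n_nodes))
  if (any(par[, "tau"] <= 0) || any(par[, "kappa"] <= 0) ||
      any(par[, "alpha"] <= 0) || any(par[, "alpha"] >= 1) ||
      any(par[, "rho"] <= 0) || any(par[, "rho"] >= 1))
    stop("invalid hemodynamic parameters: need tau, kappa > 0, ",
         "alpha and rho in (0, 1)")
  obs <- cbind(V0 = rep_len(100 * V0, n_nodes),
               k1 = 7 * par[, "rho"],
               k2 = rep_len(2, n_nodes),
               k3 = 2 * par[, "rho"] - 0.2)
  structure(list(par = par, obs = obs, n_nodes = n_nodes),
            class = "dcm_hemo")
}

#' Neuronal flow of the linear network model
#'
#' The rate of change of the neuronal states: \code{A x + C u}, where
#' \code{A[i, j]} is the influence of node j on node i (Hz) and \code{C}
#' maps the J input (basis) components onto the nodes.
#'
#' @param x neuronal state vector (length n)
#' @param A n x n coupling matrix
#' @param C n x J input-weight matrix (optional)
#' @param u input vector of length J (optional)
#' @return length-n derivative vector
#' @export
neuronal_flow <- function(x, A, C = NULL, u = NULL) {
  if (length(x) != nrow(A) || nrow(A) != ncol(A))
    stop("dimension mismatch between x and A")
  dx <- as.vector(A %*% x)
  if (!is.null(C) && !is.null(u)) {
    if (ncol(C) != length(u) || nrow(C) != length(x))
      stop("dimension mismatch between C and u")
    dx <- dx + as.vector(C %*% u)
  }
  dx
}

#' Hemodynamic (balloon) flow in log-state form
#'
#' Derivatives of the four hemodynamic states per region given the neuronal
#' state: vasodilatory signal \code{s}, log normalised flow \code{lf}, log
#' normalised volume \code{lv} and log normalised deoxyhemoglobin \code{lq}.
#' At rest (all states and x zero) every derivative is zero.
#'
#' @param h list or vector with elements \code{s, lf, lv, lq} (scalars, one
#'   region)
#' @param x neuronal state (scalar)
#' @param hemo a \code{\link{hemo_defaults}} object (first region used) or a
#'   named vector with kappa, gamma, tau, alpha, rho, epsilon
#' @return named vector of derivatives \code{(ds, dlf, dlv, dlq)}
#' @export
hemodynamic_flow <- function(h, x, hemo = hemo_defaults(1)) {
  p <- if (inherits(hemo, "dcm_hemo")) hemo$par[1, ] else hemo
  if (p[["tau"]] <= 0 || p[["alpha"]] <= 0 || p[["alpha"]] >= 1 ||
      p[["rho"]] <= 0 || p[["rho"]] >= 1)
    stop("invalid hemodynamic parameters")
  h <- as.list(h)
  ef <- exp(h$lf)
  fv <- exp(h$lv / p[["alpha"]])
  Ef <- 1 - (1 - p[["rho"]])^(1 / ef)
  c(ds = p[["epsilon"]] * x - p[["kappa"]] * h$s - p[["gamma"]] * (ef - 1),
    dlf = h$s * exp(-h$lf),
    dlv = (ef - fv) * exp(-h$lv) / p[["tau"]],
    dlq = (ef * Ef / p[["rho"]] - fv * exp(h$lq - h$lv)) *
      exp(-h$lq) / p[["tau"]])
}

#' Static BOLD observation equation
#'
#' Percent signal change from the hemodynamic log-states:
#' \code{100 V0 (k1 (1 - e^lq) + k2 (1 - e^(lq - lv)) + k3 (1 - e^lv))}.
#'
#' @inheritParams hemodynamic_flow
#' @return percent signal change (scalar)
#' @export
bold_observation <- function(h, hemo = hemo_defaults(1)) {
  ob <- if (inherits(hemo, "dcm_hemo")) hemo$obs[1, ] else hemo
  h <- as.list(h)
  ob[["V0"]] * (ob[["k1"]] * (1 - exp(h$lq)) +
                ob[["k2"]] * (1 - exp(h$lq - h$lv)) +
                ob[["k3"]] * (1 - exp(h$lv)))
}

#' Orthogonal discrete cosine basis set
#'
#' Type-II DCT basis over T samples; component 1 is the constant term. The
#' default number of components is one quarter of the length of the series
#' (64 components for T = 256). Columns are orthonormal.
#'
#' @param T number of time samples
#' @param J number of components (default \code{floor(T / 4)})
#' @return T x J matrix of class \code{dcm_basis}
#' @export
dct_basis <- function(T, J = floor(T / 4)) {
  if (J < 1 || J > T) stop("need 1 <= J <= T")
  t <- seq_len(T) - 1
  U <- vapply(seq_len(J) - 1,
              function(j) cos(pi * j * (2 * t + 1) / (2 * T)), numeric(T))
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  structure(U, class = c("dcm_basis", "matrix"), kind = "dct")
}

#' Node-by-time series container
#'
#' @param data T x n numeric matrix (% signal change; rows are time samples)
#' @param dt sampling interval / repetition time (seconds)
#' @param labels node names
#' @return object of class \code{dcm_timeseries}
#' @export
node_timeseries <- function(data, dt, labels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 time samples")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (anyNA(data)) stop("missing values in time series")
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("node", seq_len(ncol(data)))
  colnames(data) <- labels
  structure(list(data = data, dt = dt, labels = labels),
            class = "dcm_timeseries")
}

#' @export
print.dcm_timeseries <- function(x, ...) {
  cat(sprintf("Node time series: %d samples x %d nodes, dt = %.3g s (%.1f s total)\n",
              nrow(x$data), ncol(x$data), x$dt, nrow(x$data) * x$dt))
  cat("  nodes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Integrate the generative model
#'
#' Advances the linear neuronal network and the per-region balloon
#' hemodynamics jointly on a sub-sampled grid (matrix-exponential propagation
#' of the neuronal states, RK4 for the hemodynamic log-states) and emits the
#' noiseless BOLD signal every \code{dt} seconds. Sample k corresponds to
#' time (k-1) dt; the neuronal drive is held piecewise-constant within each
#' output bin. The drive can be given either directly as a T x n fluctuation
#' matrix \code{omega} or as input weights \code{C} with a basis set
#' \code{U} (drive = \code{U \%*\% t(C)}).
#'
#' @param A n x n coupling matrix (Hz); a warning is issued if its spectral
#'   abscissa is non-negative
#' @param T number of output samples
#' @param dt output sampling interval (s)
#' @param omega T x n neuronal fluctuation matrix (Hz)
#' @param C,U alternative drive specification (n x J weights, T x J basis)
#' @param hemo a \code{\link{hemo_defaults}} object
#' @param nsub integration sub-steps per output bin
#' @param hemo_noise optional T x (4 n) matrix of additive perturbations to
#'   the hemodynamic derivatives (columns region-major: s, lf, lv, lq)
#' @param neuronal_only if TRUE the observation is the neuronal state itself
#'   (hemodynamics bypassed)
#' @param want_states if TRUE also return the hidden-state trajectory
#' @return a list with \code{signal} (a \code{\link{node_timeseries}}) and,
#'   if requested, \code{states} (T x 5n matrix: x, s, lf, lv, lq
#'   region-major)
#' @export
integrate_dcm <- function(A, T, dt, omega = NULL, C = NULL, U = NULL,
                          hemo = hemo_defaults(nrow(A)), nsub = 8,
                          hemo_noise = NULL, neuronal_only = FALSE,
                          want_states = FALSE) {
  n <- nrow(A)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    warning("coupling matrix has non-negative spectral abscissa; ",
            "dynamics may be unstable")
  if (is.null(omega)) {
    if (is.null(C) || is.null(U))
      stop("supply either omega or both C and U")
    omega <- U %*% t(C)
  }
  if (nrow(omega) != T || ncol(omega) != n)
    stop("omega must be T x n")
  hn <- if (is.null(hemo_noise)) matrix(0, 0, 0) else as.matrix(hemo_noise)
  out <- .dcm_forward_cpp(A, omega, hemo$par, hemo$obs, dt, nsub, hn,
                          neuronal_only, want_states)
  res <- list(signal = node_timeseries(out$signal, dt))
  if (want_states) {
    st <- out$states
    colnames(st) <- paste0(rep(c("x", "s", "lf", "lv", "lq"), each = n),
                           "_", rep(seq_len(n), 5))
    res$states <- st
  }
  res
}
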