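#' Control parameters for model inversion
#'
#' @param maxit maximum Gauss-Newton iterations
#' @param tol convergence: stop when the free-energy improvement over the
#'   last three accepted iterations, relative to |F|, falls below \code{tol}
#'   and the last single-step improvement is below 1 nat
#' @param step central finite-difference step for the Jacobian
#' @param damping initial Levenberg damping (halved on accepted steps,
#'   doubled on rejections)
#' @param nsub integration sub-steps per output bin
#' @param max_reject damping retries per iteration before declaring
#'   convergence
#' @param update_c_variance optimise the prior variance of the input
#'   weights by empirical Bayes (maximising the free energy along with the
#'   noise precisions); the amplitude of the unknown neuronal fluctuations
#'   varies between datasets and a mismatched input prior either lets the
#'   basis set absorb all cross-node structure or prevents the model from
#'   fitting at all
#' @param c_pool partial-pooling weight for the per-node input variances
#'   on the log scale: 0 = one shared variance across nodes (fluctuation
#'   amplitudes assumed identical), 1 = fully independent per node
#' @param c_tighten multiplier on the empirical-Bayes input variances; a
#'   value below 1 asserts deliberately overconfident (smaller) fluctuation
#'   amplitudes than the data suggest
#' @return list of class \code{dcm_invert_control}
#' @export
invert_control <- function(maxit = 64, tol = 1e-2, step = 1e-4,
                           damping = 1 / 64, nsub = 4, max_reject = 16,
                           update_c_variance = TRUE, c_pool = 0.5,
                           c_tighten = 1) {
  structure(as.list(environment()), class = "dcm_invert_control")
}

#' Set up the fully connected model
#'
#' Priors for a DCM with every connection permitted, together with the
#' discrete cosine basis set that models the unknown neuronal fluctuations
#' (number of components = one quarter of the series length by default).
#'
#' @param n_nodes number of nodes
#' @param T number of time samples
#' @param dt sampling interval (s)
#' @param config a \code{\link{prior_config}}
#' @param n_inputs number of basis components (default \code{floor(T / 4)})
#' @return list with \code{priors} (a \code{dcm_priors}) and \code{basis}
#'   (a \code{\link{dct_basis}})
#' @export
build_full_model <- function(n_nodes, T, dt, config = prior_config(),
                             n_inputs = floor(T / 4), ac_width = 2) {
  if (T < 16) stop("need at least 16 samples")
  full <- adjacency(matrix(1, n_nodes, n_nodes))
  list(priors = priors_from_adjacency(full, n_inputs = n_inputs,
                                      config = config,
                                      c_shape = dct_shape(T, n_inputs,
                                                          ac_width)),
       basis = dct_basis(T, n_inputs))
}

#' Spectral weights of the input prior
#'
#' Relative prior variance of each cosine component for fluctuations with
#' a Gaussian autocorrelation function of standard deviation
#' \code{ac_width} bins: component j (frequency j / 2T cycles per bin)
#' gets weight proportional to the power spectrum
#' \code{exp(-pi^2 ac_width^2 j^2 / (2 T^2))}, normalised to mean 1. This
#' is the deterministic counterpart of a smoothness prior on the
#' fluctuations.
#'
#' @param T series length
#' @param J number of components
#' @param ac_width autocorrelation width in bins (0 for flat weights)
#' @return length-J weight vector
#' @export
dct_shape <- function(T, J, ac_width = 2) {
  if (ac_width <= 0) return(rep(1, J))
  w <- exp(-pi^2 * ac_width^2 * (seq_len(J) - 1)^2 / (2 * T^2))
  w / mean(w)
}

#' Pack coupling, input and hemodynamic parameters into a stacked vector
#'
#' Layout: \code{[vec(A), vec(C), log-scaling of kappa per region,
#' log-scaling of tau per region]} (column-major blocks), matching the
#' ordering of \code{\link{priors_from_adjacency}}.
#'
#' @param A n x n coupling matrix
#' @param C n x J input-weight matrix (or NULL for J = 0)
#' @param lambda_kappa,lambda_tau per-region log-scalings of the
#'   hemodynamic decay and transit parameters
#' @return numeric vector
#' @export
pack_theta <- function(A, C = NULL, lambda_kappa = 0, lambda_tau = 0) {
  n <- nrow(A)
  c(as.vector(A), if (!is.null(C)) as.vector(C),
    rep_len(lambda_kappa, n), rep_len(lambda_tau, n))
}

# infer n from a stacked parameter length and basis width
theta_nodes <- function(len, J) {
  n <- (-(J + 2) + sqrt((J + 2)^2 + 4 * len)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("parameter vector length inconsistent with basis width")
  as.integer(round(n))
}

#' Forward prediction from a stacked parameter vector
#'
#' Deterministic BOLD prediction of the model: the basis-weighted input
#' drives the linear neuronal network, whose states drive the balloon
#' hemodynamics.
#'
#' @param theta stacked parameter vector (see \code{\link{pack_theta}})
#' @param basis T x J basis matrix
#' @param dt sampling interval (s)
#' @param hemo baseline hemodynamic parameters (scaled per region by the
#'   packed log-scalings); default \code{\link{hemo_defaults}}
#' @param nsub integration sub-steps
#' @return a \code{\link{node_timeseries}} of predicted signal
#' @export
predict_bold <- function(theta, basis, dt, hemo = NULL, nsub = 8) {
  n <- theta_nodes(length(theta), ncol(basis))
  if (is.null(hemo)) hemo <- hemo_defaults(n)
  sig <- .dcm_predict_cpp(theta, n, unclass(basis), hemo$par, hemo$obs,
                          dt, nsub)
  node_timeseries(sig, dt)
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' \code{KL(N(m1, S1) || N(m0, S0))}; the complexity term of the Laplace
#' free energy. Accepts scalars (variances) or matrices (covariances).
#'
#' @param m1,S1 posterior mean and covariance
#' @param m0,S0 prior mean and covariance
#' @return divergence in nats
#' @export
gaussian_kl <- function(m1, S1, m0, S0) {
  m1 <- as.numeric(m1); m0 <- as.numeric(m0)
  S1 <- as.matrix(S1); S0 <- as.matrix(S0)
  k <- length(m1)
  P0 <- solve(S0)
  d <- m1 - m0
  0.5 * (sum(diag(P0 %*% S1)) + sum(d * (P0 %*% d)) - k +
         determinant(S0)$modulus - determinant(S1)$modulus)[[1]]
}

# Laplace free energy given sufficient statistics
# rss, lp, lp_var per node; d = mu - prior mean (free), Pv prior precisions,
# vfree prior variances, logdetH = -logdet(Sigma), diagSig = diag(Sigma)
laplace_F <- function(T, rss, lp, lp_var, lp0, v0, d, Pv, vfree,
                      logdetH, diagSig) {
  loglik <- sum(-(T / 2) * log(2 * pi) + (T / 2) * lp -
                0.5 * exp(lp) * rss)
  klp <- 0.5 * (sum(Pv * diagSig) + sum(Pv * d^2) - length(d) +
                sum(log(vfree)) + logdetH)
  klh <- sum(0.5 * ((lp_var + (lp - lp0)^2) / v0 - 1 + log(v0 / lp_var)))
  loglik - klp - klh
}

#' Invert the fully connected model by variational Laplace
#'
#' Gauss-Newton ascent on the Laplace free energy with Levenberg damping
#' (steps that lower the free energy, destabilise the coupling matrix or
#' blow up the integration are rejected and the damping doubled), alternated
#' with closed-form Newton updates of the per-node observation-noise
#' log-precisions under their Gaussian prior. Parameters with zero prior
#' variance are pinned at their prior mean and excluded from the free set.
#' The returned covariance is the inverse curvature at the optimum,
#' symmetrised with an eigenvalue floor of 1e-12.
#'
#' @param ts a \code{\link{node_timeseries}}
#' @param priors a \code{\link{priors_from_adjacency}} object (from
#'   \code{\link{build_full_model}} for the full graph, or any nested
#'   adjacency for explicit reduced-model inversion)
#' @param basis the basis set from \code{\link{build_full_model}}
#' @param control a \code{\link{invert_control}}
#' @param hemo baseline hemodynamic parameters (defaults)
#' @param init optional named vector of starting values for a subset of
#'   the free parameters (names as in the index map); useful for warm
#'   starts, e.g. explicit reduced-model inversions started from the
#'   full-model posterior
#' @return object of class \code{dcm_posterior}: \code{mean},
#'   \code{covariance} and \code{index_map} over the free parameters,
#'   \code{theta} (full stacked vector at the optimum), \code{free}
#'   (indices of free parameters), \code{free_energy}, per-node
#'   \code{noise_logprec} and \code{noise_logprec_var}, the free-energy
#'   \code{trace}, and the \code{priors} used
#' @export
invert_full <- function(ts, priors, basis, control = invert_control(),
                        hemo = NULL, init = NULL) {
  y <- ts$data
  T <- nrow(y); n <- ncol(y); dt <- ts$dt
  if (nrow(basis) != T) stop("basis and series lengths differ")
  if (length(priors$mean) != n * n + n * ncol(basis) + 2 * n)
    stop("priors inconsistent with series and basis dimensions")
  if (is.null(hemo)) hemo <- hemo_defaults(n)
  U <- unclass(basis)
  cfg <- priors$config
  lp0 <- cfg$noise_logprec_mean; v0 <- cfg$noise_logprec_variance

  free <- which(priors$variance > 0)
  mfree <- priors$mean[free]
  vfree <- priors$variance[free]
  Pv <- 1 / vfree
  imap_free <- priors$index_map[free, , drop = FALSE]
  # input-weight indices grouped by receiving node (per-node amplitude
  # hyperparameters: fluctuation strength differs between nodes); cbase
  # holds the spectral shape of the input prior, which empirical Bayes
  # rescales but does not reshape
  cgroups <- split(which(imap_free$block == "C"),
                   imap_free$row[imap_free$block == "C"])
  cbase <- vfree
  theta0 <- priors$mean
  rows <- lapply(seq_len(n), function(i) (i - 1) * T + seq_len(T))
  yv <- as.vector(y)
  a_idx <- seq_len(n * n)

  fwd <- function(theta)
    tryCatch(.dcm_predict_cpp(theta, n, U, hemo$par, hemo$obs, dt,
                              control$nsub),
             error = function(e) NULL)

  # full evaluation at mu: forward, Jacobian, noise and input-variance
  # updates, curvature and F. Pure: hyperparameter updates live in the
  # returned state and are only adopted when the step is accepted.
  eval_state <- function(mu, lp, vfree_l, Pv_l) {
    theta <- theta0; theta[free] <- mu
    g <- fwd(theta)
    if (is.null(g)) return(NULL)
    r <- yv - as.vector(g)
    Jm <- .dcm_jacobian_cpp(theta, n, U, hemo$par, hemo$obs, dt,
                            control$nsub, free - 1L, control$step)
    G <- lapply(rows, function(ri) crossprod(Jm[ri, , drop = FALSE]))
    rss <- vapply(rows, function(ri) sum(r[ri]^2), 0)
    curvature <- function() {
      H <- Reduce(`+`, Map(function(Gi, l) exp(l) * Gi, G, as.list(lp)))
      diag(H) <- diag(H) + Pv_l
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(ch)) {
        diag(H) <- diag(H) * (1 + 1e-8) + 1e-10
        ch <- tryCatch(chol(H), error = function(e) NULL)
      }
      if (is.null(ch)) return(NULL)
      list(H = H, Sig = chol2inv(ch), logdetH = 2 * sum(log(diag(ch))))
    }
    S <- rss
    for (pass in 1:3) {
      cv <- curvature()
      if (is.null(cv)) return(NULL)
      tr <- vapply(G, function(Gi) sum(cv$Sig * Gi), 0)
      S <- rss + tr
      for (nt in 1:4) {
        d1 <- T / 2 - 0.5 * exp(lp) * S - (lp - lp0) / v0
        d2 <- -0.5 * exp(lp) * S - 1 / v0
        lp <- lp - d1 / d2
      }
      if (control$update_c_variance && length(cgroups) > 0) {
        # ML-II update of the per-node input-weight prior scales,
        # partially pooled on the log scale; c_tighten < 1 makes the
        # assumed fluctuation amplitude deliberately overconfident
        dS <- diag(cv$Sig)
        lv <- vapply(cgroups, function(ci)
          log(mean((mu[ci]^2 + dS[ci]) / cbase[ci])), 0)
        lv <- mean(lv) + control$c_pool * (lv - mean(lv))
        lv <- pmin(pmax(lv + log(control$c_tighten), -12), 12)
        for (k in seq_along(cgroups)) {
          ci <- cgroups[[k]]
          vfree_l[ci] <- exp(lv[k]) * cbase[ci]
          Pv_l[ci] <- 1 / vfree_l[ci]
        }
      }
    }
    # final curvature consistent with the updated hyperparameters
    cv <- curvature()
    if (is.null(cv)) return(NULL)
    tr <- vapply(G, function(Gi) sum(cv$Sig * Gi), 0)
    S <- rss + tr
    lp_var <- 1 / (0.5 * exp(lp) * S + 1 / v0)
    d <- mu - mfree
    Fv <- laplace_F(T, rss, lp, lp_var, lp0, v0, d, Pv_l, vfree_l,
                    cv$logdetH, diag(cv$Sig))
    grad <- Reduce(`+`, Map(function(i)
      exp(lp[i]) * crossprod(Jm[rows[[i]], , drop = FALSE], r[rows[[i]]]),
      seq_len(n)))
    grad <- as.vector(grad) - Pv_l * d
    list(mu = mu, lp = lp, lp_var = lp_var, g = g, r = r, rss = rss,
         H = cv$H, Sig = cv$Sig, logdetH = cv$logdetH, grad = grad,
         F = Fv, vfree = vfree_l, Pv = Pv_l)
  }

  # penalised log-joint at fixed hyperparameters (cheap proposal screen)
  cheap_L <- function(mu, g, lp, Pv_l) {
    r <- yv - as.vector(g)
    rss <- vapply(rows, function(ri) sum(r[ri]^2), 0)
    sum((T / 2) * lp - 0.5 * exp(lp) * rss) -
      0.5 * sum(Pv_l * (mu - mfree)^2)
  }

  mu_init <- mfree
  if (!is.null(init)) {
    hit <- match(imap_free$name, names(init))
    mu_init[!is.na(hit)] <- init[hit[!is.na(hit)]]
  }
  acc <- eval_state(mu_init, rep(lp0, n), vfree, Pv)
  if (is.null(acc) || !is.finite(acc$F))
    stop("inversion failed: non-finite free energy at the prior mean")
  Fhist <- acc$F
  lambda <- control$damping

  for (iter in seq_len(control$maxit)) {
    L_acc <- cheap_L(acc$mu, acc$g, acc$lp, acc$Pv)
    accepted <- FALSE
    for (try in seq_len(control$max_reject)) {
      dH <- diag(acc$H)
      Hd <- acc$H
      diag(Hd) <- dH * (1 + lambda)
      dmu <- tryCatch(solve(Hd, acc$grad), error = function(e) NULL)
      if (is.null(dmu)) { lambda <- lambda * 2; next }
      mu_c <- acc$mu + dmu
      theta_c <- theta0; theta_c[free] <- mu_c
      Ac <- matrix(theta_c[a_idx], n, n)
      if (max(Re(eigen(Ac, only.values = TRUE)$values)) >= 0) {
        lambda <- lambda * 2; next
      }
      g_c <- fwd(theta_c)
      if (is.null(g_c) || cheap_L(mu_c, g_c, acc$lp, acc$Pv) <= L_acc) {
        lambda <- lambda * 2; next
      }
      cand <- eval_state(mu_c, acc$lp, acc$vfree, acc$Pv)
      if (is.null(cand) || !is.finite(cand$F) || cand$F <= acc$F) {
        lambda <- lambda * 2; next
      }
      acc <- cand
      lambda <- max(lambda / 2, 1e-8)
      accepted <- TRUE
      break
    }
    if (!accepted) break
    Fhist <- c(Fhist, acc$F)
    nf <- length(Fhist)
    if (nf >= 4) {
      dF3 <- Fhist[nf] - Fhist[nf - 3]
      dF1 <- Fhist[nf] - Fhist[nf - 1]
      if (dF3 / max(1, abs(Fhist[nf])) < control$tol &&
          dF1 < 100 * control$tol) break
    }
  }

  Sig <- (acc$Sig + t(acc$Sig)) / 2
  e <- eigen(Sig, symmetric = TRUE)
  Sig <- e$vectors %*% (pmax(e$values, 1e-12) * t(e$vectors))
  Sig <- (Sig + t(Sig)) / 2
  theta <- theta0; theta[free] <- acc$mu
  imap <- priors$index_map[free, , drop = FALSE]
  rownames(Sig) <- colnames(Sig) <- imap$name
  priors$variance[free] <- acc$vfree  # carry empirical-Bayes updates
  structure(list(mean = setNames(acc$mu, imap$name), covariance = Sig,
                 index_map = imap, free = free, theta = theta,
                 free_energy = acc$F, noise_logprec = acc$lp,
                 noise_logprec_var = acc$lp_var, trace = Fhist,
                 priors = priors, n_nodes = n, n_inputs = ncol(basis),
                 dt = dt, nsub = control$nsub, rss = acc$rss,
                 c_variance = vapply(cgroups, function(ci)
                   acc$vfree[ci[1]] / cbase[ci[1]] *
                     priors$config$c_variance, 0)),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf(paste0("DCM posterior: %d free parameters over %d nodes\n",
                     "  free energy %.2f after %d accepted iterations\n",
                     "  noise log-precision: %s\n"),
              length(x$mean), x$n_nodes, x$free_energy,
              length(x$trace) - 1,
              paste(sprintf("%.2f", x$noise_logprec), collapse = " ")))
  invisible(x)
}

#' Posterior mean coupling matrix
#'
#' @param posterior a \code{dcm_posterior}
#' @return n x n matrix of posterior expectations of A (pinned entries at
#'   their prior mean, i.e. zero for absent edges)
#' @export
posterior_coupling <- function(posterior) {
  n <- posterior$n_nodes
  matrix(posterior$theta[seq_len(n * n)], n, n)
}

#' Laplace free energy of a fitted posterior
#'
#' Recomputes the free-energy bound from a posterior and data: expected
#' log-likelihood at the posterior mode, minus the Gaussian KL divergence of
#' the parameter posterior from its prior, minus the KL of the noise
#' log-precision posteriors from theirs.
#'
#' @param posterior a \code{dcm_posterior}
#' @param priors the priors it was fitted under
#' @param ts the data
#' @param basis the basis set
#' @param hemo baseline hemodynamic parameters
#' @return free energy (nats)
#' @export
free_energy <- function(posterior, priors, ts, basis, hemo = NULL) {
  n <- posterior$n_nodes; T <- nrow(ts$data)
  nsub <- if (is.null(posterior$nsub)) 8 else posterior$nsub
  pred <- predict_bold(posterior$theta, basis, ts$dt, hemo = hemo,
                       nsub = nsub)
  r <- ts$data - pred$data
  rss <- colSums(r^2)
  free <- posterior$free
  vfree <- priors$variance[free]
  d <- posterior$mean - priors$mean[free]
  cfg <- priors$config
  ch <- chol(posterior$covariance)
  laplace_F(T, rss, posterior$noise_logprec, posterior$noise_logprec_var,
            cfg$noise_logprec_mean, cfg$noise_logprec_variance,
            d, 1 / vfree, vfree, -2 * sum(log(diag(ch))),
            diag(posterior$covariance))
}
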