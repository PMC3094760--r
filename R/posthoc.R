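# log density of N(mean, Sigma) at zero, with marginal variances floored
log_density_at_zero <- function(mu, Sigma, floor = 1e-12) {
  Sigma <- as.matrix(Sigma)
  diag(Sigma) <- pmax(diag(Sigma), floor)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("singular marginal covariance over parameters: ",
         paste(colnames(Sigma), collapse = ", "))
  z <- backsolve(ch, mu, transpose = TRUE)
  -0.5 * length(mu) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Savage-Dickey log evidence of a reduced model
#'
#' Relative log evidence of the model obtained from the full model by
#' pinning the parameters in \code{reduced_idx} at zero: the log marginal
#' posterior density at zero minus the log marginal prior density at zero,
#' both under the full model. The full model itself (empty reduction)
#' scores exactly 0.
#'
#' @param posterior a \code{dcm_posterior} for the full model
#' @param priors the priors the full model was inverted under
#' @param reduced_idx parameters to pin at zero: integer indices into the
#'   free-parameter vector or character names from the index map
#' @return relative log evidence (nats; full model = 0)
#' @export
log_evidence_reduced <- function(posterior, priors, reduced_idx) {
  if (length(reduced_idx) == 0) return(0)
  if (is.character(reduced_idx)) {
    idx <- match(reduced_idx, posterior$index_map$name)
    if (anyNA(idx))
      stop("unknown parameter(s): ",
           paste(reduced_idx[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(reduced_idx)
  if (any(idx < 1 | idx > length(posterior$mean)))
    stop("reduced_idx outside the free parameter set")
  mu <- posterior$mean[idx]
  S <- posterior$covariance[idx, idx, drop = FALSE]
  v <- priors$variance[posterior$free][idx]
  if (any(v <= 0))
    stop("reduced parameters must have nonsingular priors")
  lq <- log_density_at_zero(mu, S)
  lpr <- -0.5 * length(idx) * log(2 * pi) - 0.5 * sum(log(v))
  lq - lpr
}

# names of the directed off-diagonal A parameters a model switches off/on
offdiag_params <- function(adj, value) {
  m <- unclass(adj)
  idx <- which(m == value & row(m) != col(m), arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  sprintf("A[%d,%d]", idx[, 1], idx[, 2])
}

#' Score a set of models from the full-model posterior
#'
#' Relative log evidence of every candidate adjacency by the Savage-Dickey
#' proxy (absent directed couplings pinned at zero, jointly over their
#' marginal Gaussian posterior), optionally minus a fixed log-prior cost per
#' reciprocal connection, and the implied posterior probabilities under flat
#' priors over the scored set.
#'
#' @param posterior a \code{dcm_posterior} of the full model
#' @param priors its priors
#' @param models list of \code{\link{adjacency}} objects, e.g. from
#'   \code{\link{enumerate_models}}; every model must be nested in the
#'   inverted adjacency (only free couplings may be switched off)
#' @param penalty_per_connection log-prior cost per reciprocal connection
#'   (default 0)
#' @return data.frame of class \code{dcm_score_table}: \code{model_index}
#'   (canonical index), \code{n_connections}, \code{log_evidence} (nats,
#'   full model = 0 before penalty), \code{posterior_prob}; the scored
#'   adjacencies are kept in \code{attr(, "models")} and the selected model
#'   (ties broken towards fewer connections, then lower index) in
#'   \code{attr(, "selected")}
#' @export
score_model_space <- function(posterior, priors, models,
                              penalty_per_connection = 0) {
  pinned <- priors$index_map$name[priors$variance == 0]
  le <- numeric(length(models))
  nc <- integer(length(models))
  midx <- numeric(length(models))
  for (k in seq_along(models)) {
    adj <- models[[k]]
    absent <- offdiag_params(adj, 0)
    present <- offdiag_params(adj, 1)
    if (any(present %in% pinned))
      stop("model ", k, " is not nested in the inverted model: it permits ",
           "a coupling the full model pinned at zero")
    nc[k] <- n_connections(adj)
    midx[k] <- adjacency_to_model_index(adj)
    le[k] <- log_evidence_reduced(posterior, priors,
                                  setdiff(absent, pinned)) -
      penalty_per_connection * nc[k]
  }
  w <- exp(le - max(le))
  tab <- data.frame(model_index = midx, n_connections = nc,
                    log_evidence = le, posterior_prob = w / sum(w))
  ord <- order(-tab$log_evidence, tab$n_connections, tab$model_index)
  best <- ord[1]
  structure(tab, class = c("dcm_score_table", "data.frame"),
            models = models, selected = models[[best]],
            selected_row = best,
            penalty_per_connection = penalty_per_connection)
}

#' @export
print.dcm_score_table <- function(x, ...) {
  cat(sprintf("Model scores over %d models (penalty %.3g nats/connection)\n",
              nrow(x), attr(x, "penalty_per_connection")))
  best <- attr(x, "selected_row")
  cat(sprintf("  selected: model %d (%d connections, posterior prob %.3f)\n",
              x$model_index[best], x$n_connections[best],
              x$posterior_prob[best]))
  NextMethod()
  invisible(x)
}

#' Selected adjacency of a score table
#'
#' @param scores a \code{dcm_score_table}
#' @return the winning \code{\link{adjacency}}
#' @export
selected_model <- function(scores) attr(scores, "selected")

#' Greedy post hoc pruning of redundant connections
#'
#' Iteratively removes the connections whose removal has the smallest
#' (non-negative) effect on the Savage-Dickey log evidence: each pass scores
#' the single-unit removals relative to the current reduced model, removes
#' up to \code{batch} units whose removal log evidence is >= 0 (largest,
#' i.e. least harmful, first), and repeats to a fixed point. Units are
#' reciprocal pairs by default (\code{pair_mode}), or individual directed
#' couplings.
#'
#' @param posterior a \code{dcm_posterior} of the full model
#' @param priors its priors
#' @param batch maximum removals per pass (<= 8)
#' @param pair_mode treat reciprocal pairs as single units
#' @return list with \code{adjacency} (the pruned graph), \code{removed}
#'   (unit labels in removal order) and \code{trace} (per-pass data.frames
#'   of candidate scores)
#' @export
greedy_prune <- function(posterior, priors, batch = 8, pair_mode = TRUE) {
  if (batch < 1 || batch > 8) stop("batch must be in 1..8")
  n <- posterior$n_nodes
  free_A <- posterior$index_map[posterior$index_map$block == "A" &
                                posterior$index_map$row !=
                                posterior$index_map$col, , drop = FALSE]
  if (pair_mode) {
    key <- pmin(free_A$row, free_A$col) * (n + 1) + pmax(free_A$row,
                                                         free_A$col)
    units <- split(free_A$name, key)
    names(units) <- vapply(units, function(u)
      paste(sort(u), collapse = "+"), "")
  } else {
    units <- as.list(free_A$name)
    names(units) <- free_A$name
  }
  removed <- character(0)
  removed_params <- character(0)
  trace <- list()
  repeat {
    remaining <- setdiff(names(units), removed)
    if (length(remaining) == 0) break
    base <- log_evidence_reduced(posterior, priors, removed_params)
    delta <- vapply(remaining, function(u)
      log_evidence_reduced(posterior, priors,
                           c(removed_params, units[[u]])) - base, 0)
    trace[[length(trace) + 1]] <-
      data.frame(unit = remaining, delta = unname(delta))
    ok <- remaining[delta >= 0]
    if (length(ok) == 0) break
    ok <- ok[order(-delta[ok])]
    cand <- utils::head(ok, batch)
    # commit the prefix of the sorted batch whose joint removal gains the
    # most evidence (a batch can be jointly harmful even when each member
    # is individually redundant)
    joint <- vapply(seq_along(cand), function(k)
      log_evidence_reduced(posterior, priors,
                           c(removed_params,
                             unlist(units[cand[seq_len(k)]]))) - base, 0)
    if (max(joint) < 0) break
    take <- cand[seq_len(which.max(joint))]
    removed <- c(removed, take)
    removed_params <- c(removed_params, unlist(units[take]))
  }
  m <- matrix(0, n, n); diag(m) <- 1
  kept <- setdiff(free_A$name, removed_params)
  if (length(kept)) {
    ij <- do.call(rbind, regmatches(kept, regexec("A\\[(\\d+),(\\d+)\\]",
                                                  kept)))
    for (k in seq_len(nrow(ij))) {
      i <- as.integer(ij[k, 2]); j <- as.integer(ij[k, 3])
      m[i, j] <- m[j, i] <- 1
    }
  }
  list(adjacency = adjacency(m), removed = removed, trace = trace)
}

#' Compare Savage-Dickey scores against explicit reduced-model inversions
#'
#' For each candidate model, returns the proxy score (from the full-model
#' posterior) alongside the free-energy difference obtained by explicitly
#' inverting the reduced model on the same data. The two should agree in
#' rank when the Laplace bound is tight.
#'
#' @param posterior a \code{dcm_posterior} of the full model
#' @param priors,basis,ts the full-model priors, basis and data
#' @param models list of nested \code{\link{adjacency}} objects
#' @param control inversion control for the explicit fits
#' @param hemo baseline hemodynamic parameters
#' @return data.frame: model_index, n_connections, proxy (Savage-Dickey,
#'   nats), explicit (F_reduced - F_full, nats)
#' @export
compare_to_explicit <- function(posterior, priors, basis, ts, models,
                                control = invert_control(), hemo = NULL) {
  scores <- score_model_space(posterior, priors, models)
  explicit <- vapply(models, function(adj) {
    pri <- priors_from_adjacency(adj, n_inputs = priors$n_inputs,
                                 config = priors$config,
                                 c_shape = priors$c_shape)
    fit <- invert_full(ts, pri, basis, control = control, hemo = hemo,
                       init = posterior$mean)
    fit$free_energy - posterior$free_energy
  }, 0)
  data.frame(model_index = scores$model_index,
             n_connections = scores$n_connections,
             proxy = scores$log_evidence, explicit = explicit)
}
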