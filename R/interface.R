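#' Read / write node time series as delimited text
#'
#' Tab-delimited matrix with a one-line header of node labels, one row per
#' time sample. The sampling interval is not stored in the file and must be
#' supplied on reading (CLI flag \code{--tr}).
#'
#' @param ts a \code{\link{node_timeseries}}
#' @param file path
#' @name series_io
#' @export
write_node_series <- function(ts, file) {
  write.table(ts$data, file, sep = "\t", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
}

#' @param dt sampling interval in seconds
#' @rdname series_io
#' @export
read_node_series <- function(file, dt) {
  x <- as.matrix(read.table(file, header = TRUE, sep = "\t",
                            check.names = FALSE))
  node_timeseries(x, dt)
}

#' End-to-end network discovery
#'
#' Chains full-model inversion, model-space search (exhaustive when the
#' bidirectional space fits the enumeration limit, greedy otherwise) and
#' graph characterisation (spectral embedding and hierarchy ordering of the
#' selected graph), returning one report.
#'
#' @param ts a \code{\link{node_timeseries}}
#' @param config a \code{\link{prior_config}}
#' @param control a \code{\link{invert_control}}
#' @param mode \code{"exhaustive"}, \code{"greedy"} or \code{"auto"}
#'   (exhaustive when the space fits \code{limit})
#' @param limit enumeration capacity for the exhaustive search
#' @param penalty_per_connection log-prior cost per reciprocal connection
#' @param posterior optionally, a precomputed \code{dcm_posterior} for this
#'   data (skips the inversion stage)
#' @return list of class \code{dcm_report}: \code{posterior},
#'   \code{scores} (NULL in greedy mode), \code{selected} (adjacency),
#'   \code{coupling} (posterior mean A), \code{embedding},
#'   \code{hierarchy}, \code{mode}, \code{n_models_scored}
#' @export
run_discovery <- function(ts, config = prior_config(),
                          control = invert_control(),
                          mode = c("auto", "exhaustive", "greedy"),
                          limit = 2^20, penalty_per_connection = 0,
                          posterior = NULL) {
  mode <- match.arg(mode)
  n <- ncol(ts$data)
  T <- nrow(ts$data)
  setup <- build_full_model(n, T, ts$dt, config = config)
  if (is.null(posterior))
    posterior <- invert_full(ts, setup$priors, setup$basis,
                             control = control)
  if (mode == "auto")
    mode <- if (count_models(n) <= limit) "exhaustive" else "greedy"
  if (mode == "exhaustive") {
    models <- enumerate_models(n, limit = limit)
    scores <- score_model_space(posterior, setup$priors, models,
                                penalty_per_connection)
    selected <- selected_model(scores)
    n_scored <- length(models)
  } else {
    pruned <- greedy_prune(posterior, setup$priors)
    scores <- NULL
    selected <- pruned$adjacency
    n_scored <- sum(vapply(pruned$trace, nrow, 0L))
  }
  A_sel <- posterior_coupling(posterior) * unclass(selected)
  W <- weighted_adjacency(A_sel)
  structure(list(posterior = posterior, scores = scores,
                 selected = selected, coupling = A_sel,
                 embedding = spectral_embedding(graph_laplacian(W),
                                                k = min(3, n - 1)),
                 hierarchy = hierarchy_order(A_sel, labels = ts$labels),
                 mode = mode, n_models_scored = n_scored),
            class = "dcm_report")
}

#' @export
print.dcm_report <- function(x, ...) {
  cat(sprintf(paste0("Network discovery report (%s search, %d models",
                     " scored)\n"), x$mode, x$n_models_scored))
  cat(sprintf("  selected graph: %d of %d reciprocal connections\n",
              n_connections(x$selected),
              attr(x$selected, "n_nodes") *
                (attr(x$selected, "n_nodes") - 1) / 2))
  print(x$hierarchy)
  invisible(x)
}

#' Serialise a discovery report to JSON
#'
#' @param report a \code{dcm_report}
#' @param file path (JSON)
#' @param seed,config_used optional provenance fields stored verbatim
#' @return the file path, invisibly
#' @export
write_report <- function(report, file, seed = NULL, config_used = NULL) {
  out <- list(
    mode = report$mode,
    n_models_scored = report$n_models_scored,
    selected_adjacency = unclass(report$selected),
    selected_model_index = adjacency_to_model_index(report$selected),
    coupling = report$coupling,
    free_energy = report$posterior$free_energy,
    noise_logprec = report$posterior$noise_logprec,
    embedding = report$embedding$coordinates,
    hierarchy = list(order = report$hierarchy$order,
                     labels = report$hierarchy$labels,
                     alpha = report$hierarchy$alpha),
    seed = seed, config = config_used)
  if (!is.null(report$scores))
    out$scores <- as.data.frame(report$scores)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(file)
}

#' Monte Carlo validation of network recovery
#'
#' Repeats the full pipeline on random networks: sample a network, simulate
#' a noisy dataset, invert the full model, score the entire bidirectional
#' model space, and compare the selected adjacency with the generating one.
#' Runs are independently seeded from \code{seed} so each is reproducible.
#'
#' @param config a \code{\link{mc_config}} (use \code{n_runs} to scale)
#' @param seed integer seed
#' @param control a \code{\link{invert_control}}
#' @param prior_cfg a \code{\link{prior_config}}
#' @return list of class \code{dcm_mc_result}: \code{accuracy} (fraction of
#'   runs selecting the exact generating adjacency), \code{fp}, \code{fn}
#'   (total false-positive / false-negative reciprocal edges), \code{runs}
#'   (per-run data.frame), \code{failures} (runs that errored)
#' @export
run_monte_carlo <- function(config = mc_config(), seed = 1,
                            control = invert_control(),
                            prior_cfg = prior_config()) {
  runs <- vector("list", config$n_runs)
  failures <- 0L
  for (r in seq_len(config$n_runs)) {
    run_seed <- as.integer((as.numeric(seed) * 10007 + r) %% 2147483647)
    res <- tryCatch({
      sim <- simulate_dataset(config = config, seed = run_seed)
      rep <- run_discovery(sim$ts, config = prior_cfg, control = control,
                           mode = "exhaustive")
      truth <- sim$truth$adjacency
      sel <- rep$selected
      ut <- upper.tri(unclass(truth))
      data.frame(run = r, seed = run_seed,
                 exact = identical(unclass(sel)[ut], unclass(truth)[ut]),
                 fp = sum(unclass(sel)[ut] == 1 & unclass(truth)[ut] == 0),
                 fn = sum(unclass(sel)[ut] == 0 & unclass(truth)[ut] == 1),
                 true_edges = n_connections(truth),
                 selected_edges = n_connections(sel))
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else runs[[r]] <- res
  }
  runs <- do.call(rbind, runs)
  structure(list(accuracy = mean(runs$exact), fp = sum(runs$fp),
                 fn = sum(runs$fn), runs = runs, failures = failures),
            class = "dcm_mc_result")
}

#' @export
print.dcm_mc_result <- function(x, ...) {
  cat(sprintf(paste0("Monte Carlo recovery: %.1f%% exact over %d runs",
                     " (%d FP, %d FN edges; %d failures)\n"),
              100 * x$accuracy, nrow(x$runs), x$fp, x$fn, x$failures))
  invisible(x)
}

#' Null (phase-shuffled) analysis
#'
#' Destroys dependence between nodes by phase-shuffling each series, then
#' reruns discovery. With \code{n_shuffles = 0} this is identical to
#' \code{\link{run_discovery}}. The log-evidence profile over models should
#' be much shallower than for the unshuffled data, and the selected graph
#' sparser; the log Bayes factor of the selected model against sparser
#' competitors is reported so weak selections can be recognised.
#'
#' @param ts a \code{\link{node_timeseries}}
#' @param n_shuffles number of phase-shuffled replicates (typically 1)
#' @param seed integer seed for the shuffles
#' @inheritParams run_discovery
#' @return for \code{n_shuffles = 0} a \code{dcm_report}; otherwise a list
#'   of class \code{dcm_null_result} with per-shuffle reports plus
#'   \code{selected_edges}, \code{evidence_range} (max - min relative log
#'   evidence over models) and \code{bf_vs_sparser} (log Bayes factor of
#'   the selected model against the best model with fewer connections)
#' @export
run_null <- function(ts, n_shuffles = 1, seed = 1,
                     config = prior_config(), control = invert_control(),
                     mode = c("auto", "exhaustive", "greedy"),
                     penalty_per_connection = 0) {
  mode <- match.arg(mode)
  if (n_shuffles == 0)
    return(run_discovery(ts, config = config, control = control,
                         mode = mode,
                         penalty_per_connection = penalty_per_connection))
  reports <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shuffled <- phase_shuffle(ts, seed = seed + s - 1)
    reports[[s]] <- run_discovery(shuffled, config = config,
                                  control = control, mode = mode,
                                  penalty_per_connection =
                                    penalty_per_connection)
  }
  summarise <- function(rep) {
    if (is.null(rep$scores))
      return(c(edges = n_connections(rep$selected), range = NA,
               bf = NA))
    sc <- rep$scores
    best <- attr(sc, "selected_row")
    sparser <- sc$n_connections < sc$n_connections[best]
    bf <- if (any(sparser))
      sc$log_evidence[best] - max(sc$log_evidence[sparser]) else NA
    c(edges = n_connections(rep$selected),
      range = diff(range(sc$log_evidence)), bf = bf)
  }
  stats <- t(vapply(reports, summarise, c(edges = 0, range = 0, bf = 0)))
  structure(list(reports = reports,
                 selected_edges = stats[, "edges"],
                 evidence_range = stats[, "range"],
                 bf_vs_sparser = stats[, "bf"]),
            class = "dcm_null_result")
}

#' @export
print.dcm_null_result <- function(x, ...) {
  cat(sprintf(paste0("Null analysis over %d shuffle(s): selected %s",
                     " edges;\n  log-evidence range %s; log-BF vs sparser",
                     " models %s\n"),
              length(x$reports),
              paste(x$selected_edges, collapse = ", "),
              paste(sprintf("%.1f", x$evidence_range), collapse = ", "),
              paste(sprintf("%.1f", x$bf_vs_sparser), collapse = ", ")))
  invisible(x)
}

#' Convert a log odds ratio to the equivalent Z-score
#'
#' A log Bayes factor of b corresponds to a posterior probability
#' \code{plogis(b)} for the favoured model; the equivalent standard-normal
#' deviate is \code{qnorm(plogis(b))} (a log odds of 6, i.e. about 400:1,
#' corresponds to a Z-score of about 2.8).
#'
#' @param log_odds log Bayes factor (nats)
#' @return Z-score
#' @export
log_odds_to_z <- function(log_odds) qnorm(plogis(log_odds))
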