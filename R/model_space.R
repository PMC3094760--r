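#' Adjacency matrices and model spaces
#'
#' An adjacency matrix encodes the sparsity structure of the coupling matrix:
#' entry \code{[i, j] = 1} means the connection from node \code{j} to node
#' \code{i} is permitted (same orientation as the coupling matrix itself,
#' where \code{A[i, j]} is the influence of node \code{j} on node \code{i}).
#' Self-connections are always present, so the diagonal is always 1. Under
#' the default bidirectional constraint the matrix is symmetric and the model
#' space over \code{n} nodes has \code{2^(n(n-1)/2)} members.
#'
#' @param edges square 0/1 matrix (diagonal entries are forced to 1)
#' @param bidirectional logical; enforce \code{edges[i,j] == edges[j,i]}
#' @return an object of class \code{dcm_adjacency}: the 0/1 matrix with
#'   attributes \code{n_nodes} and \code{bidirectional}.
#' @examples
#' adjacency(matrix(1, 3, 3))
#' @export
adjacency <- function(edges, bidirectional = TRUE) {
  edges <- as.matrix(edges)
  dimnames(edges) <- NULL
  if (nrow(edges) != ncol(edges))
    stop("adjacency matrix must be square")
  if (!all(edges %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  storage.mode(edges) <- "double"
  diag(edges) <- 1
  if (bidirectional && !isTRUE(all.equal(edges, t(edges))))
    stop("adjacency is not symmetric; use bidirectional = FALSE for ",
         "non-reciprocal model spaces")
  structure(edges, class = "dcm_adjacency",
            n_nodes = nrow(edges), bidirectional = bidirectional)
}

#' @export
print.dcm_adjacency <- function(x, ...) {
  n <- attr(x, "n_nodes")
  cat(sprintf("Adjacency on %d nodes (%s), %d reciprocal pair(s) present\n",
              n, if (attr(x, "bidirectional")) "bidirectional" else "directed",
              n_connections(x)))
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  print(m)
  invisible(x)
}

#' Number of reciprocal connections in an adjacency
#'
#' Counts off-diagonal pairs \code{\{i, j\}} with at least one directed edge
#' present (for bidirectional adjacencies this is the number of bidirectional
#' connections).
#'
#' @param adj a \code{dcm_adjacency}
#' @return integer count
#' @export
n_connections <- function(adj) {
  m <- unclass(adj)
  sum((m + t(m))[upper.tri(m)] > 0)
}

#' Size of the bidirectional model space
#'
#' With all connections constrained to be reciprocal, each of the
#' \code{n(n-1)/2} node pairs is independently present or absent, giving
#' \code{2^(n(n-1)/2)} candidate graphs (64 for four nodes, 32768 for six,
#' 268435456 for eight). With \code{bidirectional = FALSE} each directed
#' off-diagonal edge toggles independently: \code{2^(n(n-1))} graphs.
#'
#' @param n_nodes number of nodes (>= 1)
#' @param bidirectional logical
#' @return the number of models (double; exact up to 2^53)
#' @export
count_models <- function(n_nodes, bidirectional = TRUE) {
  if (length(n_nodes) != 1 || !is.finite(n_nodes) || n_nodes < 1 ||
      n_nodes != round(n_nodes))
    stop("n_nodes must be a positive integer")
  k <- n_nodes * (n_nodes - 1) / 2
  if (!bidirectional) k <- 2 * k
  2^k
}

# ordered reciprocal pairs (i < j), lexicographic in (i, j)
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  unname(idx)
}

#' Enumerate the bidirectional model space
#'
#' Generates every bidirectional adjacency exactly once, in a canonical order:
#' binary counting over the reciprocal pairs sorted lexicographically by
#' \code{(i, j), i < j}, with bit value 1 meaning the pair is present and the
#' first pair as the least significant bit. Model 1 is the edgeless graph and
#' model \code{count_models(n)} is the full graph.
#'
#' @param n_nodes number of nodes
#' @param limit enumeration capacity; spaces larger than this raise an error
#'   (use \code{\link{greedy_prune}} instead for large graphs)
#' @return list of \code{dcm_adjacency}
#' @export
enumerate_models <- function(n_nodes, limit = 2^20) {
  n_models <- count_models(n_nodes)
  if (n_models > limit)
    stop(sprintf(paste0("model space has %.0f members, above the enumeration",
                        " limit %.0f; use the greedy search (greedy_prune)"),
                 n_models, limit))
  lapply(seq_len(n_models), function(i) model_index_to_adjacency(i, n_nodes))
}

#' Convert a canonical model index to its adjacency
#'
#' @param index model index in \code{1..count_models(n_nodes)}
#' @param n_nodes number of nodes
#' @return a \code{dcm_adjacency}
#' @export
model_index_to_adjacency <- function(index, n_nodes) {
  if (index < 1 || index > count_models(n_nodes))
    stop("model index out of range")
  pairs <- pair_index(n_nodes)
  bits <- as.integer(intToBits(index - 1))[seq_len(max(1, nrow(pairs)))]
  m <- diag(n_nodes)
  if (nrow(pairs) > 0)
    for (k in seq_len(nrow(pairs)))
      if (bits[k] == 1L)
        m[pairs[k, 1], pairs[k, 2]] <- m[pairs[k, 2], pairs[k, 1]] <- 1
  adjacency(m)
}

#' Convert an adjacency to its canonical model index
#'
#' Inverse of \code{\link{model_index_to_adjacency}}.
#'
#' @param adj a bidirectional \code{dcm_adjacency}
#' @return model index (1-based)
#' @export
adjacency_to_model_index <- function(adj) {
  n <- attr(adj, "n_nodes")
  pairs <- pair_index(n)
  if (nrow(pairs) == 0) return(1)
  bits <- vapply(seq_len(nrow(pairs)),
                 function(k) unclass(adj)[pairs[k, 1], pairs[k, 2]], 0)
  sum(bits * 2^(seq_along(bits) - 1)) + 1
}

#' Default prior configuration
#'
#' Shrinkage priors mirroring the standard DCM-for-fMRI set-up: present
#' off-diagonal couplings get a zero-mean prior with variance 2 (precision one
#' half); absent couplings get a delta prior at zero (variance 0);
#' self-connections are pinned near -0.5 Hz with prior precision 128. Input
#' (basis-coefficient) weights and the log-scalings of the hemodynamic decay
#' and transit parameters get weakly informative zero-mean priors; the
#' observation-noise log-precision prior has mean 6 for simulated data and 4
#' for empirical data (where the noise level is unknown), variance 1 in both
#' profiles.
#'
#' @param profile \code{"simulated"} or \code{"empirical"} (sets the
#'   observation-noise log-precision prior mean to 6 or 4)
#' @param coupling_variance prior variance of a present coupling (Hz^2)
#' @param self_mean,self_variance prior moments of self-connections
#' @param c_variance prior variance of each input weight
#' @param hemo_variance prior variance of each hemodynamic log-scaling
#' @param noise_logprec_variance prior variance of the noise log-precision
#' @return a list of class \code{dcm_prior_config}
#' @export
prior_config <- function(profile = c("simulated", "empirical"),
                         coupling_variance = 2,
                         self_mean = -0.5, self_variance = 1 / 128,
                         c_variance = 1.6e-5, hemo_variance = 0.0625,
                         noise_logprec_variance = 1) {
  profile <- match.arg(profile)
  structure(list(profile = profile,
                 coupling_variance = coupling_variance,
                 self_mean = self_mean, self_variance = self_variance,
                 c_variance = c_variance, hemo_variance = hemo_variance,
                 noise_logprec_mean = if (profile == "simulated") 6 else 4,
                 noise_logprec_variance = noise_logprec_variance),
            class = "dcm_prior_config")
}

#' Translate an adjacency into shrinkage priors on the stacked parameters
#'
#' Builds the prior over the stacked parameter vector
#' \code{[vec(A), vec(C), hemodynamic log-scalings]}: off-diagonal couplings
#' get mean 0 and variance \code{coupling_variance} where the adjacency
#' permits the edge and variance 0 (a delta prior pinning the parameter at
#' zero) where it does not; self-connections get \code{(self_mean,
#' self_variance)}; input weights and hemodynamic log-scalings come from the
#' configuration. Zero-variance parameters are excluded from the free set at
#' inversion time rather than inverted through a singular covariance.
#'
#' @param adj a \code{dcm_adjacency}
#' @param n_inputs number of input (basis) columns J; C has \code{n x J}
#'   weights
#' @param config a \code{\link{prior_config}}
#' @return a list of class \code{dcm_priors} with elements \code{mean},
#'   \code{variance}, \code{index_map} (data.frame: name, block, row, col),
#'   \code{n_nodes}, \code{n_inputs}, \code{config}
#' @export
priors_from_adjacency <- function(adj, n_inputs = 0,
                                  config = prior_config(),
                                  c_shape = NULL) {
  n <- attr(adj, "n_nodes")
  m <- unclass(adj)
  # A block, column-major to match the packed parameter vector
  a_mean <- matrix(0, n, n); diag(a_mean) <- config$self_mean
  a_var <- config$coupling_variance * m
  diag(a_var) <- config$self_variance
  a_idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  map <- data.frame(
    name = sprintf("A[%d,%d]", a_idx$row, a_idx$col),
    block = "A", row = a_idx$row, col = a_idx$col,
    stringsAsFactors = FALSE)
  mean <- as.vector(a_mean); variance <- as.vector(a_var)
  if (n_inputs > 0) {
    c_idx <- expand.grid(row = seq_len(n), col = seq_len(n_inputs))
    map <- rbind(map, data.frame(
      name = sprintf("C[%d,%d]", c_idx$row, c_idx$col),
      block = "C", row = c_idx$row, col = c_idx$col,
      stringsAsFactors = FALSE))
    if (is.null(c_shape)) c_shape <- rep(1, n_inputs)
    if (length(c_shape) != n_inputs)
      stop("c_shape must have one weight per input component")
    mean <- c(mean, rep(0, n * n_inputs))
    variance <- c(variance,
                  rep(config$c_variance * c_shape, each = n))
  }
  map <- rbind(map,
               data.frame(name = sprintf("hemo_kappa[%d]", seq_len(n)),
                          block = "hemo", row = seq_len(n), col = 1,
                          stringsAsFactors = FALSE),
               data.frame(name = sprintf("hemo_tau[%d]", seq_len(n)),
                          block = "hemo", row = seq_len(n), col = 2,
                          stringsAsFactors = FALSE))
  mean <- c(mean, rep(0, 2 * n))
  variance <- c(variance, rep(config$hemo_variance, 2 * n))
  structure(list(mean = mean, variance = variance, index_map = map,
                 n_nodes = n, n_inputs = n_inputs, config = config,
                 c_shape = if (n_inputs > 0) c_shape),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat(sprintf("DCM priors: %d parameters (%d free) over %d nodes, %d inputs\n",
              length(x$mean), sum(x$variance > 0), x$n_nodes, x$n_inputs))
  invisible(x)
}

#' Read / write adjacency matrices as plain text
#'
#' \code{write_adjacency} writes a whitespace-delimited 0/1 matrix;
#' \code{read_adjacency} reads one back. \code{write_edge_list} writes one
#' "source target" pair per line (0-based indices, directed edges, diagonal
#' omitted).
#'
#' @param adj a \code{dcm_adjacency}
#' @param file path
#' @name adjacency_io
#' @export
write_adjacency <- function(adj, file) {
  write.table(unclass(adj), file, row.names = FALSE, col.names = FALSE)
}

#' @param bidirectional passed to \code{\link{adjacency}}
#' @rdname adjacency_io
#' @export
read_adjacency <- function(file, bidirectional = TRUE) {
  adjacency(as.matrix(read.table(file)), bidirectional = bidirectional)
}

#' @rdname adjacency_io
#' @export
write_edge_list <- function(adj, file) {
  m <- unclass(adj)
  idx <- which(m == 1 & row(m) != col(m), arr.ind = TRUE)
  # edge from source j to target i under the A[i,j] orientation
  df <- data.frame(source = idx[, 2] - 1L, target = idx[, 1] - 1L)
  df <- df[order(df$source, df$target), ]
  write.table(df, file, row.names = FALSE, col.names = FALSE)
}
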