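#' Weighted adjacency from posterior coupling means
#'
#' Symmetric weights from the directed coupling estimates:
#' \code{W[i, j] = W[j, i] = max(|A[i, j]|, |A[j, i]|)}, diagonal zero.
#'
#' @param A square matrix of (posterior mean) couplings
#' @return symmetric n x n weight matrix
#' @export
weighted_adjacency <- function(A) {
  A <- unname(as.matrix(A))
  if (nrow(A) != ncol(A)) stop("A must be square")
  W <- pmax(abs(A), abs(t(A)))
  diag(W) <- 0
  W
}

#' Weighted graph Laplacian
#'
#' \code{L[i, j] = W[i, j]} off the diagonal and
#' \code{L[j, j] = W[j, j] - sum_k W[k, j]} on it (column sums), so the
#' constant vector is always in the null space. Note this convention is
#' negative semi-definite: eigenvalues are <= 0 with 0 attained by the
#' constant eigenvector.
#'
#' @param W symmetric weight matrix with zero diagonal
#' @return the Laplacian matrix
#' @export
graph_laplacian <- function(W) {
  W <- as.matrix(W)
  if (!isTRUE(all.equal(unname(W), unname(t(W)))))
    stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have zero diagonal")
  L <- W
  diag(L) <- diag(W) - colSums(W)
  L
}

#' Spectral embedding of a weighted graph
#'
#' Places nodes in a low-dimensional functional space using eigenvectors of
#' the graph Laplacian, so that strongly coupled nodes lie close together.
#' The trivial constant eigenvector (eigenvalue 0) is dropped; the
#' coordinates are the k remaining eigenvectors with eigenvalues closest to
#' zero, each scaled to unit norm, with the sign convention that the
#' largest-magnitude entry is positive.
#'
#' @param L a \code{\link{graph_laplacian}}
#' @param k embedding dimension (default 3, at most n - 1)
#' @param drop_trivial drop the constant eigenvector (default TRUE)
#' @return list of class \code{dcm_embedding}: \code{coordinates} (k x n),
#'   \code{eigenvalues} (full spectrum, decreasing, i.e. closest to zero
#'   first), \code{eigenvector_indices} (which eigenvectors were used)
#' @export
spectral_embedding <- function(L, k = 3, drop_trivial = TRUE) {
  n <- nrow(L)
  if (k > n - 1) stop("k must be at most n - 1")
  Ls <- (L + t(L)) / 2
  full <- eigen(Ls, symmetric = TRUE, only.values = TRUE)$values
  if (drop_trivial) {
    # orthonormal basis of the complement of the constant vector, so the
    # trivial eigenvector is removed exactly even when the zero eigenvalue
    # is degenerate (disconnected graphs)
    Q <- qr.Q(qr(cbind(rep(1, n), diag(n)[, seq_len(n - 1)])))[, -1,
                                                               drop = FALSE]
    e <- eigen(crossprod(Q, Ls %*% Q), symmetric = TRUE)
    ord <- order(abs(e$values))[seq_len(k)]
    vecs <- Q %*% e$vectors[, ord, drop = FALSE]
    used <- ord + 1L
  } else {
    e <- eigen(Ls, symmetric = TRUE)
    ord <- order(abs(e$values))[seq_len(k)]
    vecs <- e$vectors[, ord, drop = FALSE]
    used <- ord
  }
  coords <- t(vecs)
  for (r in seq_len(nrow(coords))) {
    coords[r, ] <- coords[r, ] / sqrt(sum(coords[r, ]^2))
    if (coords[r, which.max(abs(coords[r, ]))] < 0)
      coords[r, ] <- -coords[r, ]
  }
  structure(list(coordinates = coords, eigenvalues = full,
                 eigenvector_indices = used),
            class = "dcm_embedding")
}

#' @export
print.dcm_embedding <- function(x, ...) {
  cat(sprintf("Spectral embedding: %d coordinates over %d nodes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  print(round(x$coordinates, 3))
  invisible(x)
}

# all permutations of 1..n, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in seq_len(nrow(sub))) {
      out[r, ] <- c(first, rest[sub[s, ]])
      r <- r + 1
    }
  }
  out
}

# asymmetry score of an ordering: sum of forward-minus-backward coupling
# over ranked pairs; order[p] is the node at rank p (bottom to top)
alpha_score <- function(A, ord) {
  At <- A - t(A)
  s <- 0
  n <- length(ord)
  for (q in seq_len(n)) for (p in seq_len(q - 1))
    s <- s + At[ord[q], ord[p]]
  s
}

#' Hierarchy ordering from connection asymmetries
#'
#' Finds the ordering of the nodes (bottom to top) that maximises the total
#' asymmetry of forward over backward coupling: with \code{Atilde = A - t(A)}
#' (antisymmetric), the score of an ordering is the sum of
#' \code{Atilde[target, source]} over all ranked pairs with the source below
#' the target. The search is exhaustive over permutations (n <= 10); ties
#' are broken towards the lexicographically smallest ordering.
#'
#' @param A square matrix of directed (posterior mean) couplings;
#'   \code{A[i, j]} is the influence of node j on node i
#' @param labels optional node names
#' @return list of class \code{dcm_hierarchy}: \code{order} (node indices,
#'   bottom to top), \code{labels} in that order, \code{alpha} (the
#'   maximised score), \code{asymmetry} (the antisymmetric matrix)
#' @export
hierarchy_order <- function(A, labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n > 10) stop("exhaustive hierarchy search supports at most 10 nodes")
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  perms <- all_permutations(n)
  scores <- apply(perms, 1, function(p) alpha_score(A, p))
  best <- which(scores >= max(scores) - 1e-12)
  # perms are generated in lexicographic order; first hit is smallest
  pick <- best[1]
  structure(list(order = perms[pick, ], labels = labels[perms[pick, ]],
                 alpha = scores[pick], asymmetry = A - t(A)),
            class = "dcm_hierarchy")
}

#' @export
print.dcm_hierarchy <- function(x, ...) {
  cat(sprintf("Hierarchy (bottom to top): %s\n  alpha = %.4f\n",
              paste(x$labels, collapse = " < "), x$alpha))
  invisible(x)
}
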