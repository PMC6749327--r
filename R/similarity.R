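#' miRNA functional similarity from associated disease sets
#'
#' Computes the best-match-average functional similarity between miRNAs
#' from the disease sets they associate with: for miRNAs `a` and `b` with
#' disease sets `Sa`, `Sb`,
#' \deqn{Sim(a,b) = \frac{\sum_{d \in Sa} \max_{d' \in Sb} D(d,d') +
#'   \sum_{d \in Sb} \max_{d' \in Sa} D(d,d')}{|Sa| + |Sb|}.}
#' Self-similarity is 1 for any miRNA with a nonempty disease set.
#' If either set is empty the similarity is defined as 0 (such miRNAs carry
#' no functional information yet).
#'
#' During cross-validation this must be computed from the training fold of
#' the association matrix only, otherwise held-out links leak into the
#' similarity network; see [run_cross_validation()].
#'
#' @param A association matrix (training associations).
#' @param D disease similarity matrix covering all diseases of `A`.
#' @return a miRNA [similarity_matrix()].
#' @export
mirna_functional_similarity <- function(A, D) {
  check_data_dims(A, D = D)
  A <- unclass(A); Dm <- unclass(D)
  Nm <- nrow(A)
  sizes <- rowSums(A)
  # G[d, b] = best match of disease d against the disease set of miRNA b
  G <- matrix(0, ncol(A), Nm)
  for (b in seq_len(Nm)) {
    Sb <- which(A[b, ] == 1)
    if (length(Sb))
      G[, b] <- apply(Dm[, Sb, drop = FALSE], 1L, max)
  }
  AG <- A %*% G                       # AG[a, b] = sum over Sa of best matches in Sb
  denom <- outer(sizes, sizes, "+")
  S <- (AG + t(AG)) / ifelse(denom == 0, 1, denom)
  S[sizes == 0, ] <- 0
  S[, sizes == 0] <- 0
  diag(S)[sizes > 0] <- 1
  similarity_matrix(S, ids = rownames(A), kind = "mirna")
}

#' Build the k-nearest-neighbour miRNA graph
#'
#' For each miRNA `j`, the `k` miRNAs `i != j` with the largest similarity
#' `M[i, j]` get `S[i, j] = 1` ("`i` is one of the similar neighbours of
#' `j`"). Only strictly positive similarities qualify, so a column may end
#' up with fewer than `k` neighbours. Ties are broken by ascending index for
#' determinism. With `symmetrize = TRUE` (the default) the directed graph is
#' replaced by `max(S, t(S))`, which makes the Laplacian quadratic form the
#' standard smoothness penalty; the raw directed variant is retained behind
#' the flag.
#'
#' @param M miRNA similarity matrix.
#' @param k neighbour count, `0 < k < Nm`.
#' @param symmetrize logical.
#' @return list with class `"neighbor_graph"`: `S` (binary `Nm x Nm`,
#'   zero diagonal), `k`, `symmetrized`.
#' @export
build_neighbor_graph <- function(M, k, symmetrize = TRUE) {
  Mm <- unclass(as.matrix(M))
  Nm <- nrow(Mm)
  if (Nm != ncol(Mm)) stop("build_neighbor_graph: M must be square")
  k <- as.integer(k)
  if (k <= 0) stop("build_neighbor_graph: k must be positive")
  if (k >= Nm) stop(sprintf("build_neighbor_graph: k = %d must be < Nm = %d",
                            k, Nm))
  S <- matrix(0, Nm, Nm, dimnames = dimnames(Mm))
  for (j in seq_len(Nm)) {
    sim <- Mm[, j]
    sim[j] <- -Inf
    cand <- which(sim > 0)
    if (!length(cand)) next
    # order(-sim, index) gives largest-first with ascending-index tie-break
    top <- cand[order(-sim[cand], cand)][seq_len(min(k, length(cand)))]
    S[top, j] <- 1
  }
  if (symmetrize) S <- pmax(S, t(S))
  structure(list(S = S, k = k, symmetrized = isTRUE(symmetrize)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("miRNA neighbour graph: %d nodes, %d edges, k = %d%s\n",
              nrow(x$S), sum(x$S), x$k,
              if (x$symmetrized) ", symmetrized" else " (directed)"))
  invisible(x)
}

#' Graph Laplacian of a neighbour graph
#'
#' `L = W - S` with `W` the diagonal degree matrix, `W[i, i] = sum_j S[i, j]`.
#' For a symmetric graph every row of `L` sums to zero and `Tr(U'LU) >= 0`
#' for any `U`.
#'
#' @param G a `"neighbor_graph"` (or a bare binary adjacency matrix).
#' @return list with class `"laplacian_pair"`: `W` (diagonal matrix), `L`.
#' @export
graph_laplacian <- function(G) {
  S <- if (inherits(G, "neighbor_graph")) G$S else as.matrix(G)
  W <- diag(rowSums(S), nrow = nrow(S))
  dimnames(W) <- dimnames(S)
  structure(list(W = W, L = W - S), class = "laplacian_pair")
}
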