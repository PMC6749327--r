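#' Objective function of the association-prediction model
#'
#' The model estimates a nonnegative score matrix `U` (`Nm x Nd`) by
#' minimizing
#' \deqn{\|U-A\|_F^2 + \alpha_1\|U-MX(DY)^T\|_F^2 +
#'       \alpha_2\|U-CZ(DY)^T\|_F^2 + \alpha_3\,\mathrm{Tr}(U^TLU) +
#'       \alpha_4\|U\|_1}
#' over `U, X, Y, Z >= 0`: fidelity to the observed associations, agreement
#' with the similarity and node-attribute projections into the shared
#' c-dimensional space, smoothness over the miRNA neighbour graph, and an
#' l1 sparsity penalty. When the attribute matrix has zero columns (no
#' family/cluster information at all) the attribute term is dropped, i.e.
#' an empty `C` contributes nothing rather than pulling `U` toward zero.
#'
#' @param state list with elements `U`, `X`, `Y`, `Z` and Laplacian `L`
#'   (e.g. a [mda_fit()] result, or a hand-built list for testing).
#' @param data list with elements `A`, `M`, `D`, `C`.
#' @param h an [mda_hyperparams()] object.
#' @return list with class `"objective_breakdown"`: `fit_term`,
#'   `similarity_term`, `attribute_term`, `graph_term`, `sparsity_term`,
#'   `total`.
#' @export
mda_objective <- function(state, data, h) {
  check_state_dims(state, data, h)
  U <- unclass(state$U)
  DYt <- t(unclass(data$D) %*% state$Y)
  fit <- sum((U - unclass(data$A))^2)
  sim <- sum((U - unclass(data$M) %*% state$X %*% DYt)^2)
  has_attr <- ncol(data$C) > 0
  att <- if (has_attr) sum((U - unclass(data$C) %*% state$Z %*% DYt)^2) else 0
  gra <- sum(U * (state$L %*% U))
  spa <- sum(abs(U))
  total <- fit + h$alpha1 * sim + (if (has_attr) h$alpha2 * att else 0) +
    h$alpha3 * gra + h$alpha4 * spa
  structure(list(fit_term = fit, similarity_term = sim,
                 attribute_term = att, graph_term = gra,
                 sparsity_term = spa, total = total),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf(
    "objective %.6g = fit %.4g + sim %.4g + attr %.4g + graph %.4g + l1 %.4g (unweighted components)\n",
    x$total, x$fit_term, x$similarity_term, x$attribute_term,
    x$graph_term, x$sparsity_term))
  invisible(x)
}

#' Multiplicative update of the score matrix U
#'
#' Elementwise rule
#' \deqn{U \leftarrow U \odot
#'   \frac{2A + 2\alpha_1 MX(DY)^T + 2\alpha_2 CZ(DY)^T + 2\alpha_3 SU}
#'        {2U + 2\alpha_1 U + 2\alpha_2 U + 2\alpha_3 WU + \alpha_4 B},}
#' with `B` the all-ones matrix. The rule rescales every entry by the ratio
#' of the negative to the positive part of the gradient of the U
#' subproblem, so nonnegativity is preserved exactly. A small floor
#' (`h$delta`) is added to the denominator; the rule is undefined at zero.
#'
#' @param state list with `U`, `X`, `Y`, `Z`, `S`, `W`.
#' @param data list with `A`, `M`, `D`, `C`.
#' @param h hyperparameters.
#' @return updated `U` matrix.
#' @export
update_U <- function(state, data, h) {
  U <- unclass(state$U)
  DYt <- t(unclass(data$D) %*% state$Y)
  a2 <- if (ncol(data$C) > 0) h$alpha2 else 0
  num <- 2 * unclass(data$A) +
    2 * h$alpha1 * (unclass(data$M) %*% state$X %*% DYt) +
    2 * h$alpha3 * (state$S %*% U)
  if (a2 > 0) num <- num + 2 * a2 * (unclass(data$C) %*% state$Z %*% DYt)
  den <- 2 * U + 2 * h$alpha1 * U + 2 * a2 * U +
    2 * h$alpha3 * (state$W %*% U) + h$alpha4 + h$delta
  U * num / den
}

#' Multiplicative update of the miRNA similarity projection X
#'
#' Elementwise rule
#' \deqn{X \leftarrow X \odot \frac{M^TUDY}{M^TMX(DY)^TDY}}
#' (the weight \eqn{\alpha_1} cancels between numerator and denominator).
#'
#' @inheritParams update_U
#' @return updated `X` matrix.
#' @export
update_X <- function(state, data, h) {
  M <- unclass(data$M)
  DY <- unclass(data$D) %*% state$Y
  num <- crossprod(M, unclass(state$U) %*% DY)
  den <- crossprod(M, M %*% state$X %*% crossprod(DY)) + h$delta
  state$X * num / den
}

#' Multiplicative update of the disease projection Y
#'
#' Elementwise rule
#' \deqn{Y \leftarrow Y \odot
#'   \frac{\alpha_1 D^TU^TMX + \alpha_2 D^TU^TCZ}
#'        {\alpha_1 D^TDY(MX)^TMX + \alpha_2 D^TDY(CZ)^TCZ}.}
#'
#' @inheritParams update_U
#' @return updated `Y` matrix.
#' @export
update_Y <- function(state, data, h) {
  D <- unclass(data$D)
  MX <- unclass(data$M) %*% state$X
  DtUt <- crossprod(D, t(unclass(state$U)))
  DtDY <- crossprod(D, D %*% state$Y)
  a2 <- if (ncol(data$C) > 0) h$alpha2 else 0
  num <- h$alpha1 * (DtUt %*% MX)
  den <- h$alpha1 * (DtDY %*% crossprod(MX))
  if (a2 > 0) {
    CZ <- unclass(data$C) %*% state$Z
    num <- num + a2 * (DtUt %*% CZ)
    den <- den + a2 * (DtDY %*% crossprod(CZ))
  }
  state$Y * num / (den + h$delta)
}

#' Multiplicative update of the node-attribute projection Z
#'
#' Elementwise rule
#' \deqn{Z \leftarrow Z \odot \frac{C^TUDY}{C^TCZ(DY)^TDY}.}
#' With an empty attribute matrix (`Nf + Nc = 0`) `Z` has zero rows and is
#' returned unchanged.
#'
#' @inheritParams update_U
#' @return updated `Z` matrix.
#' @export
update_Z <- function(state, data, h) {
  C <- unclass(data$C)
  if (ncol(C) == 0) return(state$Z)
  DY <- unclass(data$D) %*% state$Y
  num <- crossprod(C, unclass(state$U) %*% DY)
  den <- crossprod(C, C %*% state$Z %*% crossprod(DY)) + h$delta
  state$Z * num / den
}

#' Fit the association-prediction model
#'
#' Builds the miRNA kNN graph and its Laplacian once, initializes the four
#' nonnegative factors (seeded), then cycles the multiplicative updates
#' `U -> X -> Y -> Z`, recording the objective after every full cycle.
#' Iteration stops when the objective difference between two adjacent
#' cycles drops below `h$epsilon` (absolute by default, relative on
#' request) or after `h$max_iter` cycles.
#'
#' Initialization (the published description leaves it open):
#' `"warm_start_from_A"` (default) sets `U0 = A + 0.1 * mean(A) * Unif(0,1)`
#' -- strictly positive, so the multiplicative rules can move every entry --
#' and `X0, Y0, Z0 ~ 0.01 * Unif(0,1)`; `"uniform_random"` draws `U0` from
#' `Unif(0,1)` instead.
#'
#' @param A association matrix (`Nm x Nd`, binary).
#' @param M miRNA similarity matrix (`Nm x Nm`).
#' @param D disease similarity matrix (`Nd x Nd`).
#' @param C node-attribute matrix (`Nm x (Nf+Nc)`); `NULL` means no
#'   attribute information (equivalent to a zero-column matrix).
#' @param h an [mda_hyperparams()] object.
#' @param graph optional precomputed `"neighbor_graph"`; by default built
#'   from `M` with `h$k_neighbors` and `h$symmetrize_graph`.
#' @return list with class `"mdapred_fit"`: factors `U`, `X`, `Y`, `Z`,
#'   graph matrices `S`, `W`, `L`, `objective_trace` (one row per recorded
#'   cycle, columns for the five components and the weighted total),
#'   `iterations`, `converged`, and the hyperparameters used.
#' @examples
#' syn <- generate_synthetic(synth_config(n_mirna = 30, n_disease = 12,
#'                                        n_family = 4, n_cluster = 5,
#'                                        rank = 3, seed = 7))
#' fit <- mda_fit(syn$A, syn$M, syn$D, syn$C,
#'                h = mda_hyperparams(c = 4, k_neighbors = 3, max_iter = 25))
#' fit
#' @export
mda_fit <- function(A, M, D, C = NULL, h = mda_hyperparams(), graph = NULL) {
  if (is.null(C))
    C <- attribute_matrix(matrix(0, nrow(A), 0), character(0), character(0),
                          mirna_ids = rownames(A) %||% paste0("m", seq_len(nrow(A))))
  check_data_dims(A, M, D, C)
  Nm <- nrow(A); Nd <- ncol(A)
  if (h$c >= min(Nm, Nd))
    stop(sprintf("latent dimension c = %d must be < min(Nm, Nd) = %d",
                 h$c, min(Nm, Nd)))
  if (ncol(C) > 0 && h$c >= ncol(C))
    stop(sprintf("latent dimension c = %d must be < Nf + Nc = %d",
                 h$c, ncol(C)))
  if (is.null(graph)) graph <- build_neighbor_graph(M, h$k_neighbors,
                                                    h$symmetrize_graph)
  lap <- graph_laplacian(graph)

  Am <- unclass(A)
  state <- local_seed(h$seed, {
    u_scale <- 0.1 * mean(Am)
    if (u_scale == 0) u_scale <- 0.01   # all-zero A: keep U movable
    U0 <- switch(h$init_scheme,
      warm_start_from_A = Am + u_scale * matrix(stats::runif(Nm * Nd), Nm, Nd),
      uniform_random = matrix(stats::runif(Nm * Nd), Nm, Nd))
    list(U = U0,
         X = 0.01 * matrix(stats::runif(Nm * h$c), Nm, h$c),
         Y = 0.01 * matrix(stats::runif(Nd * h$c), Nd, h$c),
         Z = 0.01 * matrix(stats::runif(ncol(C) * h$c), ncol(C), h$c),
         S = lap$W - lap$L, W = lap$W, L = lap$L)
  })
  data <- list(A = A, M = M, D = D, C = C)

  trace <- vector("list", h$max_iter + 1L)
  obj <- mda_objective(state, data, h)
  trace[[1L]] <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < h$max_iter) {
    iter <- iter + 1L
    state$U <- check_finite(update_U(state, data, h), iter, "U")
    state$X <- check_finite(update_X(state, data, h), iter, "X")
    state$Y <- check_finite(update_Y(state, data, h), iter, "Y")
    state$Z <- check_finite(update_Z(state, data, h), iter, "Z")
    prev <- obj
    obj <- mda_objective(state, data, h)
    trace[[iter + 1L]] <- obj
    diff <- abs(obj$total - prev$total)
    if (h$convergence == "relative") diff <- diff / max(abs(prev$total), h$delta)
    if (diff < h$epsilon) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(iter + 1L)]
  trace_df <- data.frame(
    cycle = seq_along(trace) - 1L,
    fit = vapply(trace, `[[`, 0, "fit_term"),
    similarity = vapply(trace, `[[`, 0, "similarity_term"),
    attribute = vapply(trace, `[[`, 0, "attribute_term"),
    graph = vapply(trace, `[[`, 0, "graph_term"),
    sparsity = vapply(trace, `[[`, 0, "sparsity_term"),
    total = vapply(trace, `[[`, 0, "total"))

  dimnames(state$U) <- dimnames(A)
  structure(c(state,
              list(objective_trace = trace_df, iterations = iter,
                   converged = converged, h = h)),
            class = "mdapred_fit")
}

#' @export
print.mdapred_fit <- function(x, ...) {
  cat(sprintf("association model fit: %d miRNAs x %d diseases, c = %d\n",
              nrow(x$U), ncol(x$U), x$h$c))
  cat(sprintf("  %d cycles, %s (final objective %.6g)\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace$total[nrow(x$objective_trace)]))
  invisible(x)
}

#' Predicted association scores
#'
#' @param state a fitted model ([mda_fit()]).
#' @return the nonnegative score matrix `U`; `U[i, j]` is the estimated
#'   association score of miRNA `i` with disease `j` (larger = more likely
#'   associated).
#' @export
predict_scores <- function(state) {
  state$U
}

#' Ranked candidate miRNAs for one disease
#'
#' Ranks all miRNAs for a disease by their predicted score, excluding the
#' pairs already known (positives of the training association matrix) --
#' those are not candidates.
#'
#' @param state fitted model.
#' @param disease disease identifier or column index.
#' @param exclude training association matrix whose positives are removed
#'   from the candidate list; `NULL` ranks every miRNA.
#' @return data frame with columns `mirna`, `score`, ordered by decreasing
#'   score (ties broken by ascending row index).
#' @export
rank_candidates <- function(state, disease, exclude = NULL) {
  U <- predict_scores(state)
  j <- if (is.character(disease)) match(disease, colnames(U)) else disease
  if (is.na(j) || j < 1 || j > ncol(U))
    stop(sprintf("unknown disease: %s", disease))
  scores <- U[, j]
  keep <- if (is.null(exclude)) rep(TRUE, nrow(U)) else unclass(exclude)[, j] == 0
  idx <- which(keep)
  ord <- idx[order(-scores[idx], idx)]
  data.frame(mirna = rownames(U)[ord] %||% as.character(ord),
             score = scores[ord], row.names = NULL)
}

#' Grid of term-weight combinations
#'
#' Convenience helper enumerating hyperparameter settings over the standard
#' candidate set \{0.01, 0.1, 1, 10\} for each term weight.
#'
#' @param values candidate values for each of `alpha1..alpha4`.
#' @param ... fixed arguments passed to [mda_hyperparams()].
#' @return list of `mda_hyperparams` objects, one per combination.
#' @export
alpha_grid <- function(values = c(0.01, 0.1, 1, 10), ...) {
  g <- expand.grid(alpha1 = values, alpha2 = values,
                   alpha3 = values, alpha4 = values)
  lapply(seq_len(nrow(g)), function(i)
    mda_hyperparams(alpha1 = g$alpha1[i], alpha2 = g$alpha2[i],
                    alpha3 = g$alpha3[i], alpha4 = g$alpha4[i], ...))
}

check_state_dims <- function(state, data, h) {
  Nm <- nrow(data$A); Nd <- ncol(data$A)
  check_data_dims(data$A, data$M, data$D, data$C)
  dims <- list(U = c(Nm, Nd), X = c(Nm, h$c), Y = c(Nd, h$c),
               Z = c(ncol(data$C), h$c), L = c(Nm, Nm))
  for (nm in names(dims)) {
    m <- state[[nm]]
    if (is.null(m)) stop(sprintf("model state is missing %s", nm))
    if (!all(dim(m) == dims[[nm]]))
      stop(sprintf("%s is %d x %d but should be %d x %d",
                   nm, nrow(m), ncol(m), dims[[nm]][1], dims[[nm]][2]))
  }
  invisible(TRUE)
}

check_finite <- function(x, iter, block) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s at cycle %d; try a larger delta or smaller alphas",
                 block, iter))
  x
}

# evaluate expr with a locally seeded RNG, restoring the caller's stream
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
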