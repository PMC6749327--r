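# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, brute-force enumeration) so that they
# share no code path with the package implementation.

# triple-loop matrix product
mm_loop <- function(A, B) {
  stopifnot(ncol(A) == nrow(B))
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

frob2_loop <- function(X) {
  s <- 0
  for (v in as.vector(X)) s <- s + v * v
  s
}

# brute-force objective components from raw matrices
objective_loop <- function(U, X, Y, Z, A, M, D, C, L, h) {
  DYt <- t(mm_loop(D, Y))
  fit <- frob2_loop(U - A)
  sim <- frob2_loop(U - mm_loop(mm_loop(M, X), DYt))
  att <- if (ncol(C) > 0) frob2_loop(U - mm_loop(mm_loop(C, Z), DYt)) else 0
  gra <- sum(diag(mm_loop(t(U), mm_loop(L, U))))
  spa <- sum(abs(U))
  list(fit = fit, sim = sim, att = att, gra = gra, spa = spa,
       total = fit + h$alpha1 * sim +
         (if (ncol(C) > 0) h$alpha2 * att else 0) +
         h$alpha3 * gra + h$alpha4 * spa)
}

# elementwise substitution of the published update rules
update_U_loop <- function(U, X, Y, Z, A, M, D, C, S, W, h) {
  DYt <- t(mm_loop(D, Y))
  P1 <- mm_loop(mm_loop(M, X), DYt)
  P2 <- if (ncol(C) > 0) mm_loop(mm_loop(C, Z), DYt) else matrix(0, nrow(U), ncol(U))
  a2 <- if (ncol(C) > 0) h$alpha2 else 0
  SU <- mm_loop(S, U); WU <- mm_loop(W, U)
  out <- U
  for (i in seq_len(nrow(U))) for (j in seq_len(ncol(U))) {
    num <- 2 * A[i, j] + 2 * h$alpha1 * P1[i, j] + 2 * a2 * P2[i, j] +
      2 * h$alpha3 * SU[i, j]
    den <- 2 * U[i, j] + 2 * h$alpha1 * U[i, j] + 2 * a2 * U[i, j] +
      2 * h$alpha3 * WU[i, j] + h$alpha4 + h$delta
    out[i, j] <- U[i, j] * num / den
  }
  out
}

update_X_loop <- function(U, X, Y, A, M, D, h) {
  DY <- mm_loop(D, Y)
  num <- mm_loop(t(M), mm_loop(U, DY))
  den <- mm_loop(t(M), mm_loop(M, mm_loop(X, mm_loop(t(DY), DY))))
  X * num / (den + h$delta)
}

update_Y_loop <- function(U, X, Y, Z, M, D, C, h) {
  MX <- mm_loop(M, X)
  a2 <- if (ncol(C) > 0) h$alpha2 else 0
  num <- h$alpha1 * mm_loop(t(D), mm_loop(t(U), MX))
  den <- h$alpha1 * mm_loop(mm_loop(t(D), mm_loop(D, Y)),
                            mm_loop(t(MX), MX))
  if (a2 > 0) {
    CZ <- mm_loop(C, Z)
    num <- num + a2 * mm_loop(t(D), mm_loop(t(U), CZ))
    den <- den + a2 * mm_loop(mm_loop(t(D), mm_loop(D, Y)),
                              mm_loop(t(CZ), CZ))
  }
  Y * num / (den + h$delta)
}

update_Z_loop <- function(U, Y, Z, D, C, h) {
  if (ncol(C) == 0) return(Z)
  DY <- mm_loop(D, Y)
  num <- mm_loop(t(C), mm_loop(U, DY))
  den <- mm_loop(t(C), mm_loop(C, mm_loop(Z, mm_loop(t(DY), DY))))
  Z * num / (den + h$delta)
}

# central finite differences of f at X
fd_gradient <- function(f, X, eps = 1e-6) {
  g <- X
  for (i in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[i] <- X[i] + eps; Xm[i] <- X[i] - eps
    g[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  g
}

# AUC by brute-force pair counting, ties as 1/2
auc_pairs <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# PR curve by brute-force threshold enumeration + independent trapezoid
aupr_brute <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  pr <- t(vapply(thr, function(t) {
    tp <- sum(pos >= t); fp <- sum(neg >= t)
    c(precision = tp / (tp + fp), recall = tp / length(pos))
  }, c(0, 0)))
  r <- c(0, pr[, "recall"]); p <- c(pr[1, "precision"], pr[, "precision"])
  area <- 0
  for (i in seq_len(length(r) - 1))
    area <- area + (r[i + 1] - r[i]) * (p[i] + p[i + 1]) / 2
  unname(area)
}

# random small model instance with strictly positive factors
rand_instance <- function(Nm = 4, Nd = 3, Nf = 2, Nc = 2, c = 2, seed = 1,
                          k = 2) {
  set.seed(seed)
  A <- matrix(rbinom(Nm * Nd, 1, 0.4), Nm, Nd)
  if (sum(A) == 0) A[1, 1] <- 1
  Ms <- matrix(runif(Nm * Nm), Nm, Nm); Ms <- (Ms + t(Ms)) / 2; diag(Ms) <- 1
  Ds <- matrix(runif(Nd * Nd), Nd, Nd); Ds <- (Ds + t(Ds)) / 2; diag(Ds) <- 1
  Cb <- matrix(rbinom(Nm * (Nf + Nc), 1, 0.5), Nm, Nf + Nc)
  rownames(A) <- rownames(Ms) <- rownames(Cb) <- paste0("m", seq_len(Nm))
  colnames(A) <- rownames(Ds) <- paste0("d", seq_len(Nd))
  data <- list(
    A = association_matrix(A),
    M = suppressWarnings(similarity_matrix(Ms, kind = "mirna")),
    D = suppressWarnings(similarity_matrix(Ds, kind = "disease")),
    C = attribute_matrix(Cb, paste0("f", seq_len(Nf)),
                         paste0("c", seq_len(Nc))))
  G <- build_neighbor_graph(data$M, k = k, symmetrize = TRUE)
  lap <- graph_laplacian(G)
  state <- list(U = matrix(runif(Nm * Nd), Nm, Nd) + 0.1,
                X = matrix(runif(Nm * c), Nm, c) + 0.1,
                Y = matrix(runif(Nd * c), Nd, c) + 0.1,
                Z = matrix(runif((Nf + Nc) * c), Nf + Nc, c) + 0.1,
                S = G$S, W = lap$W, L = lap$L)
  list(data = data, state = state)
}

# hyperparameters for small instances
h_small <- function(c = 2, k_neighbors = 2, ...)
  mda_hyperparams(c = c, k_neighbors = k_neighbors, ...)
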