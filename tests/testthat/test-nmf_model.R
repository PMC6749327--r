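# scalar (all dimensions 1) model pieces, built by hand
scalar_state <- function(U, X = 1, Y = 1, Z = 1, S = 0, W = 0) {
  m1 <- function(v) matrix(v, 1, 1)
  list(U = m1(U), X = m1(X), Y = m1(Y), Z = m1(Z),
       S = m1(S), W = m1(W), L = m1(W - S))
}
scalar_data <- function(A = 1, M = 1, D = 1, C = 1) {
  m1 <- function(v) matrix(v, 1, 1)
  ids <- list("m1", "d1")
  list(A = association_matrix(m1(A), "m1", "d1"),
       M = similarity_matrix(m1(M), "m1", "mirna"),
       D = similarity_matrix(m1(D), "d1", "disease"),
       C = if (is.null(C))
         attribute_matrix(matrix(0, 1, 0), character(0), character(0), "m1")
       else attribute_matrix(m1(C), "f1", character(0), "m1"))
}

test_that("objective evaluates exactly on degenerate and random instances", {
  # U = A with all penalties off -> 0
  inst <- rand_instance(seed = 1)
  h0 <- h_small(alpha1 = 0, alpha2 = 0, alpha3 = 0, alpha4 = 0)
  st <- inst$state; st$U <- unclass(inst$data$A)
  expect_equal(mda_objective(st, inst$data, h0)$total, 0)

  # everything zero -> 0
  z <- scalar_state(0, 0, 0, 0)
  expect_equal(mda_objective(z, scalar_data(A = 0), h_small(c = 1))$total, 0)

  # random instances match the brute-force summation oracle
  for (seed in 1:10) {
    inst <- rand_instance(Nm = 4, Nd = 3, seed = seed)
    h <- h_small()
    got <- mda_objective(inst$state, inst$data, h)
    want <- objective_loop(inst$state$U, inst$state$X, inst$state$Y,
                           inst$state$Z, unclass(inst$data$A),
                           unclass(inst$data$M), unclass(inst$data$D),
                           unclass(inst$data$C), inst$state$L, h)
    expect_equal(got$total, want$total, tolerance = 1e-12)
    expect_equal(got$fit_term, want$fit, tolerance = 1e-12)
    expect_equal(got$graph_term, want$gra, tolerance = 1e-12)
    # weighted identity holds exactly
    expect_identical(got$total,
                     got$fit_term + h$alpha1 * got$similarity_term +
                       h$alpha2 * got$attribute_term +
                       h$alpha3 * got$graph_term + h$alpha4 * got$sparsity_term)
  }
})

test_that("objective rejects dimension mismatches naming the offender", {
  inst <- rand_instance(seed = 2)
  st <- inst$state
  st$X <- st$X[, 1, drop = FALSE]
  expect_error(mda_objective(st, inst$data, h_small()), "X is")
})

test_that("update rules reproduce hand-evaluated scalar cases", {
  h0 <- mda_hyperparams(alpha1 = 0, alpha2 = 0, alpha3 = 0, alpha4 = 0,
                        c = 1, k_neighbors = 1)
  # with all alphas 0 the U ratio reduces to A/U
  expect_equal(update_U(scalar_state(0.5), scalar_data(A = 1), h0)[1, 1],
               1.0, tolerance = 1e-9)
  # X: M = U = D = Y = 1, X = 0.5 -> 1.0
  h1 <- mda_hyperparams(c = 1, k_neighbors = 1)
  expect_equal(unname(update_X(scalar_state(1, X = 0.5), scalar_data(), h1)[1, 1]),
               1.0, tolerance = 1e-9)
  # Y: all 1 except Y = 2, alpha1 = 1, alpha2 = 0 (no attribute columns)
  hy <- mda_hyperparams(alpha1 = 1, alpha2 = 0, c = 1, k_neighbors = 1)
  expect_equal(unname(update_Y(scalar_state(1, Y = 2), scalar_data(C = NULL), hy)[1, 1]),
               1.0, tolerance = 1e-9)
  # Z: C = U = D = Y = 1, Z = 4 -> 1.0
  expect_equal(unname(update_Z(scalar_state(1, Z = 4), scalar_data(), h1)[1, 1]),
               1.0, tolerance = 1e-9)
})

test_that("each update leaves its exact fixed points unchanged", {
  # U = A = MX(DY)' = CZ(DY)' with alpha3 = alpha4 = 0
  hu <- mda_hyperparams(alpha3 = 0, alpha4 = 0, c = 1, k_neighbors = 1)
  expect_equal(update_U(scalar_state(1), scalar_data(), hu)[1, 1], 1,
               tolerance = 1e-9)
  # MX(DY)' = U: M = 2, X = 0.5 -> projection 1 = U
  st <- scalar_state(1, X = 0.5)
  expect_equal(unname(update_X(st, scalar_data(M = 2), hu)[1, 1]), 0.5,
               tolerance = 1e-9)
  # alpha1 = alpha2, MX = CZ, MX(DY)' = U
  hy <- mda_hyperparams(alpha1 = 0.3, alpha2 = 0.3, c = 1, k_neighbors = 1)
  expect_equal(unname(update_Y(scalar_state(1), scalar_data(), hy)[1, 1]), 1,
               tolerance = 1e-9)
  expect_equal(unname(update_Z(scalar_state(1), scalar_data(), hy)[1, 1]), 1,
               tolerance = 1e-9)
})

test_that("vectorized updates match elementwise substitution oracles", {
  for (seed in 1:10) {
    inst <- rand_instance(Nm = 4, Nd = 3, seed = seed)
    h <- h_small()
    s <- inst$state; d <- inst$data
    expect_equal(update_U(s, d, h),
                 update_U_loop(s$U, s$X, s$Y, s$Z, unclass(d$A), unclass(d$M),
                               unclass(d$D), unclass(d$C), s$S, s$W, h),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(update_X(s, d, h),
                 update_X_loop(s$U, s$X, s$Y, unclass(d$A), unclass(d$M),
                               unclass(d$D), h),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(update_Y(s, d, h),
                 update_Y_loop(s$U, s$X, s$Y, s$Z, unclass(d$M), unclass(d$D),
                               unclass(d$C), h),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(update_Z(s, d, h),
                 update_Z_loop(s$U, s$Y, s$Z, unclass(d$D), unclass(d$C), h),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("update numerator/denominator split matches finite differences", {
  inst <- rand_instance(Nm = 4, Nd = 3, seed = 11)
  h <- h_small()
  s <- inst$state; d <- inst$data
  A <- unclass(d$A); M <- unclass(d$M); D <- unclass(d$D); C <- unclass(d$C)
  DYt <- t(D %*% s$Y)

  # U sub-objective (full objective as a function of U alone)
  fU <- function(U) {
    st <- s; st$U <- U
    mda_objective(st, d, h)$total
  }
  gU <- (2 * s$U + 2 * h$alpha1 * s$U + 2 * h$alpha2 * s$U +
           2 * h$alpha3 * (s$W %*% s$U) + h$alpha4) -
    (2 * A + 2 * h$alpha1 * (M %*% s$X %*% DYt) +
       2 * h$alpha2 * (C %*% s$Z %*% DYt) + 2 * h$alpha3 * (s$S %*% s$U))
  expect_equal(gU, fd_gradient(fU, s$U), tolerance = 1e-5,
               ignore_attr = TRUE)

  # X sub-objective
  fX <- function(X) h$alpha1 * sum((s$U - M %*% X %*% DYt)^2)
  gX <- 2 * h$alpha1 * (crossprod(M, M %*% s$X %*% crossprod(D %*% s$Y)) -
                          crossprod(M, s$U %*% (D %*% s$Y)))
  expect_equal(gX, fd_gradient(fX, s$X), tolerance = 1e-5,
               ignore_attr = TRUE)

  # Z sub-objective
  fZ <- function(Z) h$alpha2 * sum((s$U - C %*% Z %*% DYt)^2)
  gZ <- 2 * h$alpha2 * (crossprod(C, C %*% s$Z %*% crossprod(D %*% s$Y)) -
                          crossprod(C, s$U %*% (D %*% s$Y)))
  expect_equal(gZ, fd_gradient(fZ, s$Z), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("fit contract: max_iter = 0, forced convergence, trace recording", {
  inst <- rand_instance(Nm = 6, Nd = 4, seed = 5)
  h <- h_small(max_iter = 0)
  fit0 <- mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C, h = h)
  expect_equal(fit0$iterations, 0L)
  expect_equal(nrow(fit0$objective_trace), 1L)
  expect_true(all(predict_scores(fit0) > 0))

  # with all alphas 0 a single U update recovers A
  hA <- h_small(alpha1 = 0, alpha2 = 0, alpha3 = 0, alpha4 = 0, max_iter = 3)
  fitA <- mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C, h = hA)
  expect_lt(fitA$objective_trace$fit[2], 1e-15)

  # seeded determinism
  h2 <- h_small(max_iter = 10, seed = 42)
  f1 <- mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C, h = h2)
  f2 <- mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C, h = h2)
  expect_identical(f1$U, f2$U)

  # latent dimension must respect the data
  expect_error(mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C,
                       h = mda_hyperparams(c = 4, k_neighbors = 2)),
               "latent dimension")
})

test_that("factors stay nonnegative through a whole fit across seeds", {
  for (seed in 1:5) {
    syn <- generate_synthetic(synth_config(n_mirna = 40, n_disease = 15,
                                           n_family = 5, n_cluster = 6,
                                           rank = 4, seed = seed))
    fit <- mda_fit(syn$A, syn$M, syn$D, syn$C,
                   h = mda_hyperparams(c = 5, k_neighbors = 5,
                                       max_iter = 30, seed = seed))
    expect_gte(min(fit$U), 0)
    expect_gte(min(fit$X), 0)
    expect_gte(min(fit$Y), 0)
    expect_gte(min(fit$Z), 0)
  }
})

test_that("objective is non-increasing over recorded cycles", {
  for (seed in 1:3) {
    syn <- generate_synthetic(synth_config(n_mirna = 40, n_disease = 15,
                                           n_family = 5, n_cluster = 6,
                                           rank = 4, seed = seed))
    fit <- mda_fit(syn$A, syn$M, syn$D, syn$C,
                   h = mda_hyperparams(c = 5, k_neighbors = 5,
                                       max_iter = 50, seed = seed))
    tr <- fit$objective_trace$total
    expect_true(all(diff(tr) <= 1e-9 * abs(tr[-length(tr)])))
  }
})

test_that("doubling the sparsity weight never increases ||U||_1", {
  for (seed in 1:5) {
    syn <- generate_synthetic(synth_config(n_mirna = 30, n_disease = 12,
                                           n_family = 4, n_cluster = 5,
                                           rank = 3, seed = seed))
    l1 <- vapply(c(0.1, 0.2), function(a4) {
      fit <- mda_fit(syn$A, syn$M, syn$D, syn$C,
                     h = mda_hyperparams(alpha4 = a4, c = 4, k_neighbors = 4,
                                         max_iter = 80, seed = seed))
      sum(abs(fit$U))
    }, 0)
    expect_lte(l1[2], l1[1] + 1e-9)
  }
})

test_that("fit works across a sweep of latent dimensions", {
  syn <- generate_synthetic(synth_config(n_mirna = 60, n_disease = 25,
                                         n_family = 12, n_cluster = 12,
                                         rank = 4, seed = 8))
  for (c_dim in c(5, 10, 15, 20)) {
    fit <- mda_fit(syn$A, syn$M, syn$D, syn$C,
                   h = mda_hyperparams(c = c_dim, k_neighbors = 5,
                                       max_iter = 15, seed = 1))
    tr <- fit$objective_trace$total
    expect_lt(tr[length(tr)], tr[1])
  }
})

test_that("candidate ranking excludes known training positives", {
  inst <- rand_instance(Nm = 6, Nd = 4, seed = 9)
  fit <- mda_fit(inst$data$A, inst$data$M, inst$data$D, inst$data$C,
                 h = h_small(max_iter = 10))
  known <- which(unclass(inst$data$A)[, 1] == 1)
  rc <- rank_candidates(fit, "d1", exclude = inst$data$A)
  expect_false(any(paste0("m", known) %in% rc$mirna))
  expect_equal(nrow(rc), 6 - length(known))
  expect_true(all(diff(rc$score) <= 0))
})
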