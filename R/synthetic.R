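#' Configuration of the synthetic fixture generator
#'
#' The generator emulates the statistical shape of the real inputs (a sparse
#' binary bipartite association matrix with low-rank block structure,
#' similarity matrices consistent with that structure, and sparse one-hot
#' family/cluster attribute rows) so that every stage of the pipeline is
#' testable without downloading any database. Defaults state a world in
#' which 200 miRNAs in 20 families and 30 genomic clusters associate with 40
#' diseases through a rank-6 latent structure at 8% density, with mild
#' similarity noise (sd 0.05) and 2% label flips.
#'
#' @param n_mirna,n_disease,n_family,n_cluster positive counts.
#' @param rank planted latent dimension, `< min(n_mirna, n_disease)`.
#' @param density target fraction of positive associations in (0, 1).
#'   The clean thresholding level is chosen so that the *post-flip* expected
#'   density equals the target.
#' @param noise_sd standard deviation of the symmetric Gaussian perturbation
#'   added to the cosine similarity matrices (truncated to \[0, 1\]).
#' @param flip_prob independent label-flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @return list with class `"synth_config"`.
#' @export
synth_config <- function(n_mirna = 200L, n_disease = 40L, n_family = 20L,
                         n_cluster = 30L, rank = 6L, density = 0.08,
                         noise_sd = 0.05, flip_prob = 0.02, seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
              n_family = as.integer(n_family), n_cluster = as.integer(n_cluster),
              rank = as.integer(rank), density = density, noise_sd = noise_sd,
              flip_prob = flip_prob, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_mirna, n_disease, n_family, n_cluster, rank) < 1))
      stop("synth_config: counts and rank must be positive")
    if (rank >= min(n_mirna, n_disease))
      stop(sprintf("synth_config: rank = %d must be < min(n_mirna, n_disease) = %d",
                   rank, min(n_mirna, n_disease)))
    if (density <= 0 || density >= 1)
      stop("synth_config: density must be in (0, 1)")
    if (flip_prob < 0 || flip_prob >= 0.5)
      stop("synth_config: flip_prob must be in [0, 0.5)")
    if (noise_sd < 0) stop("synth_config: noise_sd must be >= 0")
    if (n_family < 2 && rank > 1)
      stop("synth_config: a single family cannot carry rank > 1 prototype structure")
    if (density <= flip_prob)
      stop("synth_config: density must exceed flip_prob (signal below noise floor)")
  })
  structure(cfg, class = "synth_config")
}

#' Generate a seeded synthetic association/similarity/attribute fixture
#'
#' Draws nonnegative latent factors with planted family/cluster block
#' structure: each miRNA belongs to one family and one cluster, and its
#' latent row is family prototype + 0.5 x cluster prototype + |N(0, 0.1)|
#' noise, so miRNAs sharing a family (or, more weakly, a cluster) share
#' association patterns and the attribute columns genuinely predict links.
#' The full probability matrix is `truth = P Q'` rescaled to \[0, 1\];
#' associations are obtained by thresholding `truth` at the quantile whose
#' post-flip expected density equals the target, then flipping each cell
#' independently with `flip_prob`. Similarities are cosine similarities of
#' the latent rows plus symmetric Gaussian noise, truncated to \[0, 1\] with
#' unit diagonal.
#'
#' @param config a [synth_config()].
#' @return list: `A` (association matrix), `M`, `D` (similarity matrices),
#'   `C` (attribute matrix), `truth` (full `Nm x Nd` probability matrix),
#'   `family`, `cluster` (integer membership vectors), `config`.
#' @examples
#' syn <- generate_synthetic(synth_config(n_mirna = 40, n_disease = 15,
#'                                        rank = 4, seed = 3))
#' syn$A
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    Nm <- config$n_mirna; Nd <- config$n_disease; r <- config$rank
    fam <- sample.int(config$n_family, Nm, replace = TRUE)
    clu <- sample.int(config$n_cluster, Nm, replace = TRUE)
    fam_proto <- matrix(stats::runif(config$n_family * r), config$n_family, r)
    clu_proto <- matrix(stats::runif(config$n_cluster * r), config$n_cluster, r)
    P <- fam_proto[fam, , drop = FALSE] +
      0.5 * clu_proto[clu, , drop = FALSE] +
      abs(matrix(stats::rnorm(Nm * r, sd = 0.1), Nm, r))
    Q <- matrix(stats::runif(Nd * r), Nd, r)
    truth <- P %*% t(Q)
    truth <- truth / max(truth)

    # threshold so that expected density AFTER flips hits the target:
    # density = d0 (1 - flip) + (1 - d0) flip  =>  d0 as below
    d0 <- (config$density - config$flip_prob) / (1 - 2 * config$flip_prob)
    thr <- stats::quantile(truth, 1 - d0, names = FALSE)
    A <- (truth > thr) * 1
    if (config$flip_prob > 0) {
      flip <- matrix(stats::runif(Nm * Nd) < config$flip_prob, Nm, Nd)
      A <- abs(A - flip * 1)
    }

    mirna_ids <- paste0("m", seq_len(Nm))
    disease_ids <- paste0("d", seq_len(Nd))
    dimnames(A) <- list(mirna_ids, disease_ids)
    dimnames(truth) <- dimnames(A)

    M <- noisy_cosine(P, config$noise_sd)
    D <- noisy_cosine(Q, config$noise_sd)
    dimnames(M) <- list(mirna_ids, mirna_ids)
    dimnames(D) <- list(disease_ids, disease_ids)

    family_ids <- paste0("fam", seq_len(config$n_family))
    cluster_ids <- paste0("clu", seq_len(config$n_cluster))
    C <- matrix(0, Nm, config$n_family + config$n_cluster)
    C[cbind(seq_len(Nm), fam)] <- 1
    C[cbind(seq_len(Nm), config$n_family + clu)] <- 1

    list(A = association_matrix(A),
         M = similarity_matrix(M, kind = "mirna"),
         D = similarity_matrix(D, kind = "disease"),
         C = attribute_matrix(C, family_ids, cluster_ids,
                              mirna_ids = mirna_ids),
         truth = truth, family = fam, cluster = clu, config = config)
  })
}

#' Write a synthetic fixture to a directory
#'
#' Writes `A.tsv`, `M.tsv`, `D.tsv`, `C.tsv`, `truth.tsv` plus a
#' `manifest.yaml` recording the full generator configuration (including the
#' seed), so a fixture directory is reproducible and self-describing.
#'
#' @param syn a [generate_synthetic()] result.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_synthetic <- function(syn, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(syn$A, file.path(outdir, "A.tsv"))
  write_matrix_tsv(syn$M, file.path(outdir, "M.tsv"))
  write_matrix_tsv(syn$D, file.path(outdir, "D.tsv"))
  write_matrix_tsv(syn$C, file.path(outdir, "C.tsv"))
  write_matrix_tsv(syn$truth, file.path(outdir, "truth.tsv"))
  yaml::write_yaml(unclass(syn$config), file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

# cosine similarity of rows with symmetric noise, clamped to [0,1], diag 1
noisy_cosine <- function(X, noise_sd) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(X / nrm)
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(nrow(X)^2, sd = noise_sd), nrow(X))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}
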