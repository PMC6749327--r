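#' Partition known associations into cross-validation folds
#'
#' Randomly divides all known positive (miRNA, disease) cells of `A` into
#' `n_folds` near-equal disjoint parts (sizes differ by at most 1). In each
#' cross-validation round one part is held out as the test set and the
#' remaining parts train the model.
#'
#' @param A association matrix with at least `n_folds` positives.
#' @param seed integer seed; the same seed reproduces the same folds.
#' @param n_folds number of folds (default 5).
#' @return list with class `"fold_plan"`: `folds` (list of two-column index
#'   matrices, columns `mirna`, `disease`), `seed`, `n_folds`.
#' @export
make_folds <- function(A, seed, n_folds = 5L) {
  pos <- which(unclass(A) == 1, arr.ind = TRUE)
  colnames(pos) <- c("mirna", "disease")
  n_folds <- as.integer(n_folds)
  if (nrow(pos) < n_folds)
    stop(sprintf("only %d positives but %d folds requested", nrow(pos), n_folds))
  perm <- local_seed(seed, sample.int(nrow(pos)))
  assignment <- rep_len(seq_len(n_folds), nrow(pos))
  folds <- lapply(seq_len(n_folds), function(f)
    pos[perm[assignment == f], , drop = FALSE])
  structure(list(folds = folds, seed = as.integer(seed), n_folds = n_folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: %d folds of sizes %s (seed %d)\n", x$n_folds,
              paste(vapply(x$folds, nrow, 0L), collapse = ", "), x$seed))
  invisible(x)
}

#' Mask a test fold out of the association matrix
#'
#' Returns a copy of `A` with the fold's cells set to 0 -- the training
#' matrix for that cross-validation round. The masked positives are later
#' treated as the positive class at evaluation time and are never counted
#' among the negatives.
#'
#' @param A association matrix.
#' @param fold two-column index matrix (one element of a
#'   [make_folds()] plan); every cell must be a positive of `A`.
#' @return training [association_matrix()].
#' @export
mask_fold <- function(A, fold) {
  fold <- as.matrix(fold)
  if (nrow(fold) == 0) return(A)
  if (any(unclass(A)[fold[, 1:2, drop = FALSE]] != 1))
    stop("mask_fold: fold contains cells that are not positives of A")
  out <- unclass(A)
  out[fold[, 1:2, drop = FALSE]] <- 0
  association_matrix(out)
}

#' Ranking AUC from positive and negative score lists
#'
#' Area under the ROC curve, computed by ranks: equal to the fraction of
#' (positive, negative) score pairs in which the positive scores higher,
#' counting ties as 1/2.
#'
#' @param pos_scores,neg_scores nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop("rank_auc: both score lists must be nonempty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall curve and its area
#'
#' Sweeps the decision threshold over every distinct score (descending; a
#' sample is called positive when its score is >= the threshold) and records
#' precision and recall at each. The area is computed by the trapezoid rule
#' on the recall-ordered curve, with the curve anchored at recall 0 using
#' the precision of the strictest threshold; `method = "average_precision"`
#' gives the step-function estimator instead.
#'
#' @param pos_scores,neg_scores nonempty numeric vectors.
#' @param method `"trapezoid"` (default) or `"average_precision"`.
#' @return list: `curve` (data frame `threshold`, `precision`, `recall`)
#'   and `aupr`.
#' @export
pr_aupr <- function(pos_scores, neg_scores,
                    method = c("trapezoid", "average_precision")) {
  method <- match.arg(method)
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop("pr_aupr: both score lists must be nonempty")
  np <- length(pos_scores)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos_scores >= t), 0)
  fp <- vapply(thr, function(t) sum(neg_scores >= t), 0)
  precision <- tp / (tp + fp)
  recall <- tp / np
  curve <- data.frame(threshold = thr, precision = precision, recall = recall)
  if (method == "trapezoid") {
    r <- c(0, recall); p <- c(precision[1], precision)
    aupr <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  } else {
    r <- c(0, recall)
    aupr <- sum(diff(r) * precision)
  }
  list(curve = curve, aupr = aupr)
}

#' Recall among the top-k ranked predictions
#'
#' Biologists validate the top of a ranked candidate list first, so the
#' fraction of all true positives retrieved within the first `k` positions
#' is reported alongside AUC/AUPR.
#'
#' @param ranked_labels binary vector ordered by decreasing predicted score.
#' @param k cutoff (values beyond the list length are truncated to it).
#' @param total_pos total number of positives (denominator); must be >= 1.
#' @return recall at `k`.
#' @export
top_k_recall <- function(ranked_labels, k, total_pos) {
  if (total_pos < 1) stop("top_k_recall: total_pos must be >= 1")
  if (k < 1) stop("top_k_recall: k must be >= 1")
  k <- min(k, length(ranked_labels))
  sum(ranked_labels[seq_len(k)] == 1) / total_pos
}

#' Run the 5-fold cross-validation protocol
#'
#' For each fold: mask the fold's positives out of `A`, optionally recompute
#' the miRNA functional similarity from the training matrix only (to avoid
#' test-label leakage), fit the model, then for every evaluated disease rank
#' that disease's candidate miRNAs -- the fold's held-out positives form the
#' positive class, miRNAs never associated with the disease in the full `A`
#' form the negative class, and training positives are excluded from the
#' ranking. Per-disease AUC, AUPR and top-k recall are averaged over the
#' folds in which the disease has at least one held-out positive, and ROC /
#' PR curves are vertically averaged on a fixed grid. Report-level averages
#' are arithmetic means over the evaluated diseases.
#'
#' @param A,M,D,C input matrices (`C` may be `NULL`).
#' @param h hyperparameters.
#' @param evaluated_diseases disease identifiers (or column indices) to
#'   evaluate; `NULL` selects by `min_positives`.
#' @param seed seed controlling the fold split and the per-fold model seeds.
#' @param n_folds number of folds (default 5).
#' @param min_positives when `evaluated_diseases` is `NULL`, evaluate the
#'   diseases with at least this many known miRNAs (the well-characterized
#'   common diseases); default 80, the cutoff used for the 15-disease
#'   evaluation on real data.
#' @param recompute_mirna_sim logical; recompute `M` from each training fold
#'   via [mirna_functional_similarity()] (leakage-free when `M` itself is
#'   derived from the associations). Keep `FALSE` when `M` comes from an
#'   independent source.
#' @param scorer optional function `(A_train, M, D, C, h, fold)` returning an
#'   `Nm x Nd` score matrix, replacing the model fit (used for protocol
#'   sanity checks with oracle or random scores).
#' @param top_k cutoffs for top-k recall.
#' @param curve_grid number of grid points for vertical curve averaging.
#' @return list with class `"evaluation_report"`: `per_disease` (per-disease
#'   metrics, fold table, averaged curves), `average` (mean AUC, AUPR,
#'   top-k recall over diseases), `diseases`, `fold_plan`.
#' @export
run_cross_validation <- function(A, M, D, C = NULL, h = mda_hyperparams(),
                                 evaluated_diseases = NULL, seed = 1L,
                                 n_folds = 5L, min_positives = 80L,
                                 recompute_mirna_sim = FALSE, scorer = NULL,
                                 top_k = c(30L, 60L, 90L),
                                 curve_grid = 1000L) {
  check_data_dims(A, M, D, C)
  Am <- unclass(A)
  dis_ids <- colnames(A) %||% as.character(seq_len(ncol(A)))
  if (is.null(evaluated_diseases)) {
    eval_j <- which(colSums(Am) >= min_positives)
    if (length(eval_j) == 0)
      stop(sprintf("no disease has >= %d positives; pass evaluated_diseases explicitly",
                   min_positives))
  } else {
    eval_j <- if (is.character(evaluated_diseases))
      match(evaluated_diseases, dis_ids) else as.integer(evaluated_diseases)
    if (anyNA(eval_j) || any(eval_j < 1 | eval_j > ncol(A)))
      stop("unknown disease in evaluated_diseases")
  }

  plan <- make_folds(A, seed = seed, n_folds = n_folds)
  grid <- seq(0, 1, length.out = curve_grid)
  per_fold <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    fold <- plan$folds[[f]]
    A_train <- mask_fold(A, fold)
    M_f <- if (recompute_mirna_sim) mirna_functional_similarity(A_train, D) else M
    scores <- if (is.null(scorer)) {
      h_f <- h
      h_f$seed <- h$seed + f   # independent init per fold
      predict_scores(mda_fit(A_train, M_f, D, C, h = h_f))
    } else {
      scorer(A_train, M_f, D, C, h, f)
    }
    stopifnot(all(dim(scores) == dim(A)))
    res <- lapply(eval_j, function(j) {
      pos_i <- fold[fold[, "disease"] == j, "mirna"]
      if (length(pos_i) == 0) return(NULL)
      cand <- which(unclass(A_train)[, j] == 0)   # excludes training positives
      lab <- as.integer(cand %in% pos_i)
      sc <- scores[cand, j]
      ord <- order(-sc, cand)
      pr <- pr_aupr(sc[lab == 1], sc[lab == 0])
      roc <- roc_points(sc[lab == 1], sc[lab == 0])
      list(auc = rank_auc(sc[lab == 1], sc[lab == 0]),
           aupr = pr$aupr,
           topk = vapply(top_k, function(k)
             top_k_recall(lab[ord], k, length(pos_i)), 0),
           tpr_grid = stats::approx(roc$fpr, roc$tpr, xout = grid,
                                    ties = max, rule = 2)$y,
           prec_grid = stats::approx(c(0, pr$curve$recall),
                                     c(pr$curve$precision[1], pr$curve$precision),
                                     xout = grid, ties = max, rule = 2)$y,
           n_pos = length(pos_i))
    })
    names(res) <- dis_ids[eval_j]
    per_fold[[f]] <- res
  }

  per_disease <- list()
  for (d in dis_ids[eval_j]) {
    entries <- Filter(Negate(is.null), lapply(per_fold, `[[`, d))
    if (length(entries) == 0) {
      warning(sprintf("disease %s has no held-out positives in any fold; excluded", d))
      next
    }
    topk_mat <- do.call(rbind, lapply(entries, `[[`, "topk"))
    colnames(topk_mat) <- paste0("top", top_k)
    per_disease[[d]] <- list(
      auc = mean(vapply(entries, `[[`, 0, "auc")),
      aupr = mean(vapply(entries, `[[`, 0, "aupr")),
      topk_recall = colMeans(topk_mat),
      roc = data.frame(fpr = grid,
                       tpr = rowMeans(sapply(entries, `[[`, "tpr_grid"))),
      pr = data.frame(recall = grid,
                      precision = rowMeans(sapply(entries, `[[`, "prec_grid"))),
      per_fold = data.frame(
        fold = which(!vapply(lapply(per_fold, `[[`, d), is.null, TRUE)),
        auc = vapply(entries, `[[`, 0, "auc"),
        aupr = vapply(entries, `[[`, 0, "aupr"),
        n_pos = vapply(entries, `[[`, 0, "n_pos")))
  }
  if (length(per_disease) == 0)
    stop("no evaluated disease had held-out positives in any fold")

  topk_avg <- colMeans(do.call(rbind,
    lapply(per_disease, `[[`, "topk_recall")))
  structure(list(
    per_disease = per_disease,
    average = list(auc = mean(vapply(per_disease, `[[`, 0, "auc")),
                   aupr = mean(vapply(per_disease, `[[`, 0, "aupr")),
                   topk_recall = topk_avg),
    diseases = names(per_disease),
    fold_plan = plan),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("cross-validation report: %d diseases, %d folds\n",
              length(x$diseases), x$fold_plan$n_folds))
  cat(sprintf("  mean AUC  = %.4f\n  mean AUPR = %.4f\n",
              x$average$auc, x$average$aupr))
  tk <- x$average$topk_recall
  cat(sprintf("  mean recall: %s\n",
              paste(sprintf("%s %.3f", names(tk), tk), collapse = ", ")))
  invisible(x)
}

#' Per-disease metric table of an evaluation report
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return data frame with one row per evaluated disease (AUC, AUPR and
#'   top-k recalls).
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  rows <- lapply(names(x$per_disease), function(d) {
    e <- x$per_disease[[d]]
    cbind(data.frame(disease = d, auc = e$auc, aupr = e$aupr),
          as.data.frame(as.list(e$topk_recall)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test on per-disease AUCs of two methods
#'
#' Two-sided paired t statistic on the per-disease differences with `n - 1`
#' degrees of freedom, as used to test whether one method's per-disease
#' AUCs (or AUPRs) are significantly higher than another's. With zero
#' variance of the differences, p is reported as exactly 1 when the mean
#' difference is 0 and as the 0 limit (with a warning) otherwise.
#'
#' @param auc_a,auc_b equal-length paired metric vectors (length >= 2).
#' @return list: `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_auc_test <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b))
    stop("paired_auc_test: lists must have equal length")
  n <- length(auc_a)
  if (n < 2) stop("paired_auc_test: need at least 2 paired values")
  d <- auc_a - auc_b
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p_value = 1, mean_diff = 0))
    warning("zero variance of differences with nonzero mean; p -> 0")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                mean_diff = mean(d)))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       mean_diff = mean(d))
}

#' Serialize an evaluation report to JSON
#'
#' Writes the per-disease metric blocks and the averages; curves are
#' included only on request (they are large).
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @param curves logical; include the averaged ROC/PR curves.
#' @export
write_report_json <- function(report, path, curves = FALSE) {
  per <- lapply(report$per_disease, function(e) {
    out <- list(auc = e$auc, aupr = e$aupr,
                topk_recall = as.list(e$topk_recall),
                per_fold = e$per_fold)
    if (curves) { out$roc <- e$roc; out$pr <- e$pr }
    out
  })
  jsonlite::write_json(list(average = list(auc = report$average$auc,
                                           aupr = report$average$aupr,
                                           topk_recall = as.list(report$average$topk_recall)),
                            per_disease = per,
                            seed = report$fold_plan$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# stepwise ROC points from score lists, (0,0) and (1,1) anchored
roc_points <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}
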