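#' Read a miRNA-disease association matrix
#'
#' Reads either a dense tab-separated matrix (header row of disease ids,
#' first column of miRNA ids) or a two-column tab-separated edge list of
#' `(mirna_id, disease_id)` pairs. For edge lists, row and column order is
#' the order of first appearance; duplicate edges are deduplicated with a
#' warning. The observed density is reported on load.
#'
#' @param path file path.
#' @param format `"dense_tsv"` or `"edge_list"`.
#' @return an [association_matrix()].
#' @export
read_association_matrix <- function(path, format = c("dense_tsv", "edge_list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "dense_tsv") {
    tab <- read_dense_tsv(path)
    A <- association_matrix(tab)
  } else {
    edges <- utils::read.delim(path, header = FALSE, sep = "\t",
                               colClasses = "character",
                               comment.char = "#")
    if (ncol(edges) < 2) stop("edge list must have two tab-separated columns")
    edges <- edges[, 1:2]
    dup <- duplicated(edges)
    if (any(dup)) {
      warning(sprintf("%d duplicate edge(s) removed", sum(dup)))
      edges <- edges[!dup, , drop = FALSE]
    }
    mirna_ids <- unique(edges[[1]])
    disease_ids <- unique(edges[[2]])
    A <- matrix(0, length(mirna_ids), length(disease_ids),
                dimnames = list(mirna_ids, disease_ids))
    A[cbind(match(edges[[1]], mirna_ids), match(edges[[2]], disease_ids))] <- 1
    A <- association_matrix(A)
  }
  message(sprintf("loaded %d x %d association matrix, density %.4f",
                  nrow(A), ncol(A), assoc_density(A)))
  A
}

#' Read a similarity matrix from dense TSV
#'
#' @param path file path to a square tab-separated table whose header labels
#'   match its first column.
#' @param kind `"mirna"` or `"disease"`.
#' @return a [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, kind = c("mirna", "disease")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- read_dense_tsv(path)
  if (nrow(tab) != ncol(tab))
    stop(sprintf("similarity table in %s is %d x %d, must be square",
                 path, nrow(tab), ncol(tab)))
  if (!identical(rownames(tab), colnames(tab)))
    stop("similarity table header and index labels do not match")
  similarity_matrix(tab, kind = kind)
}

#' Build the node-attribute matrix from an annotation table
#'
#' Turns a long annotation table into the binary family/cluster membership
#' matrix `C`. Family columns precede cluster columns; within each block,
#' columns follow the first-appearance order of the annotation table.
#' miRNAs in `mirna_ids` that carry no annotation get all-zero rows.
#'
#' @param annotations data frame with columns `mirna_id`, `attribute_id`,
#'   `attribute_type` (values `"family"` or `"cluster"`).
#' @param mirna_ids ordered miRNA universe; must cover every annotated miRNA.
#' @return an [attribute_matrix()].
#' @examples
#' ann <- data.frame(mirna_id = c("m1", "m2"),
#'                   attribute_id = c("fam_A", "clu_B"),
#'                   attribute_type = c("family", "cluster"))
#' build_attribute_matrix(ann, c("m1", "m2", "m3"))
#' @export
build_attribute_matrix <- function(annotations, mirna_ids) {
  mirna_ids <- as.character(mirna_ids)
  check_ids(mirna_ids, length(mirna_ids), "miRNA")
  if (nrow(annotations) == 0) {
    return(attribute_matrix(matrix(0, length(mirna_ids), 0),
                            family_ids = character(0),
                            cluster_ids = character(0),
                            mirna_ids = mirna_ids))
  }
  need <- c("mirna_id", "attribute_id", "attribute_type")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns mirna_id, attribute_id, attribute_type")
  typ <- as.character(annotations$attribute_type)
  if (!all(typ %in% c("family", "cluster")))
    stop(sprintf("unknown attribute_type value(s): %s",
                 paste(unique(setdiff(typ, c("family", "cluster"))),
                       collapse = ", ")))
  mid <- as.character(annotations$mirna_id)
  missing <- setdiff(mid, mirna_ids)
  if (length(missing))
    stop(sprintf("annotated miRNA(s) not in mirna_ids: %s",
                 paste(unique(missing), collapse = ", ")))
  aid <- as.character(annotations$attribute_id)
  family_ids <- unique(aid[typ == "family"])
  cluster_ids <- unique(aid[typ == "cluster"])
  cols <- c(family_ids, cluster_ids)
  X <- matrix(0, length(mirna_ids), length(cols),
              dimnames = list(mirna_ids, cols))
  # cluster columns sit after the family block even if an id repeats
  col_idx <- ifelse(typ == "family", match(aid, family_ids),
                    length(family_ids) + match(aid, cluster_ids))
  X[cbind(match(mid, mirna_ids), col_idx)] <- 1
  attribute_matrix(X, family_ids = family_ids, cluster_ids = cluster_ids,
                   mirna_ids = mirna_ids)
}

#' Read a node-attribute matrix written by [write_matrix_tsv()]
#'
#' The file carries a `# n_family:` comment line recording how many leading
#' columns form the family block, so a write/read round trip preserves the
#' family/cluster split.
#'
#' @param path file path.
#' @param n_family number of leading family columns; if `NULL`, taken from
#'   the `# n_family:` header comment.
#' @return an [attribute_matrix()].
#' @export
read_attribute_matrix <- function(path, n_family = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(n_family)) {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("^#\\s*n_family:\\s*(\\d+)", first))[[1]]
    if (length(m) < 2)
      stop("n_family not given and no '# n_family:' header found")
    n_family <- as.integer(m[2])
  }
  tab <- read_dense_tsv(path)
  if (n_family > ncol(tab))
    stop(sprintf("n_family = %d exceeds %d columns", n_family, ncol(tab)))
  attribute_matrix(tab,
                   family_ids = colnames(tab)[seq_len(n_family)],
                   cluster_ids = colnames(tab)[-seq_len(n_family)][
                     seq_len(ncol(tab) - n_family)])
}

#' Write a matrix to dense TSV
#'
#' Canonical on-disk format: tab-separated, a header row of column ids and
#' an index column of row ids. Attribute matrices additionally get a
#' `# n_family:` comment line so the column-block split survives a round
#' trip. Values are written with full precision.
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(x, "attr_matrix"))
    writeLines(sprintf("# n_family: %d", length(attr(x, "family_ids"))), con)
  header <- paste(c("id", colnames(x)), collapse = "\t")
  writeLines(header, con)
  body <- apply(unclass(x), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Align association, similarity and attribute matrices to one universe
#'
#' Intersects and reorders all supplied matrices to a shared miRNA order
#' (rows of `A`, `M`, `C`) and a shared disease order (columns of `A`,
#' rows/columns of `D`). The association matrix's own ordering of the
#' intersection is used as the canonical order.
#'
#' @param A association matrix.
#' @param M,D,C optional miRNA similarity, disease similarity and attribute
#'   matrices.
#' @return list with elements `A`, and whichever of `M`, `D`, `C` were given,
#'   all index-aligned.
#' @export
align_universe <- function(A, M = NULL, D = NULL, C = NULL) {
  mir <- rownames(A); dis <- colnames(A)
  if (!is.null(M)) mir <- intersect(mir, rownames(M))
  if (!is.null(C)) mir <- intersect(mir, rownames(C))
  if (!is.null(D)) dis <- intersect(dis, rownames(D))
  if (length(mir) == 0) stop("align_universe: empty miRNA intersection")
  if (length(dis) == 0) stop("align_universe: empty disease intersection")
  out <- list(A = association_matrix(unclass(A)[mir, dis, drop = FALSE]))
  if (!is.null(M))
    out$M <- similarity_matrix(unclass(M)[mir, mir, drop = FALSE],
                               kind = "mirna")
  if (!is.null(D))
    out$D <- similarity_matrix(unclass(D)[dis, dis, drop = FALSE],
                               kind = "disease")
  if (!is.null(C))
    out$C <- attribute_matrix(unclass(C)[mir, , drop = FALSE],
                              family_ids = attr(C, "family_ids"),
                              cluster_ids = attr(C, "cluster_ids"))
  out
}

#' Read hyperparameters from a YAML config file
#'
#' Recognized keys are the arguments of [mda_hyperparams()]; missing keys
#' take their defaults, unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return an `mda_hyperparams` object.
#' @export
read_hyperparams <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(mda_hyperparams))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(mda_hyperparams, cfg)
}

#' Export a binary graph as a three-column edge list
#'
#' Writes one `(i, j, 1)` row per nonzero entry, tab-separated, using the
#' row/column names of `S` as identifiers.
#'
#' @param S binary adjacency matrix (e.g. the `S` element of
#'   [build_neighbor_graph()]).
#' @param path output path.
#' @export
write_graph_edge_list <- function(S, path) {
  idx <- which(S != 0, arr.ind = TRUE)
  ids_i <- if (is.null(rownames(S))) idx[, 1] else rownames(S)[idx[, 1]]
  ids_j <- if (is.null(colnames(S))) idx[, 2] else colnames(S)[idx[, 2]]
  utils::write.table(data.frame(ids_i, ids_j, 1L), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# dense TSV with header row + index column; '#' comment lines skipped
read_dense_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, comment.char = "#")
  as.matrix(tab)
}
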