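# Reference-based annotation: highly variable gene selection, nearest-
# centroid label transfer by Pearson (and, for the concordance check,
# Spearman) correlation, SNN/Louvain clustering and subtype composition
# tables.

.logcounts <- function(sce) {
  if (methods::is(sce, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
      stop("object has no logcounts assay; run logNormalize() first")
    SummarizedExperiment::assay(sce, "logcounts")
  } else as.matrix(sce)
}

#' Select highly variable genes
#'
#' Fits a second-degree polynomial mean-variance trend to per-gene
#' log-expression (ordinary least squares) and returns the `n` genes with
#' the largest residual variance above the trend. Ties break
#' lexicographically by gene id, so the selection is deterministic.
#'
#' @param sce SingleCellExperiment with `logcounts` (or a log-expression
#'   matrix).
#' @param n number of genes to return.
#' @return Character vector of gene ids, ranked.
#' @export
findHVGs <- function(sce, n = 1000) {
  x <- .logcounts(sce)
  if (ncol(x) < 2) stop("need at least 2 cells to estimate variance")
  if (n > nrow(x)) stop("n exceeds the number of genes")
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (ncol(x) - 1)
  fit <- lm(v ~ mu + I(mu^2))
  resid <- v - predict(fit)
  ids <- rownames(x)
  ord <- order(-resid, ids)
  ids[ord][seq_len(n)]
}

.annotateCor <- function(query, atlas, hvgs, method = "pearson") {
  q <- .logcounts(query)
  p <- atlasProfiles(atlas)
  genes <- intersect(intersect(hvgs, rownames(p)), rownames(q))
  if (length(genes) < 3)
    stop("need at least 3 shared genes between query, atlas and HVG list")
  q <- q[genes, , drop = FALSE]
  p <- p[genes, , drop = FALSE]
  suppressWarnings(cc <- cor(q, p, method = method))
  types <- colnames(p)
  n <- nrow(cc)
  best <- character(n); bestCor <- rep(NA_real_, n)
  runner <- rep(NA_character_, n); runnerCor <- rep(NA_real_, n)
  tie <- logical(n); unassignable <- logical(n)
  for (i in seq_len(n)) {
    ci <- cc[i, ]
    if (all(is.na(ci))) {
      best[i] <- "unassignable"; unassignable[i] <- TRUE
      next
    }
    ord <- order(-ci, types)
    best[i] <- types[ord[1]]; bestCor[i] <- ci[ord[1]]
    if (length(types) > 1) {
      runner[i] <- types[ord[2]]; runnerCor[i] <- ci[ord[2]]
      tie[i] <- isTRUE(all.equal(ci[ord[1]], ci[ord[2]]))
    }
  }
  S4Vectors::DataFrame(
    cell_id = colnames(q), best_type = best, best_cor = bestCor,
    runner_up = runner, runner_up_cor = runnerCor,
    margin = ifelse(unassignable, NA_real_, bestCor - runnerCor),
    tie = tie, unassignable = unassignable,
    row.names = colnames(q))
}

#' Correlation-based label transfer from a reference atlas
#'
#' Computes, per query cell, the Pearson correlation of its log-expression
#' profile against every atlas centroid over the intersection of the
#' supplied highly variable genes with both gene universes, and assigns
#' the type with the highest correlation. Exact correlation ties break
#' lexicographically by type label and are flagged; cells with a constant
#' profile over the gene intersection (undefined correlation) are labelled
#' `"unassignable"`.
#'
#' @param query SingleCellExperiment with `logcounts` (or a matrix).
#' @param atlas a [ReferenceAtlas-class].
#' @param hvgs character vector of genes to correlate over.
#' @return A `DataFrame` with per-cell `best_type`, `best_cor`,
#'   `runner_up`, `runner_up_cor`, `margin`, `tie`, `unassignable`.
#' @export
labelTransfer <- function(query, atlas, hvgs) {
  .annotateCor(query, atlas, hvgs, "pearson")
}

#' Rank-correlation annotator (independent second opinion)
#'
#' Identical to [labelTransfer()] but uses Spearman rank correlation
#' against the centroids, providing an annotation route insensitive to
#' monotone transforms; used for the concordance check between annotators.
#'
#' @inheritParams labelTransfer
#' @return A `DataFrame` as in [labelTransfer()].
#' @export
labelTransferRank <- function(query, atlas, hvgs) {
  .annotateCor(query, atlas, hvgs, "spearman")
}

#' Agreement between two annotators
#'
#' @param a,b assignments from [labelTransfer()] / [labelTransferRank()]
#'   over the same cells.
#' @return list with `rate` (fraction of cells assigned the same type,
#'   excluding cells unassignable in either) and `confusion` (type x type
#'   contingency table).
#' @export
concordance <- function(a, b) {
  common <- intersect(a$cell_id, b$cell_id)
  if (!length(common)) stop("assignments cover disjoint cell sets")
  a <- a[match(common, a$cell_id), ]
  b <- b[match(common, b$cell_id), ]
  ok <- !a$unassignable & !b$unassignable
  rate <- if (any(ok)) mean(a$best_type[ok] == b$best_type[ok]) else NA_real_
  list(rate = rate,
       confusion = table(a = a$best_type[ok], b = b$best_type[ok]))
}

#' SNN-graph Louvain clustering
#'
#' PCA on the HVG log-expression, a k-nearest-neighbour graph on the
#' principal components (Euclidean), shared-nearest-neighbour edge weights
#' `|shared| / (2k - |shared|)`, and a modularity-maximizing Louvain
#' partition. Louvain's node-order dependence is fixed by shuffling the
#' vertex order once from `seed`. Cluster labels are `0..C-1` in
#' decreasing cluster size.
#'
#' @param sce SingleCellExperiment with `logcounts` (or a matrix).
#' @param nPcs number of principal components.
#' @param k neighbours per cell.
#' @param seed integer seed.
#' @param hvgs optional gene subset (default: all genes).
#' @return Integer vector of cluster labels named by cell id, with the
#'   partition modularity in `attr(, "modularity")`.
#' @export
snnLouvain <- function(sce, nPcs = 50, k = 10, seed = 1L, hvgs = NULL) {
  x <- .logcounts(sce)
  if (!is.null(hvgs)) x <- x[intersect(hvgs, rownames(x)), , drop = FALSE]
  n <- ncol(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  nPcs <- min(nPcs, n - 1L, nrow(x))
  pc <- prcomp(t(x), rank. = nPcs)$x
  d <- as.matrix(dist(pc))
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    nb[i, ] <- setdiff(ord, i)[seq_len(k)]
  }
  B <- matrix(0L, n, n)
  B[cbind(rep(seq_len(n), each = k), as.vector(t(nb)))] <- 1L
  shared <- tcrossprod(B)
  w <- shared / (2 * k - shared)
  adj <- ((B + t(B)) > 0) * w
  diag(adj) <- 0
  perm <- .withSeed(seed, sample.int(n))
  g <- igraph::graph_from_adjacency_matrix(adj[perm, perm],
                                           mode = "undirected",
                                           weighted = TRUE)
  cl <- .withSeed(seed + 1L, igraph::cluster_louvain(g))
  memb <- integer(n)
  memb[perm] <- igraph::membership(cl)
  sizes <- table(memb)
  rank <- order(-as.integer(sizes),
                vapply(names(sizes), function(m)
                  min(which(memb == as.integer(m))), 0L))
  relabel <- setNames(seq_along(rank) - 1L, names(sizes)[rank])
  out <- relabel[as.character(memb)]
  names(out) <- colnames(x)
  attr(out, "modularity") <- igraph::modularity(cl)
  out
}

#' Subtype composition per condition
#'
#' @param assign a `DataFrame` from [labelTransfer()] (or any table with
#'   `cell_id` and `best_type`), or a plain character vector of types.
#' @param cells per-cell metadata (colData or data.frame) with a
#'   `condition` column, aligned to the assignment cells.
#' @return data.frame with `condition`, `type`, `n`, `proportion`;
#'   proportions sum to 1 within each condition.
#' @export
compositionTable <- function(assign, cells) {
  types <- if (is.character(assign)) assign else assign$best_type
  cells <- as.data.frame(cells)
  if (!"condition" %in% names(cells))
    stop("condition labels missing from cell metadata")
  if (length(types) != nrow(cells))
    stop("assignment and metadata cover different cell sets")
  conds <- unique(cells$condition)
  if (any(is.na(conds)) || any(!nzchar(conds))) stop("empty condition label")
  tab <- as.data.frame(table(condition = cells$condition, type = types),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  tot <- tapply(tab$n, tab$condition, sum)
  if (any(tot == 0)) stop("empty condition: ",
                          paste(names(tot)[tot == 0], collapse = ", "))
  tab$proportion <- as.numeric(tab$n / tot[tab$condition])
  tab[order(tab$condition, tab$type), c("condition", "type", "n",
                                        "proportion")]
}
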