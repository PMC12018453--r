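# Quality control, species assignment and normalization. Boundary
# semantics follow the filtering rules literally: "fewer than X" removes
# strictly below X (a cell at exactly X is kept) and "more than Y" removes
# strictly above Y.

#' QC thresholds for plate- and droplet-based data
#'
#' Defaults are the pipeline's standard cutoffs: plate cells need at least
#' 50,000 mapped reads, 4,000 detected genes (count > 0) and at most 20%
#' mitochondrial reads; droplet cells need at least 1,000 UMIs, 500
#' detected genes and at most 10% mitochondrial counts.
#'
#' @param minMappedReads,minDetectedGenes,maxMitoFraction plate thresholds.
#' @param minUmis,minGenes10x,maxMito10x droplet thresholds.
#' @return A validated list of class `QCThresholds`.
#' @export
qcThresholds <- function(minMappedReads = 50000, minDetectedGenes = 4000,
                         maxMitoFraction = 0.20, minUmis = 1000,
                         minGenes10x = 500, maxMito10x = 0.10) {
  t <- list(minMappedReads = minMappedReads,
            minDetectedGenes = minDetectedGenes,
            maxMitoFraction = maxMitoFraction,
            minUmis = minUmis, minGenes10x = minGenes10x,
            maxMito10x = maxMito10x)
  if (any(unlist(t) <= 0)) stop("all QC thresholds must be positive")
  if (maxMitoFraction > 1 || maxMito10x > 1)
    stop("mitochondrial fractions must be in (0, 1]")
  class(t) <- "QCThresholds"
  t
}

.qcApply <- function(sce, fails, ruleNames) {
  keep <- !Reduce(`|`, fails)
  report <- data.frame(rule = c(ruleNames, "any"),
                       n_removed = c(vapply(fails, sum, 0L),
                                     sum(!keep)))
  attr(report, "n_input") <- ncol(sce)
  attr(report, "n_kept") <- sum(keep)
  list(sce = sce[, keep], report = report)
}

#' Plate-based (Smart-seq-like) cell QC
#'
#' Removes cells with fewer than `minMappedReads` mapped reads, fewer than
#' `minDetectedGenes` genes with count > 0, or a mitochondrial read
#' fraction (from the `mito_reads` / `mapped_reads` metadata columns)
#' above `maxMitoFraction`. The three predicates are independent, so the
#' filter is idempotent and order-free; the report tallies removals per
#' rule (a cell can count against several).
#'
#' @param sce SingleCellExperiment with `counts` and colData columns
#'   `mapped_reads` and `mito_reads`.
#' @param thresholds a [qcThresholds()].
#' @return list with `sce` (surviving cells) and `report` (per-rule
#'   removal counts; attributes `n_input`, `n_kept`).
#' @export
qcFilterPlate <- function(sce, thresholds = qcThresholds()) {
  cd <- SummarizedExperiment::colData(sce)
  for (col in c("mapped_reads", "mito_reads"))
    if (!col %in% names(cd)) stop("missing metadata column: ", col)
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (ncol(sce) == 0L)
    return(.qcApply(sce, list(logical(0), logical(0), logical(0)),
                    c("mapped_reads", "detected_genes", "mito_fraction")))
  detected <- Matrix::colSums(counts > 0)
  mitoFrac <- cd$mito_reads / cd$mapped_reads
  fails <- list(cd$mapped_reads < thresholds$minMappedReads,
                detected < thresholds$minDetectedGenes,
                mitoFrac > thresholds$maxMitoFraction)
  .qcApply(sce, fails, c("mapped_reads", "detected_genes", "mito_fraction"))
}

#' Droplet-based (10X-like) cell QC
#'
#' Removes cells with fewer than `minUmis` total counts, fewer than
#' `minGenes10x` detected genes, or more than `maxMito10x` of their counts
#' on mitochondrial-flagged genes (rowData `is_mito`, or gene ids matching
#' the `mt-` prefix after any species tag).
#'
#' @inheritParams qcFilterPlate
#' @return list with `sce` and `report` as in [qcFilterPlate()].
#' @export
qcFilterDroplet <- function(sce, thresholds = qcThresholds()) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  isMito <- if ("is_mito" %in% names(rd)) rd$is_mito
            else grepl("^([a-z]+:)?mt-", rownames(sce), ignore.case = TRUE)
  if (ncol(sce) == 0L)
    return(.qcApply(sce, list(logical(0), logical(0), logical(0)),
                    c("umis", "detected_genes", "mito_fraction")))
  umis <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mitoFrac <- Matrix::colSums(counts[isMito, , drop = FALSE]) / pmax(umis, 1)
  fails <- list(umis < thresholds$minUmis,
                detected < thresholds$minGenes10x,
                mitoFrac > thresholds$maxMito10x)
  .qcApply(sce, fails, c("umis", "detected_genes", "mito_fraction"))
}

#' Per-cell species assignment from species-tagged genes
#'
#' Labels each cell with the species contributing a strict majority
#' (> 50%) of its counts; cells with no majority (including exact ties)
#' are labelled `"ambiguous"`.
#'
#' @param sce SingleCellExperiment whose rowData has a `species` column.
#' @return Character vector of per-cell labels, named by cell id.
#' @export
assignSpecies <- function(sce) {
  rd <- SummarizedExperiment::rowData(sce)
  if (!"species" %in% names(rd) || all(is.na(rd$species)))
    stop("no species tags present in rowData")
  counts <- SummarizedExperiment::assay(sce, "counts")
  sp <- factor(rd$species)
  bySp <- vapply(levels(sp), function(s)
    Matrix::colSums(counts[sp == s, , drop = FALSE]), numeric(ncol(counts)))
  if (ncol(counts) == 1L) bySp <- matrix(bySp, nrow = 1,
                                         dimnames = list(NULL, levels(sp)))
  tot <- rowSums(bySp)
  frac <- bySp / pmax(tot, 1)
  best <- max.col(frac, ties.method = "first")
  lab <- ifelse(frac[cbind(seq_along(best), best)] > 0.5,
                levels(sp)[best], "ambiguous")
  setNames(lab, colnames(counts))
}

.sizeFactorsMatrix <- function(counts, method = c("median_ratio",
                                                  "library_size")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("all-zero cell: size factors undefined")
  if (method == "library_size") {
    sf <- totals
  } else {
    allPos <- rowSums(counts == 0) == 0
    if (any(allPos)) {
      logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
      sub <- counts[allPos, , drop = FALSE]
      sf <- apply(sub, 2, function(x) median(exp(log(x) - logRef)))
    } else {
      # no gene observed in every cell: geometric mean over positive
      # observations only, median of ratios over each cell's positive genes
      logRef <- apply(counts, 1, function(x) {
        x <- x[x > 0]
        if (length(x)) mean(log(x)) else NA_real_
      })
      sf <- apply(counts, 2, function(x) {
        ok <- x > 0 & !is.na(logRef)
        if (!any(ok)) stop("cell shares no expressed gene with reference")
        median(exp(log(x[ok]) - logRef[ok]))
      })
    }
  }
  sf / exp(mean(log(sf)))
}

#' Per-cell size factors
#'
#' `median_ratio` (default) divides each cell by the gene-wise geometric
#' mean reference and takes the median ratio, falling back to
#' positive-observation references when no gene is expressed in every
#' cell; `library_size` uses total counts. Either way factors are rescaled
#' to geometric mean 1.
#'
#' @param x SingleCellExperiment (counts assay) or a counts matrix.
#' @param method `"median_ratio"` or `"library_size"`.
#' @return Positive numeric vector, one factor per cell.
#' @export
computeSizeFactors <- function(x, method = c("median_ratio",
                                             "library_size")) {
  counts <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  sf <- .sizeFactorsMatrix(counts, method)
  setNames(sf, colnames(counts))
}

#' Size-factor normalization and log transformation
#'
#' Divides counts by per-cell size factors and applies
#' `log2(count / factor + 1)`. The pseudocount (1) and log base (2) are
#' recorded in the object metadata; `2^value - 1` recovers the normalized
#' count.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param factors per-cell positive factors aligned to cells; computed
#'   with [computeSizeFactors()] when `NULL`.
#' @param method passed to [computeSizeFactors()] when `factors` is NULL.
#' @return The input with an added `logcounts` assay, `sizeFactors()` set,
#'   and `metadata(sce)$normalization` recording pseudocount and base.
#' @export
logNormalize <- function(sce, factors = NULL,
                         method = c("median_ratio", "library_size")) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (is.null(factors)) factors <- .sizeFactorsMatrix(counts, method)
  if (length(factors) != ncol(counts))
    stop("size factors misaligned: ", length(factors), " factors for ",
         ncol(counts), " cells")
  if (any(factors <= 0)) stop("size factors must be positive")
  logc <- log2(sweep(as.matrix(counts), 2, factors, "/") + 1)
  SummarizedExperiment::assay(sce, "logcounts") <- logc
  SingleCellExperiment::sizeFactors(sce) <- factors
  S4Vectors::metadata(sce)$normalization <-
    list(pseudocount = 1, logBase = 2)
  sce
}
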