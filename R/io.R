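# Readers and writers for the on-disk formats the pipeline exchanges:
# Matrix-Market count triplets with aligned gene/cell annotation TSVs,
# dense TSV counts, reference atlases as genes x types TSVs, and gene
# signatures as GMT.

#' Write a count matrix with gene and cell annotation
#'
#' Emits either `matrix.mtx` (1-based Matrix-Market coordinate format) or
#' `counts.tsv` (dense, gene rows) plus `genes.tsv` and `cells.tsv` into
#' `dir`. Files round-trip through [readCounts()] exactly.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return Invisibly, the directory.
#' @export
writeCounts <- function(sce, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (format == "mtx") {
    m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  } else {
    df <- as.data.frame(as.matrix(counts))
    write.table(cbind(gene_id = rownames(counts), df),
                file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(as.data.frame(SummarizedExperiment::rowData(sce)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(SummarizedExperiment::colData(sce)),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix with gene and cell annotation
#'
#' Reads the layout written by [writeCounts()]. Matrix-Market indices are
#' 1-based on disk; dimensions are checked against the annotation tables
#' and ids are required to be unique.
#'
#' @param dir directory containing `matrix.mtx` or `counts.tsv`, plus
#'   `genes.tsv` and `cells.tsv`.
#' @param format `"mtx"` or `"tsv"`.
#' @return A [SingleCellExperiment::SingleCellExperiment].
#' @export
readCounts <- function(dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  gpath <- file.path(dir, "genes.tsv")
  cpath <- file.path(dir, "cells.tsv")
  for (p in c(gpath, cpath))
    if (!file.exists(p)) stop("missing annotation file: ", p)
  genes <- read.delim(gpath, stringsAsFactors = FALSE)
  cellsTab <- read.delim(cpath, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes))
    stop("malformed header: genes.tsv lacks a gene_id column")
  if (!"cell_id" %in% names(cellsTab))
    stop("malformed header: cells.tsv lacks a cell_id column")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate ids: gene_id values are not unique")
  if (anyDuplicated(cellsTab$cell_id))
    stop("duplicate ids: cell_id values are not unique")
  if (format == "mtx") {
    mpath <- file.path(dir, "matrix.mtx")
    if (!file.exists(mpath)) stop("missing matrix file: ", mpath)
    m <- tryCatch(Matrix::readMM(mpath),
                  error = function(e) stop("malformed header or entries in ",
                                           mpath, ": ", conditionMessage(e)))
    if (nrow(m) != nrow(genes) || ncol(m) != nrow(cellsTab))
      stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but annotations describe ", nrow(genes), " genes and ",
           nrow(cellsTab), " cells")
    counts <- as.matrix(m)
  } else {
    tpath <- file.path(dir, "counts.tsv")
    if (!file.exists(tpath)) stop("missing matrix file: ", tpath)
    tab <- read.delim(tpath, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1] != "gene_id")
      stop("malformed header: counts.tsv must start with gene_id")
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$gene_id
    if (nrow(counts) != nrow(genes) || ncol(counts) != nrow(cellsTab))
      stop("dimension mismatch between counts.tsv and annotation tables")
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, cellsTab$cell_id)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(cellsTab, row.names = cellsTab$cell_id))
}

#' Write a reference atlas as a genes x types TSV
#'
#' @param atlas a [ReferenceAtlas-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeAtlas <- function(atlas, path) {
  p <- atlasProfiles(atlas)
  df <- cbind(gene_id = rownames(p), as.data.frame(p, check.names = FALSE))
  hdr <- paste0("# supertype: ",
                paste(names(atlasSuperTypes(atlas)), atlasSuperTypes(atlas),
                      sep = "=", collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference atlas written by [writeAtlas()]
#'
#' @param path TSV path (header row of type labels; optional `# supertype:`
#'   comment line).
#' @return A [ReferenceAtlas-class].
#' @export
readAtlas <- function(path) {
  first <- readLines(path, n = 1L)
  super <- NULL
  if (startsWith(first, "# supertype:")) {
    spec <- strsplit(sub("^# supertype: *", "", first), ",")[[1]]
    kv <- strsplit(spec, "=")
    super <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  prof <- as.matrix(tab[, -1, drop = FALSE])
  rownames(prof) <- tab[[1]]
  ReferenceAtlas(prof, superType = super, note = path)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated genes.
#'
#' @param sets named list of character vectors, or a
#'   [PCNSignature-class] (written as `<name>_up` / `<name>_down`).
#' @param path output path.
#' @param description description field (recycled).
#' @return Invisibly, the path.
#' @export
writeGMT <- function(sets, path, description = "") {
  if (methods::is(sets, "PCNSignature")) {
    sets <- setNames(list(sets@up, sets@down),
                     paste0(sets@name, c("_up", "_down")))
  }
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of character gene vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}
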