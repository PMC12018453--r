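# Neuron-microenvironment interaction potentials. For ligands/receptors
# expressed by the innervating neurons, the cognate partner genes are
# scored in the microenvironment: per-gene z-scores of mean log expression
# across receiver cell types, averaged over cognate genes and shifted so
# the minimum over the comparison frame (all receiver types x both
# conditions) is exactly zero. Pair-level products of neuron-side
# expression and z-scored receiver expression rank the most-changed
# ligand-receptor interactions between conditions.

#' Ligands and receptors expressed by neuronal subpopulations
#'
#' A gene counts as expressed in a subpopulation when the log of its
#' aggregate counts over the subpopulation's cells (plus a pseudocount of
#' 1) exceeds `threshold`; the default convention is log10 with
#' threshold 2, i.e. aggregate counts above ~100.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param subpops per-cell subpopulation (or sender-group) labels.
#' @param lr ligand-receptor table with columns `ligand` and `receptor`.
#' @param threshold expression cutoff on the log aggregate.
#' @param logBase base of the log (10 by default; `exp(1)` for natural
#'   log).
#' @return Named list per subpopulation: `list(ligands =, receptors =)`,
#'   restricted to genes present in `lr`.
#' @export
expressedLR <- function(sce, subpops, lr, threshold = 2, logBase = 10) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  subpops <- as.character(subpops)
  if (length(subpops) != ncol(counts))
    stop("subpopulation labels must cover every cell")
  out <- list()
  for (s in unique(subpops)) {
    cells <- subpops == s
    if (!any(cells)) stop("empty subpopulation: ", s)
    agg <- Matrix::rowSums(counts[, cells, drop = FALSE])
    expressed <- rownames(counts)[log(agg + 1, base = logBase) > threshold]
    out[[s]] <- list(ligands = intersect(unique(lr$ligand), expressed),
                     receptors = intersect(unique(lr$receptor), expressed))
  }
  out
}

.cognatesOf <- function(expr, lr) {
  unique(c(lr$receptor[lr$ligand %in% expr$ligands],
           lr$ligand[lr$receptor %in% expr$receptors]))
}

.zAcross <- function(M) {
  # z-score each row of a genes x types matrix with population sd;
  # zero-variance rows contribute 0
  mu <- rowMeans(M)
  sdp <- sqrt(rowMeans((M - mu)^2))
  z <- (M - mu) / ifelse(sdp > 0, sdp, 1)
  z[sdp == 0, ] <- 0
  z
}

#' Interaction potential of microenvironment cell types with neurons
#'
#' For each sender neuron group and each replicate of the
#' microenvironment data: mean log expression of every cognate gene (the
#' partner of a neuron-expressed ligand or receptor) per receiver cell
#' type, z-scored per gene across the receiver types (population sd;
#' zero-variance genes contribute 0), averaged over cognate genes, and
#' min-subtracted over the whole comparison frame (all receiver types and
#' replicates of both conditions for that sender) so potentials are
#' non-negative with minimum exactly 0 and healthy/tumour values share a
#' scale.
#'
#' @param tme SingleCellExperiment of the microenvironment with
#'   `logcounts` and colData columns `cell_type`, `replicate`,
#'   `condition`.
#' @param neuronExpressed named list per sender group from
#'   [expressedLR()].
#' @param lr ligand-receptor table.
#' @return data.frame with `sender`, `condition`, `replicate`,
#'   `receiver`, `raw` (mean z) and `potential`; the number of cognate
#'   genes absent from the matrix per sender is in
#'   `attr(, "droppedGenes")`.
#' @export
interactionPotential <- function(tme, neuronExpressed, lr) {
  x <- .logcounts(tme)
  cd <- SummarizedExperiment::colData(tme)
  for (col in c("cell_type", "replicate", "condition"))
    if (!col %in% names(cd)) stop("missing metadata column: ", col)
  types <- sort(unique(cd$cell_type))
  if (length(types) < 2)
    stop("need at least 2 receiver cell types for z-scoring")
  reps <- unique(as.data.frame(cd[, c("replicate", "condition")]))
  dropped <- integer()
  out <- list()
  for (sender in names(neuronExpressed)) {
    cog <- .cognatesOf(neuronExpressed[[sender]], lr)
    if (!length(cog)) stop("cognate set empty for sender ", sender)
    present <- intersect(cog, rownames(x))
    dropped[sender] <- length(cog) - length(present)
    if (!length(present)) stop("no cognate gene present for ", sender)
    for (i in seq_len(nrow(reps))) {
      r <- reps$replicate[i]
      inRep <- cd$replicate == r
      M <- vapply(types, function(t) {
        cells <- inRep & cd$cell_type == t
        if (!any(cells)) return(rep(NA_real_, length(present)))
        rowMeans(x[present, cells, drop = FALSE])
      }, numeric(length(present)))
      M <- matrix(M, nrow = length(present),
                  dimnames = list(present, types))
      okType <- colSums(is.na(M)) == 0
      z <- .zAcross(M[, okType, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        sender = sender, condition = reps$condition[i], replicate = r,
        receiver = colnames(z), raw = colMeans(z),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  res$potential <- NA_real_
  for (sender in unique(res$sender)) {
    sel <- res$sender == sender
    res$potential[sel] <- res$raw[sel] - min(res$raw[sel])
  }
  attr(res, "droppedGenes") <- dropped
  res
}

#' Most-changed ligand-receptor pairs between conditions
#'
#' Per sender neuron group, condition and receiver type, each pair is
#' scored as the product of the neuron-side mean log expression of its
#' ligand or receptor (whichever the sender expresses; both orientations
#' are scored when both are expressed) and the z-scored receiver-type mean
#' of the cognate gene (z across receiver types within condition, cells
#' pooled over replicates). Pairs with neither side expressed by the
#' sender are excluded. The delta is tumour minus healthy; the top `topK`
#' pairs by |delta| are returned per sender.
#'
#' @param neurons SingleCellExperiment of neurons with `logcounts` and
#'   colData columns `condition` plus the sender grouping column.
#' @param tme SingleCellExperiment of the microenvironment with
#'   `logcounts` and colData `cell_type`, `condition`.
#' @param lr ligand-receptor table (`pair_id`, `ligand`, `receptor`).
#' @param neuronExpressed named list per sender group from
#'   [expressedLR()].
#' @param senderCol colData column of `neurons` holding the sender group
#'   (default `"ganglion"`).
#' @param topK pairs returned per sender (default 10).
#' @param conditions length-2 character `c(tumour, healthy)`.
#' @return data.frame with `sender`, `pair_id`, `ligand`, `receptor`,
#'   `orientation`, `receiver`, `score_healthy`, `score_tumour`, `delta`,
#'   ranked by |delta| within sender and truncated to `topK`.
#' @export
differentialPairs <- function(neurons, tme, lr, neuronExpressed,
                              senderCol = "ganglion", topK = 10,
                              conditions = c("tumour", "healthy")) {
  nx <- .logcounts(neurons)
  ncd <- SummarizedExperiment::colData(neurons)
  if (!senderCol %in% names(ncd)) stop("missing sender column: ", senderCol)
  if (!all(conditions %in% ncd$condition) ||
      !all(conditions %in% SummarizedExperiment::colData(tme)$condition))
    stop("both conditions must be present in both datasets")
  tx <- .logcounts(tme)
  tcd <- SummarizedExperiment::colData(tme)
  types <- sort(unique(tcd$cell_type))

  # z-scored receiver-type means per condition
  zByCond <- lapply(setNames(conditions, conditions), function(cond) {
    M <- vapply(types, function(t)
      rowMeans(tx[, tcd$cell_type == t & tcd$condition == cond,
                  drop = FALSE]),
      numeric(nrow(tx)))
    .zAcross(matrix(M, nrow = nrow(tx), dimnames = list(rownames(tx),
                                                        types)))
  })

  rows <- list()
  for (sender in names(neuronExpressed)) {
    expr <- neuronExpressed[[sender]]
    nMean <- vapply(setNames(conditions, conditions), function(cond)
      rowMeans(nx[, ncd[[senderCol]] == sender & ncd$condition == cond,
                  drop = FALSE]),
      numeric(nrow(nx)))
    for (i in seq_len(nrow(lr))) {
      orient <- c(if (lr$ligand[i] %in% expr$ligands) "neuron_ligand",
                  if (lr$receptor[i] %in% expr$receptors) "neuron_receptor")
      for (o in orient) {
        nGene <- if (o == "neuron_ligand") lr$ligand[i] else lr$receptor[i]
        tGene <- if (o == "neuron_ligand") lr$receptor[i] else lr$ligand[i]
        if (!nGene %in% rownames(nx) || !tGene %in% rownames(tx)) next
        for (t in types) {
          sT <- nMean[nGene, conditions[1]] *
                zByCond[[conditions[1]]][tGene, t]
          sH <- nMean[nGene, conditions[2]] *
                zByCond[[conditions[2]]][tGene, t]
          rows[[length(rows) + 1L]] <- data.frame(
            sender = sender, pair_id = lr$pair_id[i],
            ligand = lr$ligand[i], receptor = lr$receptor[i],
            orientation = o, receiver = t,
            score_healthy = sH, score_tumour = sT, delta = sT - sH,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(sender = character(), pair_id = character(),
                      ligand = character(), receptor = character(),
                      orientation = character(), receiver = character(),
                      score_healthy = numeric(), score_tumour = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  out <- lapply(split(res, res$sender), function(d) {
    d <- d[order(-abs(d$delta), d$pair_id, d$receiver), ]
    utils::head(d, topK)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
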