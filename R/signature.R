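# Consensus up/down signature construction from per-subpopulation
# differential expression, following the membership rules: top-N genes per
# direction per subpopulation, exclusion of weakly expressed
# (mean < threshold) or unreliable (padj > threshold) genes, inclusion at
# >= k contributing subpopulations (k differs by direction), and removal
# of genes supported only by sympathetic (CG-super-type) subpopulations.

#' Signature construction parameters
#'
#' Defaults mirror the consensus rules the pipeline is built around: top
#' 500 genes per direction, mean expression below 500 excluded, padj above
#' 0.2 excluded, down-genes need support from 3 or more subpopulations and
#' up-genes from 2 or more, and genes supported only by CG subpopulations
#' are excluded.
#'
#' @param topN candidates kept per direction before filtering.
#' @param minMeanExpression minimum per-population mean normalized
#'   expression; strictly smaller values are excluded.
#' @param maxPadj maximum BH-adjusted p; strictly larger values are
#'   excluded.
#' @param kDown,kUp minimum number of contributing subpopulations.
#' @param cgOnlyExcluded drop genes whose contributing subpopulations are
#'   all of the CG super-type.
#' @return A validated list of class `SignatureParams`.
#' @export
signatureParams <- function(topN = 500, minMeanExpression = 500,
                            maxPadj = 0.2, kDown = 3, kUp = 2,
                            cgOnlyExcluded = TRUE) {
  p <- list(topN = as.integer(topN),
            minMeanExpression = minMeanExpression,
            maxPadj = maxPadj, kDown = as.integer(kDown),
            kUp = as.integer(kUp), cgOnlyExcluded = cgOnlyExcluded)
  if (p$topN < 1) stop("topN must be >= 1")
  if (p$minMeanExpression <= 0 || p$maxPadj <= 0)
    stop("thresholds must be positive")
  if (p$kDown < 1 || p$kUp < 1) stop("k values must be >= 1")
  class(p) <- "SignatureParams"
  p
}

#' Per-subpopulation candidate gene lists
#'
#' Ranks the population's genes by Wald statistic (descending for the up
#' list, ascending for the down list), truncates each list to `topN`, and
#' then removes genes whose mean expression in this population is below
#' `minMeanExpression` or whose adjusted p exceeds `maxPadj`
#' (truncate-then-filter).
#'
#' @param de a `DataFrame` from [nbWaldTest()] for one subpopulation.
#' @param means named per-gene mean normalized expression in this
#'   population (both conditions pooled).
#' @param params a [signatureParams()].
#' @return list with character vectors `up` and `down`.
#' @export
perPopulationCandidates <- function(de, means, params = signatureParams()) {
  if (is.null(means) || is.null(names(means)))
    stop("missing named mean-expression table")
  ok <- !is.na(de$stat)
  de <- de[ok, ]
  genes <- de$gene
  pass <- function(g) {
    m <- means[g]
    pa <- de$padj[match(g, genes)]
    g[!is.na(m) & m >= params$minMeanExpression &
      !is.na(pa) & pa <= params$maxPadj]
  }
  upTop <- genes[order(-de$stat, genes)][seq_len(min(params$topN,
                                                     length(genes)))]
  dnTop <- genes[order(de$stat, genes)][seq_len(min(params$topN,
                                                    length(genes)))]
  list(up = pass(upTop), down = pass(dnTop))
}

#' Build a consensus signature across subpopulations
#'
#' Down-genes must appear in the down lists of at least `kDown`
#' subpopulations and up-genes in the up lists of at least `kUp`; genes
#' whose contributing subpopulations are all of the CG super-type are then
#' removed (when `cgOnlyExcluded`). A gene qualifying in both directions
#' is dropped from both sets and recorded as a conflict, keeping the sets
#' disjoint. Output is invariant to the order populations are supplied in.
#'
#' @param candidates named list (one entry per subpopulation) of
#'   [perPopulationCandidates()] results.
#' @param popSuperTypes named character vector mapping each subpopulation
#'   to its super-type (`"CG"` or `"DRG"`).
#' @param params a [signatureParams()].
#' @param name signature name.
#' @return A [PCNSignature-class].
#' @export
buildConsensus <- function(candidates, popSuperTypes,
                           params = signatureParams(), name = "PCN") {
  pops <- sort(names(candidates))
  unknown <- setdiff(pops, names(popSuperTypes))
  if (length(unknown))
    stop("unknown population label: ", paste(unknown, collapse = ", "))
  gather <- function(direction, k) {
    support <- list()
    for (p in pops)
      for (g in candidates[[p]][[direction]])
        support[[g]] <- c(support[[g]], p)
    if (!length(support))
      return(list(genes = character(), support = list()))
    keep <- names(support)[vapply(support, length, 0L) >= k]
    if (params$cgOnlyExcluded && length(keep))
      keep <- keep[vapply(keep, function(g)
        any(popSuperTypes[support[[g]]] != "CG"), logical(1))]
    keep <- as.character(sort(keep))
    list(genes = keep, support = support[keep])
  }
  up <- gather("up", params$kUp)
  dn <- gather("down", params$kDown)
  conflicts <- intersect(up$genes, dn$genes)
  upGenes <- setdiff(up$genes, conflicts)
  dnGenes <- setdiff(dn$genes, conflicts)
  prov <- rbind(
    if (length(upGenes)) data.frame(
      gene = upGenes, direction = "up",
      populations = vapply(up$support[upGenes], paste, "", collapse = ","),
      stringsAsFactors = FALSE),
    if (length(dnGenes)) data.frame(
      gene = dnGenes, direction = "down",
      populations = vapply(dn$support[dnGenes], paste, "", collapse = ","),
      stringsAsFactors = FALSE))
  if (is.null(prov))
    prov <- data.frame(gene = character(), direction = character(),
                       populations = character(), stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  new("PCNSignature", name = name, up = upGenes, down = dnGenes,
      provenance = prov, conflicts = conflicts,
      params = unclass(params))
}
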