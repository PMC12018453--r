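# Weighted Kolmogorov-Smirnov gene-set enrichment on a ranked gene list:
# hits advance the running sum proportionally to |score|^p (normalized to
# 1 over the set), misses retreat by 1/(N - |set|), and the enrichment
# score is the signed maximum deviation. Significance comes from a
# gene-set permutation null (random same-size sets), the appropriate null
# at pseudobulk replicate numbers where phenotype permutation degenerates.

#' Rank genes by a differential-expression statistic
#'
#' @param de a `DataFrame` from [nbWaldTest()] / [wilcoxonDE()], or any
#'   table with `gene` and the ranking column.
#' @param by ranking column (default the Wald statistic).
#' @return data.frame with `gene` and `score`, descending by score; exact
#'   ties break lexicographically by gene id.
#' @export
rankGenes <- function(de, by = "stat") {
  ok <- !is.na(de[[by]])
  if (!any(ok)) stop("empty differential-expression result")
  genes <- de$gene[ok]
  score <- de[[by]][ok]
  if (anyDuplicated(genes)) stop("duplicate genes in ranking")
  ord <- order(-score, genes)
  data.frame(gene = genes[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' @param ranked data.frame from [rankGenes()].
#' @param set character vector of gene ids; members absent from the
#'   ranking are ignored (their number is reported).
#' @param p hit-increment weight exponent (1 = classic weighted statistic,
#'   0 = unweighted Kolmogorov-Smirnov).
#' @return list with `ES` (signed maximum deviation, in `[-1, 1]`),
#'   `runningSum` (length `N`), `peak` (its position) and `nAbsent`.
#' @export
enrichmentScore <- function(ranked, set, p = 1) {
  hit <- ranked$gene %in% set
  nAbsent <- length(setdiff(set, ranked$gene))
  if (!any(hit)) stop("empty intersection between set and ranking")
  N <- nrow(ranked)
  nh <- sum(hit)
  w <- abs(ranked$score)^p
  wh <- w[hit]
  inc <- if (sum(wh) > 0) wh / sum(wh) else rep(1 / nh, nh)
  dec <- if (N > nh) 1 / (N - nh) else 0
  steps <- rep(-dec, N)
  steps[hit] <- inc
  rs <- cumsum(steps)
  hi <- max(rs)
  lo <- min(rs)
  # signed maximum deviation; the positive extreme wins a tie (ties are
  # compared with a small epsilon so float summation order cannot flip
  # the sign of an exactly balanced excursion)
  es <- if (hi + lo >= -1e-12) hi else lo
  peak <- which(rs == es)[1]
  list(ES = es, runningSum = rs, peak = peak, nAbsent = nAbsent)
}

# ES from sorted hit positions only (same statistic, O(set) per
# evaluation) - used for the permutation null.
.esFromPositions <- function(pos, w, N) {
  pos <- sort(pos)
  nh <- length(pos)
  wh <- w[pos]
  inc <- if (sum(wh) > 0) cumsum(wh) / sum(wh) else seq_len(nh) / nh
  dec <- if (N > nh) 1 / (N - nh) else 0
  missesBefore <- pos - seq_len(nh)
  after <- inc - missesBefore * dec          # running sum just after hit i
  before <- c(0, inc[-nh]) - missesBefore * dec  # just before hit i
  hi <- max(after)
  lo <- min(before)
  if (hi + lo >= -1e-12) hi else lo
}

#' Gene-set permutation test for enrichment
#'
#' Builds the null distribution of the enrichment score from random gene
#' sets of matching size drawn from the ranking, normalizes the observed
#' score by the mean magnitude of sign-matching null scores (NES), and
#' reports `p = (1 + #more extreme, same sign) / (1 + #same sign)` with
#' Benjamini-Hochberg correction across the tested sets.
#'
#' @param ranked data.frame from [rankGenes()].
#' @param sets named list of gene sets.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @param p weight exponent passed to the score.
#' @return data.frame per set: `set`, `size`, `n_absent`, `ES`, `NES`,
#'   `pval`, `qval`, `leading_edge` (comma-separated), `n_perm`, `seed`.
#' @export
permutationTest <- function(ranked, sets, nPerm = 1000, seed = 1L, p = 1) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  N <- nrow(ranked)
  w <- abs(ranked$score)^p
  rows <- lapply(names(sets), function(nm) {
    if (length(sets[[nm]]) > N) stop("set larger than ranking")
    inSet <- intersect(sets[[nm]], ranked$gene)
    es <- enrichmentScore(ranked, inSet, p)
    size <- sum(ranked$gene %in% inSet)
    null <- .withSeed(seed + utils::head(which(names(sets) == nm), 1), {
      vapply(seq_len(nPerm), function(i)
        .esFromPositions(sample.int(N, size), w, N), numeric(1))
    })
    same <- null[sign(null) == sign(es$ES)]
    pval <- (1 + sum(abs(same) >= abs(es$ES))) / (1 + length(same))
    nes <- if (length(same)) es$ES / mean(abs(same)) else NA_real_
    hitIdx <- which(ranked$gene %in% inSet)
    le <- if (es$ES >= 0) ranked$gene[hitIdx[hitIdx <= es$peak]]
          else ranked$gene[hitIdx[hitIdx >= es$peak]]
    data.frame(set = nm, size = size,
               n_absent = length(setdiff(sets[[nm]], ranked$gene)),
               ES = es$ES, NES = nes, pval = pval,
               leading_edge = paste(le, collapse = ","),
               n_perm = nPerm, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- p.adjust(out$pval, "BH")
  out[, c("set", "size", "n_absent", "ES", "NES", "pval", "qval",
          "leading_edge", "n_perm", "seed")]
}
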