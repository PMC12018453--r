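# Independent oracles and shared simulation scenarios for the test suite.

library(SummarizedExperiment)
library(SingleCellExperiment)
library(S4Vectors)

# Naive running-sum enrichment oracle: an explicit position-by-position
# loop, independent of the package's vectorized implementations.
bruteES <- function(genes, scores, set, p = 1) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^p)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (wsum > 0) abs(scores[i])^p / wsum else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi + lo >= -1e-12) hi else lo
}

# Exact two-sided rank-sum p by enumeration over all group assignments.
enumWilcoxP <- function(x, y) {
  all <- c(x, y)
  n <- length(x)
  r <- rank(all)
  combos <- utils::combn(length(all), n)
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * length(y) / 2
  # two-sided: arrangements at least as extreme in either tail
  min(1, mean(abs(ws - mu) >= abs(wObs - mu)))
}

# Small plate experiment used across tests.
smallNeuronSim <- function(seed = 1, nGenes = 400, cells = 10, ...) {
  cfg <- simConfig(nGenes = nGenes, nCellsPerSubpopPerReplicate = cells,
                   markerGenesPerSubpop = 20, seed = seed, ...)
  generateNeuronExperiment(cfg)
}

# Toy SingleCellExperiment built from an explicit counts matrix.
toySCE <- function(counts, mappedReads = NULL, mitoReads = NULL,
                   species = NULL, isMito = NULL, condition = NULL,
                   replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  cd <- DataFrame(cell_id = colnames(counts), row.names = colnames(counts))
  if (!is.null(mappedReads)) cd$mapped_reads <- mappedReads
  if (!is.null(mitoReads)) cd$mito_reads <- mitoReads
  if (!is.null(condition)) cd$condition <- condition
  if (!is.null(replicate)) cd$replicate <- replicate
  rd <- DataFrame(gene_id = rownames(counts), row.names = rownames(counts))
  if (!is.null(species)) rd$species <- species
  if (!is.null(isMito)) rd$is_mito <- isMito
  SingleCellExperiment(assays = list(counts = counts), rowData = rd,
                       colData = cd)
}

# The tumour-CAF interactome scenario: a 16-pair ligand-receptor table in
# which ten ligands form a CAF secretory program planted 4-fold up in
# tumour CAFs; the focal pair (P001) has a robustly expressed neuron-side
# receptor and its receptor gene co-planted in CAFs.
interactomeScenario <- function(seed, nGenes = 2000) {
  cfg <- simConfig(nGenes = nGenes, seed = seed)
  b <- simBaselineMeans(cfg)
  reserved <- seq_len(cfg$nMitoGenes +
                      length(cfg$subpopNames) * cfg$markerGenesPerSubpop)
  pool <- names(b)[setdiff(order(-b), reserved)]
  lr <- data.frame(pair_id = sprintf("P%03d", 1:16),
                   ligand = pool[101 + 1:16],
                   receptor = c(pool[1], pool[121 + 1:15]),
                   stringsAsFactors = FALSE)
  planted <- rbind(
    data.frame(ligand = lr$ligand[1:10], receptor = lr$receptor[1:10],
               tme_side = "ligand", receiver = "CAF", condition = "tumour",
               log2fc = 2, stringsAsFactors = FALSE),
    data.frame(ligand = lr$ligand[1], receptor = lr$receptor[1],
               tme_side = "receptor", receiver = "CAF",
               condition = "tumour", log2fc = 2, stringsAsFactors = FALSE))
  list(cfg = cfg, lr = lr, planted = planted, focal = "P001")
}

# The consensus-signature recovery scenario: 30 genes planted down in
# three subpopulations, 12 up in two, 8 up only in the CG subpopulations
# (decoys), all on robustly expressed genes.
signatureScenario <- function(seed) {
  base <- list(nGenes = 2000, baselineMeanLog = log(300),
               depthMeanLog = log(2e6))
  probe <- do.call(simConfig, c(base, list(seed = seed)))
  b <- simBaselineMeans(probe)
  reserved <- seq_len(probe$nMitoGenes +
                      length(probe$subpopNames) * probe$markerGenesPerSubpop)
  elig <- setdiff(which(b >= 1500), reserved)
  down <- elig[1:30]; up <- elig[31:42]; decoy <- elig[43:50]
  sets <- list(
    list(genes = down, subpops = c("CG1", "NEFM", "PEP"), log2fc = -2),
    list(genes = up, subpops = c("NEFM", "PEP"), log2fc = 2),
    list(genes = decoy, subpops = c("CG1", "CG2"), log2fc = 2))
  cfg <- do.call(simConfig, c(base, list(deGeneSets = sets,
                                         fractionLowQuality = 0.1,
                                         seed = seed)))
  list(cfg = cfg, down = names(b)[down], up = names(b)[up],
       decoy = names(b)[decoy])
}

# Run per-population DE and consensus signature construction on a
# signatureScenario simulation, using ground-truth subpopulation labels.
buildScenarioSignature <- function(sc) {
  sim <- generateNeuronExperiment(sc$cfg)
  qc <- qcFilterPlate(sim$sce, qcThresholds(minDetectedGenes = 1000))
  nm <- logNormalize(qc$sce)
  pop <- sim$truth$cells$subpop[match(colnames(nm),
                                      sim$truth$cells$cell_id)]
  q <- sweep(as.matrix(assay(nm, "counts")), 2, sizeFactors(nm), "/")
  cands <- list()
  for (p in unique(pop)) {
    sub <- nm[, pop == p]
    de <- nbWaldTest(makePseudobulk(sub, c("replicate", "condition")))
    cands[[p]] <- perPopulationCandidates(de, rowMeans(q[, pop == p]),
                                          signatureParams())
  }
  super <- setNames(c("CG", "CG", "DRG", "DRG", "DRG"),
                    c("CG1", "CG2", "NEFM", "PEP", "NPEP"))
  buildConsensus(cands, super, signatureParams())
}
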