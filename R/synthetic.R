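# Seeded synthetic-data generators with recorded ground truth. These
# emulate the structure of the study designs the pipeline targets:
# plate-based (Smart-seq2-like) traced-neuron experiments with five major
# subpopulations over 2 healthy + 3 tumour replicates, and droplet-based
# (10X-like) tumour-microenvironment experiments with six cell types.
# Distributional choices are stand-ins for real data and are documented in
# the methods vignette.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so generators are seeded
#' deterministically without disturbing the session stream.
#' @noRd
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.ganglionOf <- function(subpop) {
  ifelse(startsWith(subpop, "CG"), "CG", "DRG")
}

#' Simulation configuration
#'
#' Defines the conditions of a synthetic traced-neuron experiment:
#' negative-binomial counts with a log-normal baseline-mean distribution
#' and a declining mean-dispersion trend, subpopulation marker genes,
#' optionally planted condition-specific differentially expressed gene
#' sets, per-cell sequencing depth and mitochondrial fraction, and an
#' exactly planted fraction of low-quality cells.
#'
#' Counts for gene g in cell c are NB with mean
#' `mu = baseline_g * 2^(marker and DE log2 fold changes) * depth_c / E[depth]`
#' (after per-cell reapportioning between mitochondrial and nuclear genes so
#' the cell's expected mitochondrial fraction equals its drawn fraction) and
#' variance `mu + alpha_g mu^2`. The default dispersion trend is
#' `alpha(m) = asymptote + extraPoisson / m` evaluated at the gene baseline.
#'
#' @param nGenes total genes, including `nMitoGenes` mitochondrial genes.
#' @param nMitoGenes number of `mt-`-prefixed mitochondrial genes.
#' @param nCellsPerSubpopPerReplicate cells simulated per subpopulation in
#'   each replicate.
#' @param subpopNames subpopulation labels; names starting `CG` are treated
#'   as celiac-ganglion (sympathetic) derived, the rest as DRG (sensory).
#' @param nReplicatesHealthy,nReplicatesTumour biological replicates per
#'   condition (defaults 2 and 3, the study design).
#' @param markerGenesPerSubpop,markerLog2fc marker genes elevated by
#'   `markerLog2fc` log2 units in their own subpopulation.
#' @param deGeneSets list of planted differential-expression sets, each a
#'   list with elements `genes` (gene indices), `subpops` (affected
#'   subpopulation labels) and `log2fc` (signed; positive = up in tumour).
#'   Applied to tumour-condition cells of the affected subpopulations only.
#' @param baselineMeanLog,baselineSdLog log-normal parameters of baseline
#'   mean expression.
#' @param dispersion either `list(type = "trend", asymptote, extraPoisson)`
#'   or `list(type = "constant", value)`.
#' @param depthMeanLog,depthSdLog log-normal parameters of per-cell mapped
#'   reads (plate scale).
#' @param mitoBeta length-2 Beta parameters of the per-cell mitochondrial
#'   read fraction.
#' @param fractionLowQuality fraction of cells planted as low quality; the
#'   planted count is `round(fraction * nCells)`, exactly. Planted cells
#'   alternate between depth scaled to 50% of `qcMinMappedReads` and
#'   mitochondrial fraction set to 1.5x `qcMaxMitoFraction`, so each QC
#'   rule is exercised.
#' @param qcMinMappedReads,qcMaxMitoFraction the plate QC thresholds the
#'   low-quality planting is defined against.
#' @param seed integer; fixes all randomness (two runs with equal configs
#'   are identical).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nGenes = 5000,
                      nMitoGenes = 13,
                      nCellsPerSubpopPerReplicate = 55,
                      subpopNames = c("CG1", "CG2", "NEFM", "PEP", "NPEP"),
                      nReplicatesHealthy = 2,
                      nReplicatesTumour = 3,
                      markerGenesPerSubpop = 50,
                      markerLog2fc = 2,
                      deGeneSets = list(),
                      baselineMeanLog = log(40),
                      baselineSdLog = 1.2,
                      dispersion = list(type = "trend", asymptote = 0.1,
                                        extraPoisson = 1),
                      depthMeanLog = log(5e5),
                      depthSdLog = 0.4,
                      mitoBeta = c(20, 230),
                      fractionLowQuality = 0,
                      qcMinMappedReads = 50000,
                      qcMaxMitoFraction = 0.2,
                      seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nMitoGenes = as.integer(nMitoGenes),
              nCellsPerSubpopPerReplicate =
                as.integer(nCellsPerSubpopPerReplicate),
              subpopNames = subpopNames,
              nReplicatesHealthy = as.integer(nReplicatesHealthy),
              nReplicatesTumour = as.integer(nReplicatesTumour),
              markerGenesPerSubpop = as.integer(markerGenesPerSubpop),
              markerLog2fc = markerLog2fc,
              deGeneSets = deGeneSets,
              baselineMeanLog = baselineMeanLog,
              baselineSdLog = baselineSdLog,
              dispersion = dispersion,
              depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
              mitoBeta = mitoBeta,
              fractionLowQuality = fractionLowQuality,
              qcMinMappedReads = qcMinMappedReads,
              qcMaxMitoFraction = qcMaxMitoFraction,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  err <- validateSimConfig(cfg)
  if (length(err)) stop("invalid SimConfig: ", paste(err, collapse = "; "))
  cfg
}

#' Validate a SimConfig
#'
#' @param cfg a `SimConfig` list.
#' @return Character vector of violations (empty when valid).
#' @export
validateSimConfig <- function(cfg) {
  v <- character()
  chkPos <- function(field) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1L ||
        is.na(cfg[[field]]) || cfg[[field]] <= 0)
      v <<- c(v, paste0(field, " must be a positive scalar"))
  }
  for (f in c("nGenes", "nCellsPerSubpopPerReplicate", "nReplicatesHealthy",
              "nReplicatesTumour", "qcMinMappedReads"))
    chkPos(f)
  if (cfg$fractionLowQuality < 0 || cfg$fractionLowQuality > 1)
    v <- c(v, "fractionLowQuality must be in [0, 1]")
  if (cfg$qcMaxMitoFraction <= 0 || cfg$qcMaxMitoFraction > 1)
    v <- c(v, "qcMaxMitoFraction must be in (0, 1]")
  if (anyDuplicated(cfg$subpopNames))
    v <- c(v, "subpopNames must be unique")
  mk <- unlist(.markerIndices(cfg), use.names = FALSE)
  de <- unlist(lapply(cfg$deGeneSets, `[[`, "genes"), use.names = FALSE)
  if (length(de)) {
    if (any(de < 1 | de > cfg$nGenes))
      v <- c(v, "deGeneSets gene indices out of range")
    if (length(intersect(de, mk)))
      v <- c(v, "deGeneSets must be disjoint from marker genes")
    if (length(intersect(de, seq_len(cfg$nMitoGenes))))
      v <- c(v, "deGeneSets must not target mitochondrial genes")
    bad <- !vapply(cfg$deGeneSets, function(s)
      all(s$subpops %in% cfg$subpopNames), logical(1))
    if (any(bad)) v <- c(v, "deGeneSets reference unknown subpopulations")
  }
  total <- cfg$nMitoGenes + length(mk) + length(unique(de))
  if (total > cfg$nGenes)
    v <- c(v, "nGenes smaller than total planted genes")
  v
}

.geneIds <- function(cfg, species = "mm") {
  n <- cfg$nGenes
  m <- cfg$nMitoGenes
  w <- max(4L, nchar(as.character(n)))
  c(sprintf("%s:mt-g%02d", species, seq_len(m)),
    sprintf(paste0("%s:g%0", w, "d"), species, seq_len(n - m)))
}

.markerIndices <- function(cfg) {
  out <- list()
  start <- cfg$nMitoGenes + 1L
  for (s in cfg$subpopNames) {
    out[[s]] <- seq.int(start, length.out = cfg$markerGenesPerSubpop)
    start <- start + cfg$markerGenesPerSubpop
  }
  out
}

#' Baseline mean expression the generators will use
#'
#' Returns the per-gene log-normal baseline means drawn from the config's
#' seed, exactly as [generateNeuronExperiment()] uses them. Exposed so
#' planted gene sets can be chosen at a known expression level.
#'
#' @param cfg a [simConfig()].
#' @return Named numeric vector of baseline means (one per gene).
#' @export
simBaselineMeans <- function(cfg) {
  b <- .withSeed(cfg$seed,
                 rlnorm(cfg$nGenes, cfg$baselineMeanLog, cfg$baselineSdLog))
  names(b) <- .geneIds(cfg)
  b
}

.dispersionAt <- function(cfg, mu) {
  d <- cfg$dispersion
  a <- if (identical(d$type, "constant")) rep(d$value, length(mu))
       else d$asymptote + d$extraPoisson / pmax(mu, 1e-8)
  pmax(a, 1e-8)
}

# Simulate a block of cells given per-cell expected profiles.
# profiles: genes x nProfiles matrix of relative expression (linear scale);
# profileOf: per-cell profile column; depth, mitoFrac: per-cell scalars.
.simCounts <- function(profiles, isMito, profileOf, depth, expectedDepth,
                       mitoFrac, alpha) {
  nG <- nrow(profiles)
  nC <- length(profileOf)
  counts <- matrix(0L, nG, nC)
  sMito <- colSums(profiles[isMito, , drop = FALSE]) / colSums(profiles)
  for (j in seq_len(nC)) {
    m <- profiles[, profileOf[j]]
    s <- sMito[profileOf[j]]
    f <- mitoFrac[j]
    m[isMito] <- m[isMito] * f / s
    m[!isMito] <- m[!isMito] * (1 - f) / (1 - s)
    mu <- m * depth[j] / expectedDepth
    counts[, j] <- as.integer(rnbinom(nG, mu = mu, size = 1 / alpha))
  }
  counts
}

#' Generate a plate-based traced-neuron experiment
#'
#' Simulates gene x cell counts for `length(subpopNames)` neuronal
#' subpopulations over healthy and tumour replicates, with subpopulation
#' markers, optional planted tumour-specific DE genes, per-cell mapped-read
#' depth and mitochondrial fraction, and an exactly planted low-quality
#' cell fraction (see [simConfig()]).
#'
#' @param cfg a [simConfig()].
#' @return A list with elements `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment] with a `counts` assay,
#'   gene annotation in `rowData` and cell metadata in `colData`) and
#'   `truth` (a `GroundTruth` list: `cells`, `genes`, `deMembership`).
#' @export
generateNeuronExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  baseline <- simBaselineMeans(cfg)
  geneIds <- names(baseline)
  isMito <- seq_len(cfg$nGenes) <= cfg$nMitoGenes
  markers <- .markerIndices(cfg)
  alpha <- .dispersionAt(cfg, baseline)

  reps <- c(paste0("H", seq_len(cfg$nReplicatesHealthy)),
            paste0("T", seq_len(cfg$nReplicatesTumour)))
  conds <- c(rep("healthy", cfg$nReplicatesHealthy),
             rep("tumour", cfg$nReplicatesTumour))
  cells <- expand.grid(idx = seq_len(cfg$nCellsPerSubpopPerReplicate),
                       subpop = cfg$subpopNames, rep = seq_along(reps),
                       stringsAsFactors = FALSE)
  nC <- nrow(cells)
  cells$replicate <- reps[cells$rep]
  cells$condition <- conds[cells$rep]
  cells$cell_id <- sprintf("c%05d", seq_len(nC))

  # expression profiles per (subpop, condition) in linear scale
  profKey <- unique(cells[, c("subpop", "condition")])
  profKey$name <- paste(profKey$subpop, profKey$condition, sep = ".")
  profiles <- matrix(0, cfg$nGenes, nrow(profKey),
                     dimnames = list(geneIds, profKey$name))
  deMem <- list()
  for (i in seq_len(nrow(profKey))) {
    l2 <- log2(baseline)
    sp <- profKey$subpop[i]
    l2[markers[[sp]]] <- l2[markers[[sp]]] + cfg$markerLog2fc
    if (profKey$condition[i] == "tumour") {
      for (set in cfg$deGeneSets) {
        if (sp %in% set$subpops)
          l2[set$genes] <- l2[set$genes] + set$log2fc
      }
    }
    profiles[, i] <- 2^l2
  }
  for (set in cfg$deGeneSets) {
    deMem[[length(deMem) + 1L]] <- expand.grid(
      gene_id = geneIds[set$genes], subpop = set$subpops,
      stringsAsFactors = FALSE)
    deMem[[length(deMem)]]$direction <- if (set$log2fc >= 0) "up" else "down"
    deMem[[length(deMem)]]$log2fc <- set$log2fc
  }
  deMembership <- if (length(deMem)) do.call(rbind, deMem)
                  else data.frame(gene_id = character(), subpop = character(),
                                  direction = character(), log2fc = numeric())

  expectedDepth <- exp(cfg$depthMeanLog + cfg$depthSdLog^2 / 2)
  res <- .withSeed(cfg$seed + 1L, {
    depth <- rlnorm(nC, cfg$depthMeanLog, cfg$depthSdLog)
    mito <- rbeta(nC, cfg$mitoBeta[1], cfg$mitoBeta[2])
    nLQ <- round(cfg$fractionLowQuality * nC)
    lqCells <- if (nLQ > 0) sort(sample.int(nC, nLQ)) else integer()
    lqMode <- rep(NA_character_, nC)
    if (nLQ > 0) {
      mode <- rep(c("depth", "mito"), length.out = nLQ)
      lqMode[lqCells] <- mode
      depth[lqCells[mode == "depth"]] <- 0.5 * cfg$qcMinMappedReads
      mito[lqCells[mode == "mito"]] <- 1.5 * cfg$qcMaxMitoFraction
    }
    profileOf <- match(paste(cells$subpop, cells$condition, sep = "."),
                       profKey$name)
    counts <- .simCounts(profiles, isMito, profileOf, depth, expectedDepth,
                         mito, alpha)
    list(counts = counts, depth = depth, mito = mito,
         lq = seq_len(nC) %in% lqCells, lqMode = lqMode)
  })

  mappedReads <- as.integer(round(res$depth))
  mitoReads <- as.integer(round(res$mito * mappedReads))
  colData <- S4Vectors::DataFrame(
    cell_id = cells$cell_id,
    replicate = cells$replicate,
    condition = cells$condition,
    ganglion = .ganglionOf(cells$subpop),
    mapped_reads = mappedReads,
    mito_reads = mitoReads,
    row.names = cells$cell_id)
  rowData <- S4Vectors::DataFrame(
    gene_id = geneIds,
    species = rep("mm", cfg$nGenes),
    is_mito = isMito,
    row.names = geneIds)
  dimnames(res$counts) <- list(geneIds, cells$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = res$counts), rowData = rowData, colData = colData)

  markerOf <- rep(NA_character_, cfg$nGenes)
  for (s in names(markers)) markerOf[markers[[s]]] <- s
  truth <- list(
    cells = data.frame(cell_id = cells$cell_id, subpop = cells$subpop,
                       replicate = cells$replicate,
                       condition = cells$condition,
                       is_low_quality = res$lq, lq_mode = res$lqMode,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = geneIds, marker_of = markerOf,
                       stringsAsFactors = FALSE),
    deMembership = deMembership)
  class(truth) <- "GroundTruth"
  list(sce = sce, truth = truth)
}

#' Generate a reference atlas from freshly simulated healthy cells
#'
#' Simulates `cellsPerType` healthy cells per subpopulation under the
#' config's expression model (independent draws from a dedicated seed
#' stream), library-size normalizes and log2-transforms them, and returns
#' per-type mean profiles as centroids.
#'
#' @param cfg a [simConfig()].
#' @param cellsPerType cells simulated per reference type.
#' @return A [ReferenceAtlas-class]; super-types are the ganglion groups.
#' @export
generateReferenceAtlas <- function(cfg, cellsPerType = 100) {
  stopifnot(inherits(cfg, "SimConfig"), cellsPerType >= 1)
  baseline <- simBaselineMeans(cfg)
  geneIds <- names(baseline)
  isMito <- seq_len(cfg$nGenes) <= cfg$nMitoGenes
  markers <- .markerIndices(cfg)
  alpha <- .dispersionAt(cfg, baseline)
  profiles <- vapply(cfg$subpopNames, function(sp) {
    l2 <- log2(baseline)
    l2[markers[[sp]]] <- l2[markers[[sp]]] + cfg$markerLog2fc
    2^l2
  }, numeric(cfg$nGenes))
  expectedDepth <- exp(cfg$depthMeanLog + cfg$depthSdLog^2 / 2)
  counts <- .withSeed(cfg$seed + 2L, {
    nC <- cellsPerType * length(cfg$subpopNames)
    depth <- rlnorm(nC, cfg$depthMeanLog, cfg$depthSdLog)
    mito <- rbeta(nC, cfg$mitoBeta[1], cfg$mitoBeta[2])
    profileOf <- rep(seq_along(cfg$subpopNames), each = cellsPerType)
    .simCounts(profiles, isMito, profileOf, depth, expectedDepth, mito,
               alpha)
  })
  totals <- colSums(counts)
  sf <- totals / exp(mean(log(totals)))
  logc <- log2(sweep(counts, 2, sf, "/") + 1)
  typeOf <- rep(cfg$subpopNames, each = cellsPerType)
  cent <- vapply(cfg$subpopNames,
                 function(s) rowMeans(logc[, typeOf == s, drop = FALSE]),
                 numeric(cfg$nGenes))
  rownames(cent) <- geneIds
  ReferenceAtlas(cent,
                 superType = setNames(.ganglionOf(cfg$subpopNames),
                                      cfg$subpopNames),
                 note = "synthetic atlas (simulated healthy cells)")
}

#' Generate a droplet-based tumour-microenvironment experiment
#'
#' Simulates UMI-like counts for the given microenvironment cell types over
#' healthy and tumour replicates on a two-species gene universe (the
#' config's mouse genes plus a human gene block, so species assignment is
#' testable; cancer cells draw most of their reads from the human block).
#' Each cell type carries fixed per-gene identity effects, and the supplied
#' ligand/receptor shifts are planted in the stated receiver type and
#' condition.
#'
#' @param cfg a [simConfig()]; supplies gene universe, baselines,
#'   dispersion and seed.
#' @param cellTypes receiver cell-type labels.
#' @param plantedLR `NULL` or a data.frame with columns `ligand`,
#'   `receptor`, `tme_side` ("ligand" or "receptor": which gene is shifted
#'   in the microenvironment), `receiver`, `condition`, `log2fc`.
#' @param nCellsPerTypePerReplicate cells per type per replicate.
#' @param nReplicatesHealthy,nReplicatesTumour replicates per condition
#'   (defaults 3 and 4, the study's pancreas/PDX design).
#' @param typeEffectSd sd (log2 units) of fixed per-gene, per-type identity
#'   effects.
#' @param nHumanGenes size of the human (`hg:`) gene block.
#' @param humanTypes cell types treated as human (mostly-human reads).
#' @param hgFractionCancer,hgFractionOther expected fraction of a cell's
#'   reads on the human block for human and mouse cell types.
#' @param umiMeanLog,umiSdLog log-normal parameters of per-cell UMI totals.
#' @param mitoBeta Beta parameters of the droplet mitochondrial fraction.
#' @param qcMinUmis,qcMaxMitoFraction droplet QC thresholds the low-quality
#'   planting is defined against.
#' @param fractionLowQuality exactly planted low-quality fraction
#'   (alternating low-UMI / high-mito cells).
#' @return A list with `sce` (counts + metadata) and `truth` (`cells`,
#'   `genes`, `plantedLR`).
#' @export
generateTmeExperiment <- function(cfg,
                                  cellTypes = c("PDAC", "Epithelial",
                                                "Endothelial", "Immune",
                                                "CAF", "Fibroblast"),
                                  plantedLR = NULL,
                                  nCellsPerTypePerReplicate = 30,
                                  nReplicatesHealthy = 3,
                                  nReplicatesTumour = 4,
                                  typeEffectSd = 0.5,
                                  nHumanGenes = 1000,
                                  humanTypes = "PDAC",
                                  hgFractionCancer = 0.9,
                                  hgFractionOther = 0.02,
                                  umiMeanLog = log(8000),
                                  umiSdLog = 0.3,
                                  mitoBeta = c(30, 970),
                                  qcMinUmis = 1000,
                                  qcMaxMitoFraction = 0.1,
                                  fractionLowQuality = 0) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (!is.null(plantedLR)) {
    need <- c("ligand", "receptor", "tme_side", "receiver", "condition",
              "log2fc")
    if (!all(need %in% names(plantedLR)))
      stop("plantedLR must have columns ", paste(need, collapse = ", "))
    if (!all(plantedLR$receiver %in% cellTypes))
      stop("unknown cell type in plantedLR: ",
           paste(setdiff(plantedLR$receiver, cellTypes), collapse = ", "))
  }
  mmBase <- simBaselineMeans(cfg)
  mmIds <- names(mmBase)
  nMito <- cfg$nMitoGenes
  nHgMito <- min(13L, nHumanGenes)
  wh <- max(4L, nchar(as.character(nHumanGenes)))
  hgIds <- c(sprintf("hg:mt-g%02d", seq_len(nHgMito)),
             sprintf(paste0("hg:g%0", wh, "d"),
                     seq_len(nHumanGenes - nHgMito)))
  geneIds <- c(mmIds, hgIds)
  nG <- length(geneIds)
  species <- c(rep("mm", length(mmIds)), rep("hg", length(hgIds)))
  isMito <- grepl("^..:mt-", geneIds, ignore.case = TRUE)
  mmBlock <- species == "mm"

  reps <- c(paste0("H", seq_len(nReplicatesHealthy)),
            paste0("T", seq_len(nReplicatesTumour)))
  conds <- c(rep("healthy", nReplicatesHealthy),
             rep("tumour", nReplicatesTumour))
  cells <- expand.grid(idx = seq_len(nCellsPerTypePerReplicate),
                       cell_type = cellTypes, rep = seq_along(reps),
                       stringsAsFactors = FALSE)
  nC <- nrow(cells)
  cells$replicate <- reps[cells$rep]
  cells$condition <- conds[cells$rep]
  cells$cell_id <- sprintf("t%05d", seq_len(nC))

  if (!is.null(plantedLR) && nrow(plantedLR)) {
    plantedLR$tme_gene <- ifelse(plantedLR$tme_side == "ligand",
                                 plantedLR$ligand, plantedLR$receptor)
    if (!all(plantedLR$tme_gene %in% geneIds))
      stop("plantedLR gene absent from the gene universe")
  }

  out <- .withSeed(cfg$seed + 3L, {
    hgBase <- rlnorm(length(hgIds), cfg$baselineMeanLog, cfg$baselineSdLog)
    baseline <- c(mmBase, hgBase)
    alpha <- .dispersionAt(cfg, baseline)
    typeEff <- matrix(rnorm(nG * length(cellTypes), 0, typeEffectSd),
                      nG, length(cellTypes),
                      dimnames = list(geneIds, cellTypes))
    # per (type, condition) linear profiles, species-block normalized later
    profKey <- expand.grid(cell_type = cellTypes,
                           condition = c("healthy", "tumour"),
                           stringsAsFactors = FALSE)
    profKey$name <- paste(profKey$cell_type, profKey$condition, sep = ".")
    profiles <- matrix(0, nG, nrow(profKey),
                       dimnames = list(geneIds, profKey$name))
    for (i in seq_len(nrow(profKey))) {
      l2 <- log2(baseline) + typeEff[, profKey$cell_type[i]]
      if (!is.null(plantedLR) && nrow(plantedLR)) {
        hit <- plantedLR$receiver == profKey$cell_type[i] &
               plantedLR$condition == profKey$condition[i]
        if (any(hit)) {
          gi <- match(plantedLR$tme_gene[hit], geneIds)
          l2[gi] <- l2[gi] + plantedLR$log2fc[hit]
        }
      }
      profiles[, i] <- 2^l2
    }
    depth <- rlnorm(nC, umiMeanLog, umiSdLog)
    mito <- rbeta(nC, mitoBeta[1], mitoBeta[2])
    nLQ <- round(fractionLowQuality * nC)
    lqCells <- if (nLQ > 0) sort(sample.int(nC, nLQ)) else integer()
    lqMode <- rep(NA_character_, nC)
    if (nLQ > 0) {
      mode <- rep(c("depth", "mito"), length.out = nLQ)
      lqMode[lqCells] <- mode
      depth[lqCells[mode == "depth"]] <- 0.5 * qcMinUmis
      mito[lqCells[mode == "mito"]] <- 1.5 * qcMaxMitoFraction
    }
    profileOf <- match(paste(cells$cell_type, cells$condition, sep = "."),
                       profKey$name)
    hgFrac <- ifelse(cells$cell_type %in% humanTypes,
                     hgFractionCancer, hgFractionOther)
    counts <- matrix(0L, nG, nC, dimnames = list(geneIds, cells$cell_id))
    for (j in seq_len(nC)) {
      m <- profiles[, profileOf[j]]
      for (blk in list(mmBlock, !mmBlock)) {
        bm <- isMito & blk
        bn <- !isMito & blk
        s <- sum(m[bm]) / sum(m[blk])
        m[bm] <- m[bm] * mito[j] / s
        m[bn] <- m[bn] * (1 - mito[j]) / (1 - s)
        w <- if (identical(blk, mmBlock)) 1 - hgFrac[j] else hgFrac[j]
        m[blk] <- m[blk] / sum(m[blk]) * w
      }
      mu <- m * depth[j]
      counts[, j] <- as.integer(rnbinom(nG, mu = mu, size = 1 / alpha))
    }
    list(counts = counts, depth = depth, mito = mito,
         lq = seq_len(nC) %in% lqCells, lqMode = lqMode)
  })

  colData <- S4Vectors::DataFrame(
    cell_id = cells$cell_id,
    cell_type = cells$cell_type,
    replicate = cells$replicate,
    condition = cells$condition,
    umi_total = colSums(out$counts),
    row.names = cells$cell_id)
  rowData <- S4Vectors::DataFrame(gene_id = geneIds, species = species,
                                  is_mito = isMito, row.names = geneIds)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = out$counts), rowData = rowData, colData = colData)
  truth <- list(
    cells = data.frame(cell_id = cells$cell_id, cell_type = cells$cell_type,
                       replicate = cells$replicate,
                       condition = cells$condition,
                       is_low_quality = out$lq, lq_mode = out$lqMode,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = geneIds, species = species,
                       stringsAsFactors = FALSE),
    plantedLR = if (is.null(plantedLR)) data.frame() else plantedLR)
  class(truth) <- "GroundTruth"
  list(sce = sce, truth = truth)
}

#' Generate a synthetic ligand-receptor pair table
#'
#' Draws `2 * nPairs` distinct genes from the universe and pairs them so
#' that ligand and receptor sets are disjoint.
#'
#' @param nPairs number of pairs.
#' @param geneUniverse candidate gene ids.
#' @param seed integer seed.
#' @return data.frame with columns `pair_id`, `ligand`, `receptor`.
#' @export
generateLRTable <- function(nPairs, geneUniverse, seed = 1L) {
  if (2 * nPairs > length(geneUniverse))
    stop("gene universe too small for ", nPairs, " pairs")
  if (nPairs == 0)
    return(data.frame(pair_id = character(), ligand = character(),
                      receptor = character(), stringsAsFactors = FALSE))
  genes <- .withSeed(seed, sample(geneUniverse, 2 * nPairs))
  data.frame(pair_id = sprintf("P%03d", seq_len(nPairs)),
             ligand = genes[seq_len(nPairs)],
             receptor = genes[nPairs + seq_len(nPairs)],
             stringsAsFactors = FALSE)
}

#' Write ground truth tables to a directory
#'
#' @param truth a `GroundTruth` list.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(truth)) {
    x <- truth[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0("truth_", nm, ".tsv"))
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
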