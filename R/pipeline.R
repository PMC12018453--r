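# End-to-end orchestration: synthetic data (or files) -> QC ->
# normalization -> annotation -> per-subpopulation and aggregate
# pseudobulk DE -> consensus signature -> enrichment -> interactome, with
# every stage writing TSV outputs carrying provenance headers, and a run
# report. All randomness derives from the config seed, so a rerun with
# the same config is byte-identical.

.writeStageTSV <- function(df, path, stage, seed, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# neurotrace stage=%s seed=%d", stage, seed),
               paste0("# ", extra)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Validate a pipeline configuration
#'
#' @param cfg pipeline configuration list (see [runPipeline()]).
#' @return Character vector of violations, each naming the offending
#'   field; empty when valid.
#' @export
validateConfig <- function(cfg) {
  v <- character()
  hasSim <- !is.null(cfg$sim)
  hasInputs <- !is.null(cfg$inputs)
  if (hasSim == hasInputs)
    v <- c(v, "exactly one of sim / inputs must be present")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    v <- c(v, "seed must be an integer")
  if (is.null(cfg$outputDir) || !nzchar(cfg$outputDir))
    v <- c(v, "outputDir must be set")
  if (hasInputs) {
    for (f in c("neuronDir", "tmeDir", "atlasPath", "lrPath"))
      if (is.null(cfg$inputs[[f]]))
        v <- c(v, paste0("inputs$", f, " is missing"))
  }
  if (hasSim && !hasInputs) {
    sc <- tryCatch(do.call(simConfig, c(cfg$sim$neuron,
                                        list(seed = cfg$seed))),
                   error = function(e) conditionMessage(e))
    if (is.character(sc)) v <- c(v, paste0("sim$neuron: ", sc))
  }
  if (!is.null(cfg$qc)) {
    t <- tryCatch(do.call(qcThresholds, cfg$qc),
                  error = function(e) conditionMessage(e))
    if (is.character(t) && !inherits(t, "QCThresholds"))
      v <- c(v, paste0("qc: ", t))
  }
  if (!is.null(cfg$signature)) {
    s <- tryCatch(do.call(signatureParams, cfg$signature),
                  error = function(e) conditionMessage(e))
    if (!inherits(s, "SignatureParams"))
      v <- c(v, paste0("signature: ", s))
  }
  if (!is.null(cfg$enrichment$nPerm) && cfg$enrichment$nPerm < 100)
    v <- c(v, "enrichment$nPerm must be >= 100")
  if (!is.null(cfg$interactome$topK) && cfg$interactome$topK < 1)
    v <- c(v, "interactome$topK must be >= 1")
  v
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return Configuration list for [runPipeline()].
#' @export
readConfig <- function(path) {
  yaml::read_yaml(path)
}

#' Demonstration configuration (synthetic, small)
#'
#' A complete synthetic run at reduced scale: 1,200 genes, 20 cells per
#' subpopulation per replicate, planted tumour DE gene sets (down in three
#' subpopulations, up in two, plus a CG-only decoy set) on robustly
#' expressed genes, and a 16-pair ligand-receptor table with a CAF-directed
#' tumour secretory program. QC thresholds are scaled to the gene universe.
#'
#' @param seed integer seed driving the whole run.
#' @param outputDir output directory.
#' @return Configuration list for [runPipeline()].
#' @export
demoConfig <- function(seed = 1L, outputDir = tempfile("neurotrace_demo")) {
  seed <- as.integer(seed)
  neuron <- list(nGenes = 1200L, nCellsPerSubpopPerReplicate = 20L,
                 markerGenesPerSubpop = 30L, markerLog2fc = 2,
                 baselineMeanLog = log(300), baselineSdLog = 1.2,
                 depthMeanLog = log(1e6), depthSdLog = 0.4,
                 fractionLowQuality = 0.1)
  probe <- do.call(simConfig, c(neuron, list(seed = seed)))
  b <- simBaselineMeans(probe)
  planted <- setdiff(order(-b),
                     seq_len(probe$nMitoGenes +
                             length(probe$subpopNames) *
                             probe$markerGenesPerSubpop))
  neuron$deGeneSets <- list(
    list(genes = planted[1:15], subpops = c("CG1", "NEFM", "PEP"),
         log2fc = -2),
    list(genes = planted[16:25], subpops = c("NEFM", "PEP"), log2fc = 2),
    list(genes = planted[26:31], subpops = c("CG1", "CG2"), log2fc = 2))
  lrCandidates <- names(b)[planted[40:120]]
  list(
    seed = seed, outputDir = outputDir,
    sim = list(neuron = neuron,
               tme = list(nCellsPerTypePerReplicate = 25L,
                          fractionLowQuality = 0.1),
               nLrPairs = 16L, lrUniverse = lrCandidates,
               cafProgramSize = 8L),
    qc = list(minDetectedGenes = 600),
    annotation = list(nHvgs = 300L, nPcs = 20L, k = 10L),
    de = list(contrast = c("tumour", "healthy"), shrinkWeight = 0.75,
              maxPadj = 0.1),
    signature = list(topN = 300L, minMeanExpression = 500, maxPadj = 0.2,
                     kDown = 3L, kUp = 2L),
    enrichment = list(nPerm = 500L, weight = 1),
    interactome = list(threshold = 2, logBase = 10, topK = 10L))
}

.popMeans <- function(sce, labels) {
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  sf <- SingleCellExperiment::sizeFactors(sce)
  q <- sweep(counts, 2, sf, "/")
  lapply(setNames(unique(labels), unique(labels)), function(p)
    rowMeans(q[, labels == p, drop = FALSE]))
}

#' Run the full pipeline
#'
#' Executes QC, normalization, annotation, differential expression (per
#' subpopulation and whole-ganglion aggregate), signature construction,
#' enrichment and the interactome analysis in order, writing all outputs
#' under `cfg$outputDir`. Any stage failure halts the run with the stage
#' named. All randomness is derived from `cfg$seed`.
#'
#' @param cfg configuration list (see [demoConfig()] for the synthetic
#'   layout; set `cfg$inputs` with `neuronDir`, `tmeDir`, `atlasPath`,
#'   `lrPath` to run on files instead).
#' @return The run report (named list of per-stage records: parameters,
#'   outputs, counts), invisibly written as `report.yaml`.
#' @export
runPipeline <- function(cfg) {
  viol <- validateConfig(cfg)
  if (length(viol))
    stop("invalid configuration: ", paste(viol, collapse = "; "))
  seed <- as.integer(cfg$seed)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed,
                 version = as.character(utils::packageVersion("neurotrace")))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report[[name]] <<- c(res$record,
                         list(wall_clock_s =
                                round(proc.time()[["elapsed"]] - t0, 2)))
    res$value
  }

  data <- stage("data", {
    if (!is.null(cfg$sim)) {
      neuronCfg <- do.call(simConfig, c(cfg$sim$neuron, list(seed = seed)))
      neu <- generateNeuronExperiment(neuronCfg)
      atlas <- generateReferenceAtlas(neuronCfg,
                                      cellsPerType =
                                        cfg$annotation$cellsPerType %||% 100)
      lrUniverse <- cfg$sim$lrUniverse %||% rownames(neu$sce)
      lr <- generateLRTable(cfg$sim$nLrPairs %||% 16, lrUniverse,
                            seed = seed + 11L)
      nProg <- min(cfg$sim$cafProgramSize %||% 8, nrow(lr))
      plantedLR <- data.frame(ligand = lr$ligand[seq_len(nProg)],
                              receptor = lr$receptor[seq_len(nProg)],
                              tme_side = "ligand", receiver = "CAF",
                              condition = "tumour", log2fc = 2,
                              stringsAsFactors = FALSE)
      tme <- do.call(generateTmeExperiment,
                     c(list(cfg = neuronCfg, plantedLR = plantedLR),
                       cfg$sim$tme))
      writeGroundTruth(neu$truth, file.path(cfg$outputDir, "truth_neuron"))
      writeGroundTruth(tme$truth, file.path(cfg$outputDir, "truth_tme"))
      list(value = list(neurons = neu$sce, tme = tme$sce, atlas = atlas,
                        lr = lr, truth = neu$truth, tmeTruth = tme$truth),
           record = list(mode = "synthetic",
                         n_neurons = ncol(neu$sce),
                         n_tme_cells = ncol(tme$sce),
                         n_lr_pairs = nrow(lr)))
    } else {
      neurons <- readCounts(cfg$inputs$neuronDir,
                            cfg$inputs$format %||% "mtx")
      tme <- readCounts(cfg$inputs$tmeDir, cfg$inputs$format %||% "mtx")
      lr <- read.delim(cfg$inputs$lrPath, stringsAsFactors = FALSE)
      if (!"pair_id" %in% names(lr))
        lr$pair_id <- sprintf("P%03d", seq_len(nrow(lr)))
      list(value = list(neurons = neurons, tme = tme,
                        atlas = readAtlas(cfg$inputs$atlasPath), lr = lr,
                        truth = NULL, tmeTruth = NULL),
           record = list(mode = "files", n_neurons = ncol(neurons),
                         n_tme_cells = ncol(tme)))
    }
  })

  thresholds <- do.call(qcThresholds, cfg$qc %||% list())
  qcd <- stage("qc", {
    plate <- qcFilterPlate(data$neurons, thresholds)
    droplet <- qcFilterDroplet(data$tme, thresholds)
    species <- assignSpecies(droplet$sce)
    SummarizedExperiment::colData(droplet$sce)$species <- species
    p1 <- .writeStageTSV(plate$report,
                         file.path(cfg$outputDir, "qc_neurons.tsv"),
                         "qc", seed)
    p2 <- .writeStageTSV(droplet$report,
                         file.path(cfg$outputDir, "qc_tme.tsv"),
                         "qc", seed)
    list(value = list(neurons = plate$sce, tme = droplet$sce),
         record = list(outputs = c(p1, p2),
                       neurons_kept = ncol(plate$sce),
                       tme_kept = ncol(droplet$sce)))
  })

  norm <- stage("normalize", {
    neurons <- logNormalize(qcd$neurons, method = "median_ratio")
    # droplet data are too sparse for ratio-based references; use
    # library-size factors there
    tme <- logNormalize(qcd$tme, method = "library_size")
    list(value = list(neurons = neurons, tme = tme),
         record = list(neurons = "median_ratio", tme = "library_size",
                       logBase = 2, pseudocount = 1))
  })

  ann <- stage("annotate", {
    nHvgs <- min(cfg$annotation$nHvgs %||% 1000, nrow(norm$neurons))
    hvgs <- findHVGs(norm$neurons, nHvgs)
    assign <- labelTransfer(norm$neurons, data$atlas, hvgs)
    assign2 <- labelTransferRank(norm$neurons, data$atlas, hvgs)
    conc <- concordance(assign, assign2)
    clusters <- snnLouvain(norm$neurons,
                           nPcs = cfg$annotation$nPcs %||% 50,
                           k = cfg$annotation$k %||% 10,
                           seed = seed + 21L, hvgs = hvgs)
    comp <- compositionTable(assign,
                             SummarizedExperiment::colData(norm$neurons))
    adf <- as.data.frame(assign)
    adf$cluster <- as.integer(clusters[adf$cell_id])
    p1 <- .writeStageTSV(adf,
                         file.path(cfg$outputDir, "assignments.tsv"),
                         "annotate", seed,
                         sprintf("hvgs=%d concordance=%.4f", nHvgs,
                                 conc$rate))
    p2 <- .writeStageTSV(comp,
                         file.path(cfg$outputDir, "composition.tsv"),
                         "annotate", seed)
    list(value = list(assign = assign, hvgs = hvgs, concordance = conc,
                      clusters = clusters),
         record = list(outputs = c(p1, p2), n_hvgs = nHvgs,
                       concordance = conc$rate,
                       n_clusters = length(unique(clusters))))
  })

  contrast <- cfg$de$contrast %||% c("tumour", "healthy")
  de <- stage("de", {
    cd <- SummarizedExperiment::colData(norm$neurons)
    pops <- sort(unique(ann$assign$best_type))
    pops <- setdiff(pops, "unassignable")
    runs <- c(list(aggregate = rep(TRUE, ncol(norm$neurons))),
              setNames(lapply(pops, function(p) ann$assign$best_type == p),
                       pops))
    results <- list(); outputs <- character(); skipped <- character()
    for (nm in names(runs)) {
      sel <- runs[[nm]]
      sub <- norm$neurons[, sel]
      subCd <- cd[sel, ]
      okWald <- all(table(unique(data.frame(
        r = subCd$replicate, c = subCd$condition))$c)[contrast] >= 2)
      res <- if (isTRUE(okWald)) {
        pb <- makePseudobulk(sub, c("replicate", "condition"))
        nbWaldTest(pb, contrast = contrast,
                   shrinkWeight = cfg$de$shrinkWeight %||% 0.75)
      } else if (all(table(subCd$condition)[contrast] >= 2)) {
        skipped <- c(skipped, paste0(nm, ":wald"))
        wilcoxonDE(sub, subCd$condition, contrast = contrast)
      } else {
        skipped <- c(skipped, nm)
        NULL
      }
      if (is.null(res)) next
      results[[nm]] <- res
      outputs <- c(outputs, .writeStageTSV(
        as.data.frame(res),
        file.path(cfg$outputDir, sprintf("de_%s.tsv", nm)), "de", seed,
        sprintf("contrast=%s:%s", contrast[1], contrast[2])))
    }
    list(value = results,
         record = list(outputs = outputs, contrast = contrast,
                       runs = names(results), fallbacks = skipped))
  })

  sig <- stage("signature", {
    params <- do.call(signatureParams, cfg$signature %||% list())
    popDE <- de[setdiff(names(de), "aggregate")]
    popDE <- popDE[vapply(popDE, function(r) all(r$test == "wald"),
                          logical(1))]
    means <- .popMeans(norm$neurons, ann$assign$best_type)
    cands <- lapply(setNames(names(popDE), names(popDE)), function(p)
      perPopulationCandidates(popDE[[p]], means[[p]], params))
    superTypes <- atlasSuperTypes(data$atlas)
    extra <- setdiff(names(cands), names(superTypes))
    if (length(extra))
      superTypes <- c(superTypes, setNames(.ganglionOf(extra), extra))
    signature <- buildConsensus(cands, superTypes, params)
    gmt <- file.path(cfg$outputDir, "signature.gmt")
    writeGMT(signature, gmt)
    prov <- .writeStageTSV(signatureProvenance(signature),
                           file.path(cfg$outputDir,
                                     "signature_provenance.tsv"),
                           "signature", seed)
    list(value = signature,
         record = list(outputs = c(gmt, prov),
                       n_up = length(signatureUp(signature)),
                       n_down = length(signatureDown(signature)),
                       n_conflicts = length(signature@conflicts)))
  })

  enr <- stage("enrichment", {
    sets <- list()
    if (length(signatureUp(sig))) sets$PCN_up <- signatureUp(sig)
    if (length(signatureDown(sig))) sets$PCN_down <- signatureDown(sig)
    if (!length(sets)) {
      list(value = NULL, record = list(skipped = "empty signature"))
    } else {
      ranked <- rankGenes(de$aggregate)
      res <- permutationTest(ranked, sets,
                             nPerm = cfg$enrichment$nPerm %||% 1000,
                             seed = seed + 31L,
                             p = cfg$enrichment$weight %||% 1)
      p1 <- .writeStageTSV(res,
                           file.path(cfg$outputDir, "enrichment.tsv"),
                           "enrichment", seed)
      list(value = res, record = list(outputs = p1,
                                      n_sets = length(sets)))
    }
  })

  inter <- stage("interactome", {
    cd <- SummarizedExperiment::colData(norm$neurons)
    expr <- expressedLR(norm$neurons, cd$ganglion, data$lr,
                        threshold = cfg$interactome$threshold %||% 2,
                        logBase = cfg$interactome$logBase %||% 10)
    pot <- interactionPotential(norm$tme, expr, data$lr)
    pairs <- differentialPairs(norm$neurons, norm$tme, data$lr, expr,
                               senderCol = "ganglion",
                               topK = cfg$interactome$topK %||% 10,
                               conditions = contrast)
    p1 <- .writeStageTSV(pot,
                         file.path(cfg$outputDir, "interactome_potentials.tsv"),
                         "interactome", seed)
    p2 <- .writeStageTSV(pairs,
                         file.path(cfg$outputDir, "interactome_pairs.tsv"),
                         "interactome", seed)
    list(value = list(potentials = pot, pairs = pairs),
         record = list(outputs = c(p1, p2),
                       n_pairs_ranked = nrow(pairs)))
  })

  report$outputs <- unlist(lapply(report, function(s)
    if (is.list(s)) s$outputs else NULL), use.names = FALSE)
  yaml::write_yaml(report, file.path(cfg$outputDir, "report.yaml"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
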