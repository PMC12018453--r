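test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(nGenes = 300, nCellsPerSubpopPerReplicate = 5,
                   markerGenesPerSubpop = 10, fractionLowQuality = 0.1,
                   seed = 7)
  a <- generateNeuronExperiment(cfg)
  b <- generateNeuronExperiment(cfg)
  expect_identical(assay(a$sce, "counts"), assay(b$sce, "counts"))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(atlasProfiles(generateReferenceAtlas(cfg, 10)),
                   atlasProfiles(generateReferenceAtlas(cfg, 10)))
  t1 <- generateTmeExperiment(cfg, nCellsPerTypePerReplicate = 4)
  t2 <- generateTmeExperiment(cfg, nCellsPerTypePerReplicate = 4)
  expect_identical(assay(t1$sce, "counts"), assay(t2$sce, "counts"))
  expect_identical(generateLRTable(5, rownames(a$sce), seed = 3),
                   generateLRTable(5, rownames(a$sce), seed = 3))
})

test_that("config validation rejects inconsistent planting", {
  expect_error(simConfig(nGenes = 300, markerGenesPerSubpop = 10,
                         deGeneSets = list(list(genes = 14:20,
                                                subpops = "CG1",
                                                log2fc = 1))),
               "disjoint from marker")
  expect_error(simConfig(nGenes = 60, markerGenesPerSubpop = 10),
               "smaller than total planted")
  expect_error(simConfig(nGenes = 300, markerGenesPerSubpop = 5,
                         deGeneSets = list(list(genes = 200:210,
                                                subpops = "XXX",
                                                log2fc = 1))),
               "unknown subpopulations")
})

test_that("no planted effects means empty DE membership", {
  sim <- smallNeuronSim(seed = 2)
  expect_equal(nrow(sim$truth$deMembership), 0L)
})

test_that("planted DE genes hit their analytic negative-binomial mean", {
  # one gene shifted 4-fold in tumour NEFM cells; the empirical mean over
  # >= 500 cells must sit within 3 Monte-Carlo standard errors of the
  # analytic mean 4 * baseline
  cfg <- simConfig(nGenes = 300, nCellsPerSubpopPerReplicate = 167,
                   markerGenesPerSubpop = 10,
                   deGeneSets = list(list(genes = 150L, subpops = "NEFM",
                                          log2fc = 2)),
                   seed = 5)
  b <- simBaselineMeans(cfg)
  sim <- generateNeuronExperiment(cfg)
  sel <- sim$truth$cells$subpop == "NEFM" &
         sim$truth$cells$condition == "tumour"
  expect_gte(sum(sel), 500)
  x <- assay(sim$sce, "counts")[150, sel]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 4 * b[150]), 3 * se)
  # unaffected condition keeps the baseline mean
  hx <- assay(sim$sce, "counts")[150, sim$truth$cells$subpop == "NEFM" &
                                      sim$truth$cells$condition == "healthy"]
  expect_lt(abs(mean(hx) - b[150]), 4 * sd(hx) / sqrt(length(hx)))
})

test_that("simulated counts match the NB mean-variance law", {
  # fixed depth and constant dispersion isolate the count law:
  # var = mu + alpha mu^2
  cfg <- simConfig(nGenes = 200, nCellsPerSubpopPerReplicate = 100,
                   subpopNames = "CG1", markerGenesPerSubpop = 0,
                   nReplicatesHealthy = 5, nReplicatesTumour = 5,
                   dispersion = list(type = "constant", value = 0.2),
                   depthSdLog = 1e-8, mitoBeta = c(2000, 23000),
                   seed = 9)
  b <- simBaselineMeans(cfg)
  sim <- generateNeuronExperiment(cfg)
  x <- assay(sim$sce, "counts")
  expect_gte(ncol(x), 1000)
  keep <- b > 20 & b < 500 & seq_along(b) > cfg$nMitoGenes
  mu <- rowMeans(x[keep, ])
  v <- apply(x[keep, ], 1, var)
  expect_lt(median(abs(mu / b[keep] - 1)), 0.05)
  expect_lt(median(abs(v / (mu + 0.2 * mu^2) - 1)), 0.15)
})

test_that("low-quality planting is exact and exercises both QC rules", {
  cfg <- simConfig(nGenes = 300, nCellsPerSubpopPerReplicate = 8,
                   markerGenesPerSubpop = 10, fractionLowQuality = 0.1,
                   seed = 3)
  sim <- generateNeuronExperiment(cfg)
  tc <- sim$truth$cells
  expect_equal(sum(tc$is_low_quality), round(0.1 * nrow(tc)))
  expect_setequal(unique(tc$lq_mode[tc$is_low_quality]),
                  c("depth", "mito"))
  cd <- colData(sim$sce)
  lowDepth <- tc$is_low_quality & tc$lq_mode == "depth"
  expect_true(all(cd$mapped_reads[lowDepth] < cfg$qcMinMappedReads))
  lowMito <- tc$is_low_quality & tc$lq_mode == "mito"
  frac <- cd$mito_reads / cd$mapped_reads
  expect_true(all(frac[lowMito] > cfg$qcMaxMitoFraction))
})

test_that("reference atlas centroids carry the marker structure", {
  cfg <- simConfig(nGenes = 300, markerGenesPerSubpop = 10,
                   markerLog2fc = 2, seed = 4)
  atlas <- generateReferenceAtlas(cfg, cellsPerType = 100)
  expect_setequal(atlasTypes(atlas), cfg$subpopNames)
  expect_identical(rownames(atlasProfiles(atlas)),
                   names(simBaselineMeans(cfg)))
  # every CG1 marker strictly highest in the CG1 centroid
  m <- atlasProfiles(atlas)[14:23, ]
  expect_true(all(m[, "CG1"] > apply(m[, -1, drop = FALSE], 1, max)))
  expect_equal(unname(atlasSuperTypes(atlas)),
               c("CG", "CG", "DRG", "DRG", "DRG"))
})

test_that("TME planting shifts the receiver type by the stated fold", {
  cfg <- simConfig(nGenes = 500, markerGenesPerSubpop = 10, seed = 6)
  b <- simBaselineMeans(cfg)
  gene <- names(b)[order(-b)][5]
  planted <- data.frame(ligand = gene, receptor = names(b)[400],
                        tme_side = "ligand", receiver = "CAF",
                        condition = "tumour", log2fc = 2)
  tme <- generateTmeExperiment(cfg, plantedLR = planted,
                               nCellsPerTypePerReplicate = 60)
  cd <- colData(tme$sce)
  x <- assay(tme$sce, "counts")[gene, ]
  mT <- mean(x[cd$cell_type == "CAF" & cd$condition == "tumour"])
  mH <- mean(x[cd$cell_type == "CAF" & cd$condition == "healthy"])
  expect_gt(mT / mH, 3.2)
  expect_lt(mT / mH, 4.8)
  expect_error(generateTmeExperiment(cfg, plantedLR =
    transform(planted, receiver = "Astrocyte")), "unknown cell type")
})

test_that("ligand-receptor tables are disjoint and sized by construction", {
  expect_equal(nrow(generateLRTable(0, letters)), 0L)
  tab <- generateLRTable(5, sprintf("g%03d", 1:100), seed = 2)
  expect_equal(nrow(tab), 5L)
  expect_length(unique(c(tab$ligand, tab$receptor)), 10L)
  expect_length(intersect(tab$ligand, tab$receptor), 0L)
  expect_error(generateLRTable(10, letters[1:5]), "too small")
})
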