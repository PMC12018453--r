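lrToy <- data.frame(pair_id = c("P1", "P2"),
                    ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                    stringsAsFactors = FALSE)

test_that("expression calls follow the log-aggregate threshold", {
  counts <- rbind(L1 = c(0, 0, 101, 0), L2 = c(0, 0, 0, 0),
                  R1 = c(50, 51, 0, 0), R2 = c(20, 20, 30, 30))
  sce <- toySCE(counts)
  subpops <- c("A", "A", "B", "B")
  out <- expressedLR(sce, subpops, lrToy, threshold = 2, logBase = 10)
  # A: R1 aggregate 101 -> log10(102) > 2 expressed; R2 aggregate 40 not
  expect_equal(out$A$receptors, "R1")
  expect_length(out$A$ligands, 0)
  # B: L1 aggregate 101 expressed; L2 aggregate 0 not
  expect_equal(out$B$ligands, "L1")
  expect_length(expressedLR(sce, subpops, lrToy,
                            threshold = Inf)$A$receptors, 0)
  expect_error(expressedLR(sce, c("A", "A", "A", "A")[1:3], lrToy),
               "cover every cell")
})

mkTme <- function(vals, types, replicate = "r1", condition = "healthy") {
  # vals: genes x types matrix of log expression, one cell per type
  sce <- toySCE(matrix(1L, nrow(vals), length(types)))
  rownames(sce) <- rownames(vals)
  SummarizedExperiment::assay(sce, "logcounts") <-
    matrix(vals, nrow(vals), length(types),
           dimnames = list(rownames(vals), colnames(sce)))
  SummarizedExperiment::colData(sce)$cell_type <- types
  SummarizedExperiment::colData(sce)$replicate <- replicate
  SummarizedExperiment::colData(sce)$condition <- condition
  sce
}

test_that("interaction potentials match the hand-computed z-scores", {
  expr <- list(DRG = list(ligands = "L1", receptors = character()))
  # 2 receiver types, 1 cognate gene (R1) with means 1 and 3: population
  # (n-denominator) sd is 1, so z = (-1, +1); min-subtraction -> (0, 2)
  vals <- rbind(L1 = c(0, 0), R1 = c(1, 3))
  tme <- mkTme(vals, c("T1", "T2"))
  pot <- interactionPotential(tme, expr, lrToy)
  expect_equal(pot$raw, c(-1, 1), tolerance = 1e-12)
  expect_equal(pot$potential, c(0, 2), tolerance = 1e-12)
  # identical receiver types: all z zero, all potentials zero
  same <- mkTme(rbind(L1 = c(0, 0), R1 = c(2, 2)), c("T1", "T2"))
  potSame <- interactionPotential(same, expr, lrToy)
  expect_equal(potSame$potential, c(0, 0))
  # location invariance: shifting a cognate gene everywhere changes nothing
  shifted <- mkTme(rbind(L1 = c(0, 0), R1 = c(1, 3) + 5), c("T1", "T2"))
  expect_equal(interactionPotential(shifted, expr, lrToy)$potential,
               pot$potential)
  expect_error(interactionPotential(mkTme(vals, c("T1", "T1")), expr,
                                    lrToy),
               "at least 2 receiver")
  expect_error(interactionPotential(tme,
    list(DRG = list(ligands = character(), receptors = character())),
    lrToy), "cognate set empty")
})

test_that("the minimum potential is exactly zero per comparison frame", {
  sim <- interactomeScenario(seed = 1, nGenes = 500)
  tme <- generateTmeExperiment(sim$cfg, plantedLR = sim$planted,
                               nCellsPerTypePerReplicate = 10)
  tnm <- logNormalize(tme$sce, method = "library_size")
  expr <- list(DRG = list(ligands = sim$lr$ligand[1:4],
                          receptors = sim$lr$receptor[1:4]))
  pot <- interactionPotential(tnm, expr, sim$lr)
  expect_equal(min(pot$potential), 0)
  expect_true(all(pot$potential >= 0))
  # removing a receiver type changes the frame, hence the potentials
  sub <- tnm[, tnm$cell_type != "Immune"]
  pot2 <- interactionPotential(sub, expr, sim$lr)
  joined <- merge(pot, pot2,
                  by = c("sender", "condition", "replicate", "receiver"))
  expect_false(isTRUE(all.equal(joined$raw.x, joined$raw.y)))
})

test_that("differential pairs vanish on identical conditions and negate on swap", {
  set.seed(20)
  vals <- matrix(rnorm(4 * 8, 3), 4, 8,
                 dimnames = list(c("L1", "L2", "R1", "R2"), NULL))
  tme <- mkTme(vals, rep(c("T1", "T2"), 4),
               replicate = rep(c("r1", "r2"), each = 4),
               condition = rep(c("healthy", "tumour"), each = 4))
  # neurons: same expression in both conditions
  nvals <- matrix(rnorm(4 * 4, 5), 4, 4,
                  dimnames = list(c("L1", "L2", "R1", "R2"), NULL))
  neurons <- mkTme(nvals, rep("x", 4),
                   condition = rep(c("healthy", "tumour"), each = 2))
  SummarizedExperiment::colData(neurons)$ganglion <- "DRG"
  expr <- list(DRG = list(ligands = c("L1", "L2"),
                          receptors = c("R1", "R2")))
  # identical TME conditions: force equality by reusing healthy cells
  tSame <- mkTme(cbind(vals[, 1:4], vals[, 1:4]), rep(c("T1", "T2"), 4),
                 condition = rep(c("healthy", "tumour"), each = 4))
  nSame <- mkTme(cbind(nvals[, 1:2], nvals[, 1:2]), rep("x", 4),
                 condition = rep(c("healthy", "tumour"), each = 2))
  SummarizedExperiment::colData(nSame)$ganglion <- "DRG"
  same <- differentialPairs(nSame, tSame, lrToy, expr, topK = 100)
  expect_equal(same$delta, rep(0, nrow(same)))
  # swapping the condition labels negates deltas, |delta| ranking intact
  a <- differentialPairs(neurons, tme, lrToy, expr, topK = 100)
  swap <- function(x) c(healthy = "tumour", tumour = "healthy")[x]
  tme2 <- tme; neurons2 <- neurons
  SummarizedExperiment::colData(tme2)$condition <- swap(tme$condition)
  SummarizedExperiment::colData(neurons2)$condition <-
    swap(neurons$condition)
  b <- differentialPairs(neurons2, tme2, lrToy, expr, topK = 100)
  key <- function(d) paste(d$pair_id, d$orientation, d$receiver)
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$delta, -b$delta, tolerance = 1e-12)
  # pairs with neither side expressed are excluded
  none <- differentialPairs(neurons, tme, lrToy,
                            list(DRG = list(ligands = "L1",
                                            receptors = character())),
                            topK = 100)
  expect_true(all(none$pair_id == "P1"))
})

test_that("a planted CAF program is recovered as the top tumour partner", {
  sc <- interactomeScenario(seed = 1)
  neu <- generateNeuronExperiment(sc$cfg)
  tme <- generateTmeExperiment(sc$cfg, plantedLR = sc$planted,
                               fractionLowQuality = 0.1)
  tnm <- logNormalize(qcFilterDroplet(tme$sce)$sce,
                      method = "library_size")
  nnm <- logNormalize(qcFilterPlate(neu$sce,
                                    qcThresholds(minDetectedGenes =
                                                   1000))$sce)
  expr <- expressedLR(nnm, SummarizedExperiment::colData(nnm)$ganglion,
                      sc$lr)
  pot <- interactionPotential(tnm, expr, sc$lr)
  agg <- aggregate(potential ~ sender + condition + receiver, pot, mean)
  tu <- agg[agg$condition == "tumour" & agg$sender == "DRG", ]
  expect_equal(tu$receiver[which.max(tu$potential)], "CAF")
  pairs <- differentialPairs(nnm, tnm, sc$lr, expr, topK = 10)
  expect_true(sc$focal %in% pairs$pair_id[pairs$sender == "DRG"])
})
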