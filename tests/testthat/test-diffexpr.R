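test_that("pseudobulk aggregation sums member cells per gene", {
  m <- cbind(c(1, 2), c(3, 4), c(5, 6))
  sce <- toySCE(m, condition = c("h", "h", "t"),
                replicate = c("r1", "r1", "r2"))
  pb <- makePseudobulk(sce, c("replicate", "condition"))
  expect_equal(unname(as.matrix(assay(pb, "counts"))),
               cbind(c(4, 6), c(5, 6)))
  expect_equal(pb$n_cells, c(2L, 1L))
  # one cell per group reproduces the cell
  pb1 <- makePseudobulk(sce, data.frame(g = c("a", "b", "c")))
  expect_equal(unname(as.matrix(assay(pb1, "counts"))), unname(m))
  # splitting a group and re-merging conserves totals
  pbSplit <- makePseudobulk(sce, data.frame(g = c("a", "b", "c")))
  expect_equal(rowSums(assay(pbSplit, "counts")),
               rowSums(assay(pb, "counts")))
  expect_error(makePseudobulk(sce, "nonexistent"), "grouping column")
})

test_that("the NB Wald test is null on identical libraries and symmetric", {
  m <- matrix(rep(c(10, 25, 40), 5), 3, 5)
  rownames(m) <- paste0("g", 1:3)
  cond <- c("healthy", "healthy", "tumour", "tumour", "tumour")
  de <- nbWaldTest(m, condition = cond)
  expect_equal(de$log2FC, rep(0, 3), tolerance = 1e-8)
  expect_equal(de$pvalue, rep(1, 3), tolerance = 1e-6)

  sim <- smallNeuronSim(seed = 6, nGenes = 300, cells = 8)
  pb <- makePseudobulk(sim$sce, c("replicate", "condition"))
  a <- nbWaldTest(pb, contrast = c("tumour", "healthy"))
  b <- nbWaldTest(pb, contrast = c("healthy", "tumour"))
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-8)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-8)
  expect_error(nbWaldTest(m[, 1:3], condition = cond[1:3]),
               "wilcoxonDE")
})

test_that("all-zero genes are excluded before adjustment", {
  m <- rbind(g1 = c(5, 6, 7, 8, 9), g2 = c(0, 0, 0, 0, 0),
             g3 = c(9, 9, 2, 2, 2))
  de <- nbWaldTest(m, contrast = c("t", "h"),
                   condition = c("h", "h", "t", "t", "t"))
  expect_true(is.na(de["g2", "pvalue"]))
  expect_equal(S4Vectors::metadata(de)$nExcluded, 1L)
  expect_false(any(is.na(de[c("g1", "g3"), "padj"])))
})

test_that("the Wald fit agrees with glm at its Poisson and NB limits", {
  set.seed(4)
  m <- matrix(rnbinom(40 * 5, mu = 60, size = 10), 40, 5)
  rownames(m) <- paste0("g", 1:40)
  cond <- c("h", "h", "t", "t", "t")
  x <- factor(cond, levels = c("h", "t"))
  de0 <- nbWaldTest(m, contrast = c("t", "h"), condition = cond,
                    dispersions = 1e-8)
  sf <- S4Vectors::metadata(de0)$sizeFactors
  # dispersion ~0: the NB Wald z must match a Poisson GLM Wald z
  zPois <- vapply(seq_len(nrow(m)), function(i) {
    fit <- glm(m[i, ] ~ x + offset(log(sf)), family = poisson())
    unname(coef(summary(fit))[2, 3])
  }, numeric(1))
  expect_equal(de0$stat, zPois, tolerance = 1e-3)
  # at a real dispersion the IRLS matches the NB-family glm fit
  deNB <- nbWaldTest(m, contrast = c("t", "h"), condition = cond,
                     dispersions = 0.05)
  for (i in c(1, 7, 19)) {
    fit <- suppressWarnings(
      glm(m[i, ] ~ x + offset(log(sf)),
          family = MASS::negative.binomial(theta = 1 / 0.05)))
    expect_equal(unname(coef(fit)[2]) / log(2), deNB$log2FC[i],
                 tolerance = 1e-4)
    expect_equal(unname(coef(summary(fit, dispersion = 1))[2, 2]) / log(2),
                 deNB$se[i], tolerance = 1e-2)
  }
})

test_that("planted effects are recovered and the direction is right", {
  probe <- simConfig(nGenes = 500, nCellsPerSubpopPerReplicate = 20,
                     markerGenesPerSubpop = 10, seed = 12)
  b <- simBaselineMeans(probe)
  elig <- setdiff(which(b >= 50), 1:63)
  sets <- list(list(genes = elig[1:20], subpops = probe$subpopNames,
                    log2fc = 2),
               list(genes = elig[21:40], subpops = probe$subpopNames,
                    log2fc = -2))
  cfg <- simConfig(nGenes = 500, nCellsPerSubpopPerReplicate = 20,
                   markerGenesPerSubpop = 10, deGeneSets = sets, seed = 12)
  sim <- generateNeuronExperiment(cfg)
  de <- nbWaldTest(makePseudobulk(sim$sce, c("replicate", "condition")))
  up <- names(b)[elig[1:20]]; dn <- names(b)[elig[21:40]]
  expect_gte(mean(de[up, "padj"] < 0.1), 0.9)
  expect_gte(mean(de[dn, "padj"] < 0.1), 0.9)
  expect_true(all(de[up, "log2FC"] > 0))
  expect_true(all(de[dn, "log2FC"] < 0))
  # independent check of effect size: planted log2fc = 2 recovered
  expect_equal(median(de[up, "log2FC"]), 2, tolerance = 0.2)
})

test_that("Wilcoxon DE matches the enumeration oracle on the exact path", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = c(2, 2, 2, 2, 2, 2))
  groups <- c("h", "h", "h", "t", "t", "t")
  de <- wilcoxonDE(m, groups, contrast = c("t", "h"))
  expect_equal(unname(de["g1", "pvalue"]), 0.1)
  expect_equal(unname(de["g1", "pvalue"]),
               enumWilcoxP(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(unname(de["g2", "pvalue"]), 1)
  # monotone transforms leave rank-sum p unchanged
  de2 <- wilcoxonDE(rbind(g1 = exp(m["g1", ]), g2 = m["g2", ]), groups,
                    contrast = c("t", "h"))
  expect_equal(unname(de2["g1", "pvalue"]), unname(de["g1", "pvalue"]))
  expect_error(wilcoxonDE(m, c("h", "t", "t", "t", "t", "t")),
               "at least 2 cells")
})

test_that("the exact and normal Wilcoxon paths agree at moderate n", {
  set.seed(5)
  x <- matrix(rnorm(3 * 20, mean = rep(c(0, 0, 1), 20)), 3, 20)
  rownames(x) <- paste0("g", 1:3)
  groups <- rep(c("a", "b"), each = 10)
  exact <- wilcoxonDE(x, groups)                 # both groups of 10: exact
  pApprox <- apply(x, 1, function(g)
    suppressWarnings(wilcox.test(g[groups == "b"], g[groups == "a"],
                                 exact = FALSE, correct = TRUE))$p.value)
  expect_lt(max(abs(exact$pvalue - pApprox)), 0.02)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
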