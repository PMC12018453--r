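test_that("HVG selection ranks residual variance with a stable tie-break", {
  # equal mean and variance everywhere: residuals all zero, selection
  # falls back to lexicographic gene order
  m <- matrix(rep(c(0, 2), 50), nrow = 10, ncol = 10, byrow = TRUE)
  rownames(m) <- sprintf("g%02d", 10:1)
  expect_equal(findHVGs(m, 3), c("g01", "g02", "g03"))
  # one gene with much larger variance at comparable mean tops the list
  set.seed(1)
  m2 <- matrix(rnorm(200 * 20, mean = 5, sd = 1), 200, 20)
  rownames(m2) <- sprintf("g%03d", 1:200)
  m2["g050", ] <- rnorm(20, mean = 5, sd = sqrt(10))
  expect_equal(findHVGs(m2, 1), "g050")
  expect_length(findHVGs(m2, 200), 200)
  expect_error(findHVGs(m2, 201), "exceeds")
  expect_error(findHVGs(m2[, 1, drop = FALSE], 5), "at least 2 cells")
})

test_that("label transfer reproduces hand-computed correlations", {
  centroids <- cbind(A = c(1, 2, 3), B = c(3, 2, 1))
  rownames(centroids) <- c("g1", "g2", "g3")
  atlas <- ReferenceAtlas(centroids)
  q <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  a <- labelTransfer(q, atlas, c("g1", "g2", "g3"))
  expect_equal(a$best_type, "A")
  expect_equal(a$best_cor, 1)
  expect_equal(a$runner_up, "B")
  expect_equal(a$runner_up_cor, -1)
  expect_equal(a$margin, 2)
  expect_false(a$unassignable)
  # permuting genes identically in query and atlas changes nothing
  perm <- c(3, 1, 2)
  a2 <- labelTransfer(q[perm, , drop = FALSE],
                      ReferenceAtlas(centroids[perm, ]),
                      c("g1", "g2", "g3"))
  expect_equal(as.data.frame(a), as.data.frame(a2))
  # constant profiles have undefined correlation
  qc <- matrix(2, 3, 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  expect_equal(labelTransfer(qc, atlas, c("g1", "g2", "g3"))$best_type,
               "unassignable")
  expect_error(labelTransfer(q[1:2, , drop = FALSE], atlas, c("g1", "g2")),
               "at least 3 shared genes")
})

test_that("the rank annotator is invariant to monotone transforms", {
  centroids <- cbind(A = c(1, 2, 3, 4), B = c(4, 1, 3, 2))
  rownames(centroids) <- paste0("g", 1:4)
  atlas <- ReferenceAtlas(centroids)
  q <- matrix(exp(c(1, 2, 3, 4)), 4, 1,
              dimnames = list(paste0("g", 1:4), "c1"))
  a <- labelTransferRank(q, atlas, paste0("g", 1:4))
  expect_equal(a$best_type, "A")
  expect_equal(a$best_cor, 1)
  qc <- matrix(5, 4, 1, dimnames = list(paste0("g", 1:4), "c1"))
  expect_equal(labelTransferRank(qc, atlas, paste0("g", 1:4))$best_type,
               "unassignable")
})

test_that("concordance is the agreement rate over assignable cells", {
  mk <- function(types) S4Vectors::DataFrame(
    cell_id = paste0("c", seq_along(types)), best_type = types,
    unassignable = types == "unassignable")
  expect_equal(concordance(mk(c("A", "B", "A")), mk(c("A", "B", "A")))$rate,
               1)
  expect_equal(concordance(mk(c("A", "A", "B", "B")),
                           mk(c("B", "B", "A", "A")))$rate, 0)
  # unassignable cells are excluded from the denominator
  expect_equal(concordance(mk(c("A", "unassignable")), mk(c("A", "A")))$rate,
               1)
  expect_error(concordance(mk("A"),
                           S4Vectors::DataFrame(cell_id = "z",
                                                best_type = "A",
                                                unassignable = FALSE)),
               "disjoint")
})

test_that("label transfer recovers planted subpopulations on simulation", {
  cfg <- simConfig(nGenes = 1000, nCellsPerSubpopPerReplicate = 10,
                   markerGenesPerSubpop = 25, markerLog2fc = 2, seed = 8)
  sim <- generateNeuronExperiment(cfg)
  nm <- logNormalize(sim$sce)
  atlas <- generateReferenceAtlas(cfg, cellsPerType = 50)
  hvgs <- findHVGs(nm, 300)
  a <- labelTransfer(nm, atlas, hvgs)
  truth <- sim$truth$cells$subpop[match(a$cell_id,
                                        sim$truth$cells$cell_id)]
  expect_gte(mean(a$best_type == truth), 0.95)
  b <- labelTransferRank(nm, atlas, hvgs)
  expect_gte(concordance(a, b)$rate, 0.9)
})

test_that("SNN/Louvain separates well-separated clouds deterministically", {
  set.seed(3)
  x <- cbind(matrix(rnorm(50 * 30, 0, 0.5), 50, 30),
             matrix(rnorm(50 * 30, 10, 0.5), 50, 30))
  rownames(x) <- paste0("g", 1:50)
  colnames(x) <- paste0("c", 1:60)
  cl <- snnLouvain(x, nPcs = 10, k = 15, seed = 1)
  expect_length(unique(cl), 2L)
  expect_length(unique(cl[1:30]), 1L)
  expect_length(unique(cl[31:60]), 1L)
  expect_identical(cl, snnLouvain(x, nPcs = 10, k = 15, seed = 1))
  expect_gte(attr(cl, "modularity"), 0)
  # duplicating every cell: each duplicate stays with its original and
  # the two clouds never merge
  x2 <- cbind(x, x)
  colnames(x2) <- paste0("c", 1:120)
  cl2 <- snnLouvain(x2, nPcs = 10, k = 15, seed = 1)
  expect_equal(unname(cl2[1:60]), unname(cl2[61:120]))
  expect_length(intersect(cl2[c(1:30, 61:90)], cl2[c(31:60, 91:120)]), 0L)
  expect_error(snnLouvain(x, k = 60), "smaller than the number of cells")
})

test_that("composition tables are normalized within condition", {
  one <- compositionTable(rep("A", 4),
                          data.frame(condition = rep("healthy", 4)))
  expect_equal(one$proportion, 1)
  types <- c(rep("NEFM", 100), rep("PEP", 51))
  tab <- compositionTable(types,
                          data.frame(condition = rep("tumour", 151)))
  expect_equal(round(tab$proportion, 4), c(0.6623, 0.3377))
  # row sums are 1 within every condition for arbitrary input
  set.seed(2)
  types2 <- sample(LETTERS[1:4], 200, replace = TRUE)
  conds <- sample(c("healthy", "tumour"), 200, replace = TRUE)
  tab2 <- compositionTable(types2, data.frame(condition = conds))
  sums <- tapply(tab2$proportion, tab2$condition, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})
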