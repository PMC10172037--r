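test_that("preprocessing normalizes, transforms and filters as asked", {
  counts <- matrix(c(2, 4, 6,
                     4, 8, 12,
                     2, 4, 6), 3, 3, byrow = TRUE)
  rownames(counts) <- paste0("g", 1:3)
  # depths (8, 16, 24): median 16; cell 2 at median unchanged
  X <- preprocessCounts(counts, logTransform = FALSE)
  expect_equal(X[, 2], counts[, 2])
  # cell with depth 2x median is halved
  counts2 <- cbind(a = c(1, 1), b = c(1, 1), c = c(4, 0))
  X2 <- preprocessCounts(counts2, logTransform = FALSE)
  expect_equal(sum(X2[, "c"]), 2)
  # identical cells stay identical
  X3 <- preprocessCounts(matrix(5, 4, 6))
  expect_true(all(X3 == X3[1, 1]))
  # log1p applied
  expect_equal(preprocessCounts(counts2, normalize = FALSE),
               log1p(counts2), ignore_attr = TRUE)
  # HVG off keeps all genes; on keeps the most dispersed
  counts4 <- rbind(constant = rep(10, 8),
                   noisy = c(0, 40, 0, 40, 0, 40, 0, 40))
  expect_equal(nrow(preprocessCounts(counts4, normalize = FALSE)), 2)
  X4 <- preprocessCounts(counts4, normalize = FALSE, nHVG = 1)
  expect_equal(rownames(X4), "noisy")
  # zero-depth cells dropped with a warning
  expect_warning(X5 <- preprocessCounts(cbind(c(1, 2), c(0, 0))),
                 "zero")
  expect_equal(ncol(X5), 1)
  expect_error(preprocessCounts(matrix(-1, 2, 2)), "nonnegative")
})

test_that("kNN Louvain clustering separates well-separated groups", {
  set.seed(10)
  X <- rbind(matrix(rnorm(50 * 20, 0), 50, 20),
             matrix(rnorm(50 * 20, 3), 50, 20))
  rownames(X) <- paste0("c", 1:100)
  labs <- clusterCells(X, k = 10, seed = 1)
  expect_equal(ariScore(rep(1:2, each = 50), labs), 1)
  # duplicating every cell preserves the partition structure
  X2 <- rbind(X, X)
  rownames(X2) <- paste0("c", 1:200)
  labs2 <- clusterCells(X2, k = 10, seed = 1)
  expect_equal(ariScore(labs2[1:100], labs2[101:200]), 1)
  expect_error(clusterCells(X[1:5, ], k = 10), "k")
})

test_that("representative selection is stratified and near-optimal", {
  set.seed(11)
  X <- matrix(rnorm(16), 8, 2)
  labs <- rep(1, 8)
  # saturation: budget = n returns everything
  expect_equal(selectRepresentativeCells(X, labs, 8), 1:8)
  # greedy achieves >= (1 - 1/e) of the brute-force optimum
  h <- median(dist(X))
  S <- exp(-as.matrix(dist(X))^2 / (2 * h^2))
  fac <- function(idx) sum(apply(S[, idx, drop = FALSE], 1, max))
  best <- max(combn(8, 3, fac))
  sel <- selectRepresentativeCells(X, labs, 3)
  expect_gte(fac(sel), (1 - exp(-1)) * best)
  # stratification: one cell per cluster at minimal budget
  labs2 <- rep(1:2, each = 4)
  sel2 <- selectRepresentativeCells(X, labs2, 2)
  expect_equal(sort(unique(labs2[sel2])), 1:2)
  expect_error(selectRepresentativeCells(X, labs2, 1), "budget")
})

test_that("max-pooling weights behaves elementwise", {
  expect_equal(poolWeights(c(1, 0), c(0, 2)), c(1, 2))
  expect_equal(poolWeights(c(3, 1, 4)), c(3, 1, 4))
  set.seed(12)
  ws <- replicate(3, runif(6), simplify = FALSE)
  pooled <- poolWeights(ws)
  expect_true(all(vapply(ws, function(w) all(pooled >= w), logical(1))))
  expect_true(all(apply(
    vapply(ws, function(w) pooled == w, logical(6)), 1, any)))
  expect_error(poolWeights(1:3, 1:4), "equal length")
})

# small two-population experiment used by the pipeline tests
smallSim <- function(seed = 21)
  simulatePerturbation("all_same", nGenes = 300, cellsPerPop = 40,
                       avgMarkers = 20, seed = seed)

test_that("state assignment conserves control labels bit-exactly", {
  sim <- smallSim()
  res <- identifyStates(sim, control = "control", variant = "control",
                        nHVG = 200, seed = 5)
  labs <- stateLabels(res)
  ctl <- controlStates(res)
  expect_identical(labs[names(ctl)], ctl)
  expect_true(all(startsWith(ctl, "C")))
  # provenance echoes the configuration
  expect_equal(provenance(res)$seed, 5)
  expect_equal(provenance(res)$variant, "control")
})

test_that("pipeline is deterministic under a fixed seed", {
  sim <- smallSim()
  r1 <- identifyStates(sim, variant = "joint", nHVG = 200, seed = 9)
  r2 <- identifyStates(sim, variant = "joint", nHVG = 200, seed = 9)
  expect_identical(stateLabels(r1), stateLabels(r2))
  expect_identical(pooledWeights(r1), pooledWeights(r2))
})

test_that("an experiment with no treated cells reduces to control clustering", {
  sim <- smallSim()
  ctrl <- sim[, SummarizedExperiment::colData(sim)$treatment == "control"]
  res <- identifyStates(ctrl, control = "control", nHVG = 200, seed = 3)
  expect_identical(stateLabels(res), controlStates(res))
})

test_that("pooling a single treatment reproduces its weights exactly", {
  sim <- smallSim()
  ctrl <- sim[, SummarizedExperiment::colData(sim)$treatment == "control"]
  res <- identifyStates(ctrl, control = "control", variant = "joint",
                        nHVG = 200, seed = 3)
  expect_identical(unname(pooledWeights(res)),
                   unname(geneWeights(res@weights$control)))
})

test_that("missing control label and bad inputs are rejected", {
  sim <- smallSim()
  expect_error(identifyStates(sim, control = "nope"), "control")
  counts <- SummarizedExperiment::assay(sim, "counts")
  expect_error(identifyStates(as.matrix(counts), treatment = c("a", "b")),
               "one entry per cell")
})

test_that("guided clustering recovers states where naive Louvain splits them", {
  sim <- simulatePerturbation("all_same", nGenes = 600, cellsPerPop = 60,
                              avgMarkers = 20, percPerturbed = 0.1,
                              seed = 31)
  truth <- SummarizedExperiment::colData(sim)$ground_truth
  res <- identifyStates(sim, variant = "joint", nHVG = 300, seed = 31)
  expect_gte(ariScore(truth, stateLabels(res)[colnames(sim)]), 0.8)
})
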