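test_that("ARI matches brute-force pair counting", {
  expect_equal(ariScore(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ariScore(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ariScore(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ariScore(c(0, 0, 1, 1), c(0, 1, 0, 1), clip = TRUE), 0)
  # symmetric, relabel-invariant, exact vs pair counting
  set.seed(4)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(ariScore(a, b), bruteARI(a, b), tolerance = 1e-12)
    expect_equal(ariScore(a, b), ariScore(b, a))
  }
  # cross-check against an established implementation
  set.seed(5)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(ariScore(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("LISI hits its closed-form anchor cases", {
  # two well-separated blocks, neighbors all share the cell's treatment
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 50), 20, 2))
  treat <- rep(c("a", "b"), each = 20)
  li <- lisiScore(X, treat, perplexity = 5, k = 10)
  expect_equal(li$perCell, rep(1, 40), tolerance = 1e-6)
  expect_equal(li$scaled, 0, tolerance = 1e-6)
  # perfectly interleaved 50/50 neighborhoods, uniform weights
  X <- cbind(seq(0, 3.9, by = 0.1), 0)
  treat <- rep(c("a", "b"), 20)
  li <- lisiScore(X, treat, k = 10, uniform = TRUE)
  expect_equal(mean(li$perCell), 2, tolerance = 0.05)
  expect_lte(max(li$perCell), 2 + 1e-9)
  # three-treatment Simpson arithmetic: weights (0.5, 0.25, 0.25)
  X <- matrix(c(0, 1, 2, 3, 4, 100), ncol = 1)
  treat <- c("a", "a", "a", "b", "c", "c")
  li <- lisiScore(X, treat, k = 4, uniform = TRUE)
  expect_equal(li$perCell[1], 1 / (0.5^2 + 0.25^2 + 0.25^2),
               tolerance = 1e-9)
  # raw range and relabel invariance
  expect_true(all(li$perCell >= 1 & li$perCell <= 3))
  li2 <- lisiScore(X, c("x", "x", "x", "y", "z", "z"), k = 4,
                   uniform = TRUE)
  expect_equal(li$perCell, li2$perCell)
  expect_error(lisiScore(X, treat, perplexity = 10, k = 4), "perplexity")
})

test_that("population F1 follows the best-overlap-cluster rule", {
  truth <- rep(c("u", "v"), each = 10)
  expect_equal(populationF1(truth, truth, "u"), 1)
  # |P| = 10, best cluster size 10, overlap 5 (competitors overlap <= 1)
  pred <- c(rep(1, 5), 2:6, rep(1, 5), rep(7, 5))
  expect_equal(populationF1(truth, pred, "u"), 2 * 5 / (10 + 10))
  # ties prefer the smaller cluster
  truth2 <- c("u", "u", "v", "v", "v")
  pred2 <- c(1, 2, 2, 2, 2)   # cluster 1 overlap 1 size 1; cluster 2 overlap 1 size 4
  expect_equal(populationF1(truth2, pred2, "u"), 2 * 1 / (2 + 1))
  expect_error(populationF1(truth, pred, "missing"), "empty")
  # F1 = 1 iff a cluster equals the target set
  expect_lt(populationF1(truth, pred, "v"), 1)
})

test_that("Davies-Bouldin equals the textbook formula", {
  # duplicated points: zero scatter, distinct centroids
  X <- rbind(matrix(1, 5, 2), matrix(8, 5, 2))
  db <- daviesBouldin(X, rep(c("a", "b"), each = 5))
  expect_equal(db$raw, 0)
  expect_equal(db$scaled, 1)
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  labs <- sample(1:3, 30, replace = TRUE)
  db <- daviesBouldin(X, labs)
  expect_equal(db$raw, bruteDB(X, labs), tolerance = 1e-9)
  expect_equal(db$scaled, 1 / (1 + db$raw))
  expect_true(db$scaled > 0 && db$scaled <= 1)
})

test_that("Gini coefficient matches the double-sum definition", {
  expect_equal(giniCoefficient(c(100, 100, 100)), 0)
  expect_equal(giniCoefficient(c(50, 150)), 0.25)
  expect_equal(giniCoefficient(7), 0)
  sizes <- c(50, 100, 150)
  expect_equal(giniCoefficient(sizes),
               sum(abs(outer(sizes, sizes, "-"))) /
                 (2 * 9 * mean(sizes)))
  expect_error(giniCoefficient(c(0, 0)), "zero")
})

test_that("composition testing flags treatment-dependent clusters", {
  # perfect independence: G = 0, nothing significant
  ct <- compositionTest(matrix(10, 2, 2))
  expect_equal(ct$omnibus$G, c(0, 0))
  expect_false(any(ct$omnibus$significant))
  # complete separation: Fisher 2x2 [[5,0],[0,5]] has p = 1/126
  tab <- rbind(c(5, 0), c(0, 5))
  colnames(tab) <- c("control", "treated")
  ct <- compositionTest(tab)
  expect_true(all(ct$omnibus$significant))
  expect_equal(ct$pairwise$p, rep(1 / 126, 2), tolerance = 1e-12)
  # BH correction equals the hand step-up procedure
  set.seed(2)
  tab <- rbind(c(40, 10), c(25, 18), c(20, 22), c(15, 30))
  ct <- compositionTest(tab)
  p <- ct$omnibus$p
  stepup <- rev(cummin(rev(sort(p) * 4 / seq_len(4))))[rank(p)]
  expect_equal(ct$omnibus$q, pmin(stepup, 1), tolerance = 1e-12)
  # G-test approaches Pearson chi-squared on large balanced tables
  big <- rbind(c(5000, 5200), c(4800, 5100))
  G <- compositionTest(big)$omnibus$G[1]
  chi <- suppressWarnings(
    stats::chisq.test(rbind(big[1, ], colSums(big) - big[1, ]),
                      correct = FALSE)$statistic)
  expect_lt(abs(G - chi) / chi, 0.01)
})

test_that("scoreClustering assembles a consistent report", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  truth <- rep(c("p1", "p2"), each = 20)
  treat <- rep(c("c", "t"), 20)
  rep0 <- scoreClustering(truth, truth, treatment = treat, X = X,
                          f1Targets = c(unique = "p2"),
                          perplexity = 5, k = 10)
  expect_equal(rep0$ari, 1)
  expect_equal(rep0$f1_unique, 1)
  expect_true(rep0$lisiScaled >= 0 && rep0$lisiScaled <= 1)
  expect_true(rep0$dbScaled > 0 && rep0$dbScaled <= 1)
  expect_equal(rep0$gini, 0)
})
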