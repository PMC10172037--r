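test_that("baseline means follow the configured Gamma distribution", {
  set.seed(1)
  mu <- sampleBaseMeans(1e5, shape = 2, scale = 1)
  se <- sqrt(2 * 1^2 / 1e5)  # Var(Gamma(2,1)) = 2
  expect_lt(abs(mean(mu) - 2), 3 * se)
  expect_true(all(mu >= 0.01))
  set.seed(9); a <- sampleBaseMeans(100)
  set.seed(9); b <- sampleBaseMeans(100)
  expect_identical(a, b)
  expect_error(sampleBaseMeans(10, shape = -1), "shape")
})

test_that("marker sets are disjoint with the configured multipliers", {
  set.seed(2)
  sizes <- numeric(200)
  for (i in 1:200) {
    mk <- assignMarkers(1500, 3, avgMarkers = 10)
    expect_equal(anyDuplicated(unlist(mk$markers)), 0)
    sizes[i] <- mean(lengths(mk$markers))
  }
  # Poisson(10) floored at 1: mean ~ 10
  expect_lt(abs(mean(sizes) - 10), 0.5)
  # Gamma(3,3) multipliers: mean 9
  set.seed(3)
  mult <- unlist(assignMarkers(1e5, 1, avgMarkers = 5e4)$multipliers)
  se <- sqrt(3 * 9 / length(mult))
  expect_lt(abs(mean(mult) - 9), 3 * se)
  # one population keeps all markers in one set
  expect_length(assignMarkers(100, 1, 10)$markers, 1)
})

test_that("perturbation hits the requested gene fraction", {
  mu <- rep(1, 1000)
  set.seed(4)
  expect_identical(applyPerturbation(mu, 0)$mu, mu)
  for (fr in c(0.01, 0.1, 0.25)) {
    p <- applyPerturbation(mu, fr)
    expect_length(p$genes, ceiling(fr * 1000))
    expect_identical(p$mu[-p$genes], mu[-p$genes])
  }
  # Gamma(2,2) multipliers: mean 4
  set.seed(5)
  mult <- applyPerturbation(rep(1, 1e5), 1)$multipliers
  se <- sqrt(2 * 4 / 1e5)
  expect_lt(abs(mean(mult) - 4), 3 * se)
  expect_error(applyPerturbation(mu, 1.2), "fraction")
})

test_that("ZINB counts match closed-form moments", {
  set.seed(6)
  n <- 5e4
  # beta = 0: plain negative binomial at mu = 5, r = 2
  x <- simulateCounts(rep(5, n), r = 2, beta = 0)
  expect_lt(abs(mean(x) - 5), 3 * sqrt(17.5 / n))
  expect_lt(abs(var(x) - 17.5), 3 * 17.5 * sqrt(2 / n) * 2)
  # dropout: zero fraction matches pi + (1 - pi) P(NB = 0)
  for (mu in c(1, 5)) {
    x <- simulateCounts(rep(mu, n), r = 2, beta = 0.1)
    pi0 <- exp(-0.1 * mu)
    p0 <- pi0 + (1 - pi0) * (2 / (2 + mu))^2
    expect_lt(abs(mean(x == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
    # mean: (1 - pi) mu
    varz <- (1 - pi0) * (mu + mu^2 / 2) + pi0 * (1 - pi0) * mu^2
    expect_lt(abs(mean(x) - (1 - pi0) * mu), 3 * sqrt(varz / n))
  }
  # formula limits: tiny positive beta zeroes everything (pi -> 1);
  # very large beta*mu leaves the NB untouched
  expect_true(all(simulateCounts(rep(5, 1000), beta = 1e-9) == 0))
  x <- simulateCounts(rep(50, 2000), r = 5, beta = 10)
  expect_lt(abs(mean(x) - 50), 3 * sqrt((50 + 2500 / 5) / 2000))
  expect_error(simulateCounts(c(1, -1)), "mu")
})

test_that("scenario composition tables match their definitions", {
  spec <- list(
    all_same = list(control = c("pop1", "pop2"),
                    treated = c("pop1", "pop2")),
    rx_unique = list(control = c("pop1", "pop2"),
                     treated = c("pop1", "pop2", "pop3")),
    control_unique = list(control = c("pop1", "pop2", "pop3"),
                          treated = c("pop1", "pop2")),
    both_unique = list(control = c("pop1", "pop2", "pop3"),
                       treated = c("pop1", "pop2", "pop4")),
    none_same = list(control = c("pop1", "pop2"),
                     treated = c("pop3", "pop4")))
  for (sc in names(spec)) {
    sim <- simulatePerturbation(sc, nGenes = 300, cellsPerPop = 20,
                                avgMarkers = 5, seed = 1)
    cd <- SummarizedExperiment::colData(sim)
    for (tr in c("control", "treated")) {
      pops <- sort(unique(cd$ground_truth[cd$treatment == tr]))
      expect_equal(pops, sort(spec[[sc]][[tr]]), label = paste(sc, tr))
      expect_true(all(table(cd$ground_truth[cd$treatment == tr]) == 20))
    }
  }
  # stimulated scenario: pop1 relabeled pop1+ in treated cells only
  sim <- simulatePerturbation("asym_stim", nGenes = 400, cellsPerPop = 15,
                              avgMarkers = 5, seed = 2)
  cd <- SummarizedExperiment::colData(sim)
  expect_true("pop1+" %in% cd$ground_truth[cd$treatment == "treated"])
  expect_false("pop1+" %in% cd$ground_truth[cd$treatment == "control"])
  expect_equal(sort(unique(cd$ground_truth[cd$treatment == "treated"])),
               c("pop1+", "pop2", "pop3", "pop4", "pop5"))
})

test_that("marker effect raises expected expression in the design", {
  sim <- simulatePerturbation("all_same", nGenes = 300, cellsPerPop = 10,
                              avgMarkers = 8, seed = 3)
  d <- S4Vectors::metadata(sim)$design
  for (p in seq_along(d$markers)) {
    up <- d$markerMultipliers[[p]] > 1
    expect_true(all((d$baseMeans[d$markers[[p]]] *
                       d$markerMultipliers[[p]])[up] >
                      d$baseMeans[d$markers[[p]]][up]))
  }
})

test_that("identical design and seed give identical counts", {
  s1 <- simulatePerturbation("both_unique", nGenes = 200, cellsPerPop = 10,
                             avgMarkers = 5, seed = 7)
  s2 <- simulatePerturbation("both_unique", nGenes = 200, cellsPerPop = 10,
                             avgMarkers = 5, seed = 7)
  expect_identical(SummarizedExperiment::assay(s1, "counts"),
                   SummarizedExperiment::assay(s2, "counts"))
  s3 <- simulatePerturbation("both_unique", nGenes = 200, cellsPerPop = 10,
                             avgMarkers = 5, seed = 8)
  expect_false(identical(SummarizedExperiment::assay(s1, "counts"),
                         SummarizedExperiment::assay(s3, "counts")))
})

test_that("unequal population sizes flow through to the Gini metric", {
  sim <- simulatePerturbation("all_same", nGenes = 200, avgMarkers = 5,
                              popSizes = list(pop1 = 50, pop2 = 150),
                              seed = 4)
  cd <- SummarizedExperiment::colData(sim)
  sizes <- table(cd$ground_truth[cd$treatment == "control"])
  expect_equal(as.numeric(sizes[c("pop1", "pop2")]), c(50, 150))
  expect_equal(giniCoefficient(as.numeric(sizes)), 0.25)
})
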