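# Scenario benchmark driver: simulate -> cluster -> score, in long
# format, for the composition scenarios and the robustness grids.

#' Run naive Louvain clustering on a combined experiment
#'
#' Baseline comparator: preprocesses the counts and clusters all cells
#' together (Louvain on a Euclidean kNN graph) without accounting for
#' treatment status. Treatment effects typically split shared states by
#' condition, which is the failure mode control-guided clustering
#' corrects.
#'
#' @inheritParams identifyStates
#' @return Integer cluster label per cell.
#' @export
naiveLouvain <- function(x, k = 15, gamma = 1, normalize = TRUE,
                         logTransform = TRUE, nHVG = NULL,
                         normMethod = c("deconvolution", "total"),
                         seed = 0) {
  counts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  Xp <- preprocessCounts(as.matrix(counts), normalize = normalize,
                         logTransform = logTransform, nHVG = nHVG,
                         method = match.arg(normMethod))
  clusterCells(.minmaxScale(t(Xp)), k = k, gamma = gamma,
               metric = "euclidean", seed = seed)
}

#' Benchmark composition scenarios against ground truth
#'
#' For each scenario and replicate: simulate an experiment
#' ([simulatePerturbation()]), cluster it with [identifyStates()] and
#' with the naive Louvain baseline, and score both against the simulated
#' ground truth ([ariScore()], and scaled [lisiScore()] when
#' `lisi = TRUE`). Results are returned in long format (scenario,
#' replicate, method, metric, value), one row per score.
#'
#' @param scenarios Character vector of scenario names (see
#'   [simulatePerturbation()]).
#' @param replicates Replicates per scenario (default 3).
#' @param variant Pipeline variant passed to [identifyStates()].
#' @param lisi Also compute scaled LISI over treatments in the weighted
#'   space.
#' @param k,gamma,nHVG,subsampleThreshold,subsampleSize Pipeline configuration,
#'   shared by the guided run and the naive baseline (which sees the same
#'   preprocessed matrix). Benchmarks select the 500 most variable genes
#'   by default.
#' @param seed Master seed; replicate r of scenario s uses a derived
#'   child seed.
#' @param ... Further arguments to [simulatePerturbation()] (e.g.
#'   `percPerturbed`, `avgMarkers`, `popSizes`).
#' @return A long-format `data.frame`.
#' @export
benchmarkScenarios <- function(scenarios = c("all_same", "rx_unique",
                                             "control_unique",
                                             "both_unique", "none_same"),
                               replicates = 3, variant = "control",
                               lisi = FALSE, k = 15, gamma = 1,
                               nHVG = 500,
                               subsampleThreshold = 2000,
                               subsampleSize = 500, seed = 0, ...) {
  rows <- list()
  add <- function(sc, rep, method, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(
      scenario = sc, replicate = rep, method = method, metric = metric,
      value = value, stringsAsFactors = FALSE)
  for (sc in scenarios) {
    for (r in seq_len(replicates)) {
      s <- .childSeed(seed, match(sc, scenarios) * 1000 + r)
      sim <- simulatePerturbation(scenario = sc, seed = s, ...)
      truth <- SummarizedExperiment::colData(sim)$ground_truth
      res <- identifyStates(sim, control = "control", variant = variant,
                            k = k, gamma = gamma, nHVG = nHVG,
                            subsampleThreshold = subsampleThreshold,
                            subsampleSize = subsampleSize, seed = s)
      labs <- stateLabels(res)[colnames(sim)]
      nl <- naiveLouvain(sim, k = k, gamma = gamma, nHVG = nHVG, seed = s)
      add(sc, r, "guided", "ari", ariScore(truth, labs))
      add(sc, r, "louvain", "ari", ariScore(truth, nl))
      if (lisi) {
        treatment <- SummarizedExperiment::colData(sim)$treatment
        Xw <- applyGeneWeights(
          .minmaxScale(t(preprocessCounts(
            as.matrix(SummarizedExperiment::assay(sim, "counts")),
            nHVG = nHVG))),
          pooledWeights(res))
        li <- lisiScore(Xw, treatment)
        add(sc, r, "guided", "lisi_scaled", li$scaled)
      }
    }
  }
  do.call(rbind, rows)
}
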