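# Ground-truthed simulation of control/perturbed scRNA-seq experiments.
# Counts follow a zero-inflated negative binomial: NB(mean mu, size r)
# with excess zeros at probability pi(mu) = exp(-beta * mu). Populations
# are defined by disjoint marker gene sets whose baseline means are
# shifted by Gamma(3, 3) (shape-scale) multipliers; treatments perturb a
# random gene subset with Gamma(2, 2) multipliers.

#' Sample baseline per-gene mean expression
#'
#' I.i.d. Gamma(shape, scale) draws, floored at a small epsilon so every
#' gene has positive mean.
#'
#' @param nGenes Number of genes.
#' @param shape,scale Gamma parameters (shape-scale convention).
#' @param eps Positive floor (default 0.01).
#' @return Numeric vector of length `nGenes`.
#' @export
sampleBaseMeans <- function(nGenes, shape = 2, scale = 1, eps = 0.01) {
  if (shape <= 0 || scale <= 0)
    stop("shape and scale must be > 0", call. = FALSE)
  pmax(rgamma(nGenes, shape = shape, scale = scale), eps)
}

#' Assign disjoint marker gene sets and expression multipliers
#'
#' Each population receives Poisson(`avgMarkers`) marker genes (at least
#' one), drawn without replacement from the gene pool so sets are
#' pairwise disjoint. Every marker gets an independent
#' Gamma(`shape`, `scale`) multiplier (default Gamma(3, 3), mean 9)
#' applied to its baseline mean within its population.
#'
#' @param nGenes Number of genes available.
#' @param nPopulations Number of populations.
#' @param avgMarkers Mean marker count per population.
#' @param shape,scale Multiplier Gamma parameters (shape-scale).
#' @return A list with `markers` (list of integer gene index vectors) and
#'   `multipliers` (list of numeric vectors, parallel to `markers`).
#' @export
assignMarkers <- function(nGenes, nPopulations, avgMarkers = 50,
                          shape = 3, scale = 3) {
  counts <- pmax(1L, rpois(nPopulations, avgMarkers))
  if (sum(counts) > nGenes)
    stop("marker sets cannot be disjoint: too few genes", call. = FALSE)
  pool <- sample.int(nGenes, sum(counts))
  splits <- rep(seq_len(nPopulations), counts)
  markers <- split(pool, splits)
  names(markers) <- NULL
  multipliers <- lapply(counts, function(k)
    rgamma(k, shape = shape, scale = scale))
  list(markers = markers, multipliers = multipliers)
}

#' Perturb a fraction of genes with Gamma multipliers
#'
#' Selects `ceiling(fraction * length(mu))` genes uniformly at random and
#' multiplies their means by independent Gamma(`shape`, `scale`) draws
#' (default Gamma(2, 2), mean 4), emulating a treatment that disrupts
#' expression genome-wide without respecting population structure.
#'
#' @param mu Per-gene baseline means.
#' @param fraction Fraction of genes to perturb, in \eqn{[0, 1]}.
#' @param shape,scale Multiplier Gamma parameters (shape-scale).
#' @return A list with `mu` (perturbed means), `genes` (indices of
#'   perturbed genes) and `multipliers`.
#' @export
applyPerturbation <- function(mu, fraction, shape = 2, scale = 2) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  nPerturb <- ceiling(fraction * length(mu))
  if (nPerturb == 0)
    return(list(mu = mu, genes = integer(0), multipliers = numeric(0)))
  genes <- sample.int(length(mu), nPerturb)
  mult <- rgamma(nPerturb, shape = shape, scale = scale)
  mu[genes] <- mu[genes] * mult
  list(mu = mu, genes = genes, multipliers = mult)
}

#' Draw zero-inflated negative binomial counts
#'
#' Counts are NB with mean `mu` and size (dispersion) `r`, then forced to
#' zero with dropout probability \eqn{\pi(\mu) = e^{-\beta\mu}}, so
#' lowly expressed genes drop out most and dropout vanishes for large
#' `beta * mu`. Moments: \eqn{E = (1-\pi)\mu} and
#' \eqn{Var = (1-\pi)(\mu + \mu^2/r) + \pi(1-\pi)\mu^2}.
#'
#' @param mu Per-gene means: a vector (one cell) or a genes-by-cells
#'   matrix.
#' @param r NB size parameter (> 0); larger is less overdispersed.
#' @param beta Dropout decay coefficient (>= 0). `beta = 0` disables
#'   zero inflation entirely (plain NB) rather than following the
#'   formula's \eqn{\pi = 1} limit, which would zero every count.
#' @return Integer counts with the same shape as `mu`.
#' @export
simulateCounts <- function(mu, r = 2, beta = 0.25) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  x <- rnbinom(length(mu), mu = as.numeric(mu), size = r)
  if (beta > 0) {
    drop <- rbinom(length(mu), 1, exp(-beta * as.numeric(mu)))
    x[drop == 1] <- 0L
  }
  if (is.matrix(mu)) dim(x) <- dim(mu)
  x
}

.scenarioTable <- function(scenario) {
  # populations and the treatments they appear in
  switch(scenario,
    all_same = list(pops = c("pop1", "pop2"),
                    control = c("pop1", "pop2"),
                    treated = c("pop1", "pop2"), stim = NULL),
    rx_unique = list(pops = c("pop1", "pop2", "pop3"),
                     control = c("pop1", "pop2"),
                     treated = c("pop1", "pop2", "pop3"), stim = NULL),
    control_unique = list(pops = c("pop1", "pop2", "pop3"),
                          control = c("pop1", "pop2", "pop3"),
                          treated = c("pop1", "pop2"), stim = NULL),
    both_unique = list(pops = c("pop1", "pop2", "pop3", "pop4"),
                       control = c("pop1", "pop2", "pop3"),
                       treated = c("pop1", "pop2", "pop4"), stim = NULL),
    none_same = list(pops = c("pop1", "pop2", "pop3", "pop4"),
                     control = c("pop1", "pop2"),
                     treated = c("pop3", "pop4"), stim = NULL),
    asym_stim = list(pops = paste0("pop", 1:5),
                     control = c("pop1", "pop2", "pop3"),
                     treated = c("pop1", "pop2", "pop3", "pop4", "pop5"),
                     stim = "pop1"),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' Simulate a control/treated perturbation experiment
#'
#' Generates a ground-truthed two-condition experiment under one of six
#' cellular composition scenarios:
#' \describe{
#'   \item{`all_same`}{two populations shared by both conditions;}
#'   \item{`rx_unique`}{two shared plus one treatment-only population;}
#'   \item{`control_unique`}{two shared plus one control-only;}
#'   \item{`both_unique`}{two shared plus one unique to each condition;}
#'   \item{`none_same`}{no shared populations (two per condition);}
#'   \item{`asym_stim`}{three shared populations of which one is
#'     "stimulated" (its markers further elevated by `stimMultiplier` in
#'     the treated condition, labeled `pop1+`), plus two treatment-only
#'     populations.}
#' }
#' Marker sets define populations ([assignMarkers()]); a random
#' `percPerturbed` fraction of genes is disrupted by Gamma(2, 2)
#' multipliers in the treated condition only ([applyPerturbation()]);
#' counts are zero-inflated negative binomial ([simulateCounts()]).
#'
#' @param scenario One of the composition scenarios above.
#' @param nGenes Total genes (default 1500).
#' @param cellsPerPop Cells per population per treatment (default 100).
#' @param popSizes Optional named list/vector overriding `cellsPerPop`
#'   per population (applies in every treatment the population occupies),
#'   for unequal-proportion designs.
#' @param avgMarkers Mean markers per population (default 50).
#' @param percPerturbed Fraction of genes perturbed in treated cells
#'   (default 0.1).
#' @param stimMultiplier Extra multiplier on the stimulated population's
#'   markers in the treated condition (`asym_stim` only). `NULL` (the
#'   default) draws one independent Gamma(3, 3) multiplier per marker —
#'   the same family as the marker-effect model, so activation is
#'   heterogeneous across marker genes; a scalar applies uniformly.
#' @param meanShape,meanScale Baseline mean Gamma parameters.
#' @param dispersion NB size parameter `r` (default 2).
#' @param dropoutBeta Dropout coefficient (default 0.25).
#' @param seed RNG seed; identical design + seed gives identical counts.
#' @return A `SingleCellExperiment` with assay `"counts"`, `colData`
#'   columns `treatment` and `ground_truth`, and the full design
#'   (markers, multipliers, perturbed genes, parameters) in
#'   `metadata(x)$design`.
#' @export
simulatePerturbation <- function(scenario = c("all_same", "rx_unique",
                                              "control_unique",
                                              "both_unique", "none_same",
                                              "asym_stim"),
                                 nGenes = 1500, cellsPerPop = 100,
                                 popSizes = NULL, avgMarkers = 50,
                                 percPerturbed = 0.1,
                                 stimMultiplier = NULL,
                                 meanShape = 2, meanScale = 1,
                                 dispersion = 2, dropoutBeta = 0.25,
                                 seed = 0) {
  scenario <- match.arg(scenario)
  sc <- .scenarioTable(scenario)
  .withSeed(seed, {
    mu0 <- sampleBaseMeans(nGenes, shape = meanShape, scale = meanScale)
    mk <- assignMarkers(nGenes, length(sc$pops), avgMarkers = avgMarkers)
    pert <- applyPerturbation(mu0, percPerturbed)
    stimMult <- if (is.null(sc$stim)) numeric(0)
      else if (is.null(stimMultiplier))
        rgamma(length(mk$markers[[match(sc$stim, sc$pops)]]),
               shape = 3, scale = 3)
      else rep(stimMultiplier,
               length(mk$markers[[match(sc$stim, sc$pops)]]))

    sizeOf <- function(pop) {
      if (is.null(popSizes)) cellsPerPop
      else if (!is.null(popSizes[[pop]])) popSizes[[pop]]
      else cellsPerPop
    }

    blocks <- list()
    for (tr in c("control", "treated")) {
      present <- if (tr == "control") sc$control else sc$treated
      for (pop in present) {
        pi0 <- match(pop, sc$pops)
        mu <- if (tr == "treated") pert$mu else mu0
        mu <- replace(mu, mk$markers[[pi0]],
                      mu[mk$markers[[pi0]]] * mk$multipliers[[pi0]])
        truth <- pop
        if (tr == "treated" && !is.null(sc$stim) && pop == sc$stim) {
          mu[mk$markers[[pi0]]] <- mu[mk$markers[[pi0]]] * stimMult
          truth <- paste0(pop, "+")
        }
        nCells <- sizeOf(pop)
        muMat <- matrix(mu, nGenes, nCells)
        blocks[[length(blocks) + 1]] <-
          list(counts = simulateCounts(muMat, r = dispersion,
                                       beta = dropoutBeta),
               treatment = rep(tr, nCells),
               truth = rep(truth, nCells))
      }
    }
    counts <- do.call(cbind, lapply(blocks, `[[`, "counts"))
    treatment <- unlist(lapply(blocks, `[[`, "treatment"))
    truth <- unlist(lapply(blocks, `[[`, "truth"))
    rownames(counts) <- sprintf("gene%04d", seq_len(nGenes))
    colnames(counts) <- sprintf("cell%05d", seq_along(treatment))

    design <- list(scenario = scenario, nGenes = nGenes,
                   populations = sc$pops,
                   presentIn = list(control = sc$control,
                                    treated = sc$treated),
                   stimulated = sc$stim,
                   markers = mk$markers,
                   markerMultipliers = mk$multipliers,
                   baseMeans = mu0,
                   perturbedGenes = pert$genes,
                   perturbMultipliers = pert$multipliers,
                   cellsPerPop = cellsPerPop, popSizes = popSizes,
                   avgMarkers = avgMarkers,
                   percPerturbed = percPerturbed,
                   stimMultiplier = stimMultiplier,
                   stimMultipliers = stimMult,
                   dispersion = dispersion, dropoutBeta = dropoutBeta,
                   meanShape = meanShape, meanScale = meanScale,
                   seed = seed)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(treatment = treatment,
                                     ground_truth = truth,
                                     row.names = colnames(counts)),
      metadata = list(design = design))
  })
}
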