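# Pipeline orchestration: preprocess -> cluster controls -> (subsample)
# -> NCFS weights -> max-pool across treatments -> transform -> kNN graph
# -> semisupervised clustering with immutable control labels.

#' Normalize, log-transform and select highly variable genes
#'
#' Per-cell size-factor normalization, followed by `log1p`, followed by
#' optional selection of the `nHVG` most dispersed genes (variance/mean
#' of normalized counts). Each step can be skipped individually. Cells
#' with zero total counts are dropped with a warning.
#'
#' Two size-factor estimators are available. `"deconvolution"` (the
#' default) uses pooled deconvolution
#' (`scran::calculateSumFactors()`), which is robust to composition
#' differences between cell states: when one state's marker genes take
#' up a large share of its library (as in a strongly stimulated
#' population), total-count scaling divides the very signal that
#' distinguishes the state, while deconvolution factors track sequencing
#' depth only. `"total"` scales each cell to the median library size;
#' it is also used automatically for datasets with fewer than 30 cells,
#' where pooling is not possible.
#'
#' @param counts Genes-by-cells numeric matrix of nonnegative counts
#'   (dense or `Matrix` sparse).
#' @param normalize Apply size-factor normalization.
#' @param logTransform Apply `log1p`.
#' @param nHVG Keep only this many top-dispersion genes; `NULL` keeps all.
#' @param method Size-factor estimator, `"deconvolution"` or `"total"`.
#' @return Genes-by-cells matrix of preprocessed expression, with attribute
#'   `"droppedCells"` listing any removed zero-depth cells.
#' @export
preprocessCounts <- function(counts, normalize = TRUE, logTransform = TRUE,
                             nHVG = NULL,
                             method = c("deconvolution", "total")) {
  method <- match.arg(method)
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  depth <- colSums(counts)
  dropped <- which(depth == 0)
  if (length(dropped)) {
    warning(length(dropped), " cell(s) with zero counts dropped")
    counts <- counts[, -dropped, drop = FALSE]
    depth <- depth[-dropped]
  }
  X <- counts
  if (normalize && ncol(X)) {
    if (method == "deconvolution" && ncol(X) >= 30) {
      sf <- suppressWarnings(scran::calculateSumFactors(X))
      if (any(!is.finite(sf)) || any(sf <= 0))
        sf <- depth / median(depth)
    } else {
      sf <- depth / median(depth)
    }
    X <- sweep(X, 2, sf, "/")
  }
  if (!is.null(nHVG) && nHVG < nrow(X)) {
    mu <- rowMeans(X)
    v <- apply(X, 1, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    keep <- order(disp, decreasing = TRUE)[seq_len(nHVG)]
    X <- X[sort(keep), , drop = FALSE]
  }
  if (logTransform) X <- log1p(X)
  attr(X, "droppedCells") <- dropped
  X
}

# k-nearest-neighbor graph on rows of X (union-of-neighborhoods,
# undirected). Unit edge weights by default; `snn = TRUE` weights each
# edge by the Jaccard overlap of the two cells' neighborhoods (shared
# nearest neighbors), which de-emphasizes spurious long-range links while
# keeping boundary edges between interleaved groups informative.
# Deterministic: distance ties resolved by row order.
.knnGraph <- function(X, k = 15,
                      metric = c("euclidean", "manhattan"),
                      snn = FALSE) {
  metric <- match.arg(metric)
  n <- nrow(X)
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k < number of cells", call. = FALSE)
  D <- as.matrix(dist(X, method = metric))
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    nbr[i, ] <- o[o != i][seq_len(k)]
  }
  el <- cbind(rep(seq_len(n), each = k), as.integer(t(nbr)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g <- igraph::simplify(g)
  if (snn) {
    # Jaccard of closed neighborhoods (cell + its k nearest)
    M <- matrix(FALSE, n, n)
    M[cbind(rep(seq_len(n), each = k), as.integer(t(nbr)))] <- TRUE
    diag(M) <- TRUE
    ee <- igraph::as_edgelist(g, names = FALSE)
    shared <- rowSums(M[ee[, 1], , drop = FALSE] &
                        M[ee[, 2], , drop = FALSE])
    igraph::E(g)$weight <- shared / (2 * (k + 1) - shared)
  } else {
    igraph::E(g)$weight <- 1
  }
  if (!is.null(rownames(X))) igraph::V(g)$name <- rownames(X)
  g
}

#' Cluster cells by Louvain community detection on a kNN graph
#'
#' Builds a k-nearest-neighbor graph on the rows of `X` and partitions it
#' with unseeded [ssLouvain()]. This is the control-only clustering step
#' of the pipeline, and also serves per-treatment clustering for the
#' joint variant.
#'
#' @param X Cells-by-genes matrix of preprocessed expression.
#' @param k Number of nearest neighbors (default 15).
#' @param gamma Louvain resolution (default 1).
#' @param metric Distance for the kNN graph.
#' @param snn Weight edges by shared-nearest-neighbor (Jaccard) overlap
#'   instead of unit weights.
#' @param seed RNG seed for Louvain traversal order.
#' @return Integer cluster label per cell (named by rownames of `X`).
#' @export
clusterCells <- function(X, k = 15, gamma = 1,
                         metric = c("euclidean", "manhattan"),
                         snn = FALSE, seed = 0) {
  X <- .assertMatrix(X)
  if (nrow(X) < k + 1)
    stop("need at least k+1 cells to cluster", call. = FALSE)
  g <- .knnGraph(X, k = k, metric = match.arg(metric), snn = snn)
  res <- ssLouvain(g, seeds = NULL, gamma = gamma, seed = seed)
  out <- res$membership
  names(out) <- rownames(X)
  out
}

#' Select representative cells by greedy facility-location maximization
#'
#' Chooses `budget` cells maximizing the submodular facility-location
#' objective \eqn{F(S) = \sum_v \max_{s \in S} \mathrm{sim}(v, s)} with an
#' RBF similarity on Euclidean distances (bandwidth = median pairwise
#' distance). Selection is stratified by cluster label: the budget is
#' split across labels proportionally to cluster size, with every label
#' retaining at least one cell, so small states survive subsampling. The
#' greedy maximizer of a monotone submodular function is within
#' \eqn{1 - 1/e} of the optimum.
#'
#' @param X Cells-by-genes matrix.
#' @param labels Cluster label per cell.
#' @param budget Total number of cells to retain.
#' @param seed RNG seed (used only to break exact ties).
#' @return Sorted integer indices of the selected cells.
#' @export
selectRepresentativeCells <- function(X, labels, budget, seed = 0) {
  X <- .assertMatrix(X)
  n <- nrow(X)
  if (length(labels) != n)
    stop("labels must have one entry per cell", call. = FALSE)
  if (budget > n) stop("budget exceeds number of cells", call. = FALSE)
  labs <- unique(labels)
  if (budget < length(labs))
    stop("budget smaller than the number of cluster labels", call. = FALSE)
  if (budget == n) return(seq_len(n))

  sizes <- as.numeric(table(labels)[as.character(labs)])
  alloc <- pmax(1, floor(budget * sizes / n))
  # distribute the remainder by largest fractional part
  while (sum(alloc) < budget) {
    fr <- budget * sizes / n - alloc
    i <- which.max(ifelse(alloc < sizes, fr, -Inf))
    alloc[i] <- alloc[i] + 1
  }
  while (sum(alloc) > budget) {
    i <- which.max(ifelse(alloc > 1, alloc - budget * sizes / n, -Inf))
    alloc[i] <- alloc[i] - 1
  }

  picked <- integer(0)
  for (li in seq_along(labs)) {
    idx <- which(labels == labs[li])
    b <- min(alloc[li], length(idx))
    if (b == length(idx)) {
      picked <- c(picked, idx)
      next
    }
    D <- as.matrix(dist(X[idx, , drop = FALSE]))
    h <- median(D[upper.tri(D)])
    if (!is.finite(h) || h == 0) h <- 1
    S <- exp(-D^2 / (2 * h^2))
    best <- numeric(length(idx))   # current max similarity to chosen set
    chosen <- integer(0)
    for (step in seq_len(b)) {
      gains <- colSums(pmax(S - best, 0))
      gains[chosen] <- -Inf
      chosen <- c(chosen, which.max(gains))
      best <- pmax(best, S[, chosen[length(chosen)]])
    }
    picked <- c(picked, idx[chosen])
  }
  sort(picked)
}

#' Pool per-treatment gene weights by elementwise maximum
#'
#' Reduces one weight vector per treatment to a single vector by taking
#' the per-gene maximum, so genes that are informative in any condition
#' (including condition-asymmetric states) keep their weight.
#'
#' @param ... Numeric weight vectors and/or [FeatureWeights-class]
#'   objects of equal length, or a single list of them.
#' @return Numeric vector of elementwise maxima.
#' @examples
#' poolWeights(c(1, 0), c(0, 2))  # c(1, 2)
#' @export
poolWeights <- function(...) {
  ws <- list(...)
  if (length(ws) == 1 && is.list(ws[[1]]) && !is(ws[[1]], "FeatureWeights"))
    ws <- ws[[1]]
  ws <- lapply(ws, function(w)
    if (is(w, "FeatureWeights")) geneWeights(w) else as.numeric(w))
  if (!length(ws)) stop("no weight vectors given", call. = FALSE)
  p <- unique(vapply(ws, length, integer(1)))
  if (length(p) != 1)
    stop("weight vectors must have equal length", call. = FALSE)
  do.call(pmax, ws)
}

#' Identify cell states across control and perturbed conditions
#'
#' Two-step control-guided clustering. Step one learns cluster-defining
#' genes: control cells are clustered alone (Louvain on a Euclidean kNN
#' graph) and the labels are fed to [ncfsFit()], which weights genes by
#' their predictiveness. In the `"control"` variant only control cells
#' are weighted; in the `"joint"` variant every treatment is clustered
#' and weighted independently and the weight vectors are max-pooled, so
#' genes marking treatment-only states are retained. Step two re-weights
#' the full expression matrix by the squared weights, builds a Manhattan
#' kNN graph in that learned metric, and runs [ssLouvain()] with control
#' labels immutable and all treated cells as singletons. Control cells
#' therefore keep their control-only labels (prefix `"C"`); treated cells
#' either join a control state or form novel states (prefix `"N"`).
#'
#' Feature weighting on more than `subsampleThreshold` cells uses a
#' representative subset chosen by [selectRepresentativeCells()].
#'
#' @param x A `SingleCellExperiment` (assay `"counts"`; treatment taken
#'   from `colData(x)[[treatment]]`) or a genes-by-cells count matrix.
#' @param treatment For a matrix: per-cell treatment vector. For a
#'   `SingleCellExperiment`: name of the `colData` column (default
#'   `"treatment"`).
#' @param control Treatment value regarded as the control condition.
#' @param variant `"control"` (weights from control cells only) or
#'   `"joint"` (per-treatment weights, max-pooled).
#' @param k Neighbors for kNN graphs (default 15).
#' @param snn Use shared-nearest-neighbor (Jaccard) edge weights in the
#'   kNN graphs instead of unit weights.
#' @param gamma Louvain resolution (default 1).
#' @param sigma,lambda,eta0,tol,maxIter Passed to [ncfsFit()].
#' @param subsampleThreshold,subsampleSize Cell count above which NCFS
#'   fits use a representative subset, and the subset size.
#' @param normalize,logTransform,nHVG,normMethod Passed to
#'   [preprocessCounts()].
#' @param seed Master RNG seed; per-stage child seeds are derived from it
#'   and echoed in the provenance.
#' @return A [StateAssignment-class] object.
#' @export
identifyStates <- function(x, treatment = "treatment", control = "control",
                           variant = c("control", "joint"),
                           k = 15, gamma = 1, snn = FALSE,
                           sigma = 1, lambda = 1, eta0 = 0.01,
                           tol = 1e-4, maxIter = 1000L,
                           subsampleThreshold = 2000, subsampleSize = 500,
                           normalize = TRUE, logTransform = TRUE,
                           nHVG = NULL,
                           normMethod = c("deconvolution", "total"),
                           seed = 0) {
  variant <- match.arg(variant)
  normMethod <- match.arg(normMethod)
  if (is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    cd <- SummarizedExperiment::colData(x)
    if (!treatment %in% colnames(cd))
      stop("colData column '", treatment, "' not found", call. = FALSE)
    treat <- as.character(cd[[treatment]])
  } else {
    counts <- x
    if (length(treatment) != ncol(counts))
      stop("treatment must have one entry per cell", call. = FALSE)
    treat <- as.character(treatment)
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (!control %in% treat)
    stop("control label '", control, "' not present in treatment",
         call. = FALSE)
  if (sum(treat == control) < 2)
    stop("need at least 2 control cells", call. = FALSE)

  Xp <- preprocessCounts(counts, normalize = normalize,
                         logTransform = logTransform, nHVG = nHVG,
                         method = normMethod)
  dropped <- attr(Xp, "droppedCells")
  if (length(dropped)) treat <- treat[-dropped]
  Xc <- t(Xp)                      # cells x genes
  Xs <- .minmaxScale(Xc)           # common [0,1] range; sigma = 1 applies

  seeds <- list(controlCluster = .childSeed(seed, 1),
                subsample = .childSeed(seed, 2),
                treatmentCluster = .childSeed(seed, 3),
                finalCluster = .childSeed(seed, 4))
  ctrlIdx <- which(treat == control)

  # step 1a: cluster controls alone
  kCtrl <- min(k, length(ctrlIdx) - 1)
  ctrlLabels <- clusterCells(Xs[ctrlIdx, , drop = FALSE], k = kCtrl,
                             gamma = gamma, metric = "euclidean",
                             snn = snn, seed = seeds$controlCluster)

  fitWeights <- function(Xsub, labs, childSeed) {
    if (length(unique(labs)) < 2) {
      warning("a single cluster was found; gene weights left at 1")
      return(new("FeatureWeights",
                 weights = setNames(rep(1, ncol(Xsub)), colnames(Xsub)),
                 sigma = sigma, lambda = lambda, trace = numeric(0),
                 converged = TRUE, nIter = 0L, scaling = "none"))
    }
    if (nrow(Xsub) > subsampleThreshold) {
      sel <- selectRepresentativeCells(Xsub, labs,
                                       budget = subsampleSize,
                                       seed = childSeed)
      Xsub <- Xsub[sel, , drop = FALSE]
      labs <- labs[sel]
    }
    ncfsFit(Xsub, labs, sigma = sigma, lambda = lambda, eta0 = eta0,
            tol = tol, maxIter = maxIter, scale = "none")
  }

  # step 1b: learn gene weights
  fits <- list()
  fits[[control]] <- fitWeights(Xs[ctrlIdx, , drop = FALSE], ctrlLabels,
                                seeds$subsample)
  if (variant == "joint") {
    for (tr in setdiff(unique(treat), control)) {
      idx <- which(treat == tr)
      if (length(idx) < 3) next
      kT <- min(k, length(idx) - 1)
      labsT <- clusterCells(Xs[idx, , drop = FALSE], k = kT, gamma = gamma,
                            metric = "euclidean", snn = snn,
                            seed = .childSeed(seeds$treatmentCluster,
                                              match(tr, unique(treat))))
      fits[[tr]] <- fitWeights(Xs[idx, , drop = FALSE], labsT,
                               .childSeed(seeds$subsample,
                                          match(tr, unique(treat))))
    }
  }
  pooled <- poolWeights(fits)
  names(pooled) <- colnames(Xs)

  ctrlNames <- rownames(Xs)[ctrlIdx]
  controlLabels <- setNames(paste0("C", ctrlLabels), ctrlNames)

  if (all(treat == control)) {
    labels <- setNames(controlLabels[rownames(Xs)], rownames(Xs))
    graph <- NULL
  } else {
    # step 2: transform, kNN in the learned metric, seeded clustering
    Xt <- applyGeneWeights(Xs, pooled)
    active <- which(pooled > 0)
    if (!length(active)) active <- seq_along(pooled)
    graph <- .knnGraph(Xt[, active, drop = FALSE], k = k,
                       metric = "manhattan", snn = snn)
    res <- ssLouvain(graph, seeds = controlLabels, gamma = gamma,
                     seed = seeds$finalCluster)
    labels <- res$labels
  }

  new("StateAssignment",
      labels = labels,
      controlLabels = controlLabels,
      weights = fits,
      pooledWeights = pooled,
      graph = if (is.null(graph)) list() else graph,
      provenance = list(variant = variant, control = control, k = k,
                        gamma = gamma, snn = snn,
                        sigma = sigma, lambda = lambda,
                        eta0 = eta0, tol = tol, maxIter = maxIter,
                        subsampleThreshold = subsampleThreshold,
                        subsampleSize = subsampleSize,
                        normalize = normalize, logTransform = logTransform,
                        nHVG = nHVG, normMethod = normMethod,
                        seed = seed, stageSeeds = seeds,
                        droppedCells = dropped))
}
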