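# Neighborhood component feature selection (NCFS): sparse per-gene
# weighting by gradient ascent on a regularized leave-one-out kernel
# classification objective.
#
# Weighted distance between cells i and j:
#   D_w(x_i, x_j) = sum_l w_l^2 |x_il - x_jl|
# Reference-point probabilities with exponential kernel K(z) = exp(-z/sigma):
#   p_ij = K(D_w(x_i, x_j)) / sum_{k != i} K(D_w(x_i, x_k)),  p_ii = 0
# Objective maximized over w:
#   xi(w) = sum_i sum_j y_ij p_ij  -  lambda * sum_l w_l^2

.checkLabels <- function(y, n, requireTwo = TRUE) {
  if (length(y) != n)
    stop("length of labels must equal the number of cells", call. = FALSE)
  if (anyNA(y)) stop("labels must not contain NA", call. = FALSE)
  yi <- as.integer(factor(y))
  if (requireTwo && length(unique(yi)) < 2)
    stop("at least 2 distinct labels are required", call. = FALSE)
  yi
}

#' Weighted Manhattan distance between two expression profiles
#'
#' Computes \eqn{D_w(x_i, x_j) = \sum_l w_l^2 |x_{il} - x_{jl}|}, the metric
#' in which NCFS evaluates leave-one-out classification. With unit weights
#' this is the Manhattan distance; genes with zero weight do not contribute.
#'
#' @param xi,xj Numeric expression vectors of equal length.
#' @param w Numeric weight vector of the same length.
#' @return A single nonnegative number.
#' @examples
#' weightedDistance(c(1, 2), c(3, 5), c(1, 1))  # Manhattan: 5
#' @export
weightedDistance <- function(xi, xj, w) {
  if (length(xi) != length(xj) || length(xi) != length(w))
    stop("xi, xj and w must have the same length", call. = FALSE)
  if (any(!is.finite(w))) stop("w must be finite", call. = FALSE)
  sum(w^2 * abs(xi - xj))
}

#' Reference-point probabilities and leave-one-out accuracy
#'
#' For each cell \eqn{i}, the probability that cell \eqn{j} is picked as its
#' reference point under the exponential kernel over weighted distances,
#' \eqn{p_{ij} = e^{-D_w(x_i,x_j)/\sigma} / \sum_{k\neq i}
#' e^{-D_w(x_i,x_k)/\sigma}}, with \eqn{p_{ii} = 0}. The per-cell
#' leave-one-out accuracy is \eqn{p_i = \sum_j y_{ij} p_{ij}} where
#' \eqn{y_{ij} = 1} iff cells \eqn{i,j} share a label. Rows are normalized
#' after a row-minimum shift (mathematically identical, robust to kernel
#' underflow); a fully non-finite row falls back to uniform off-diagonal
#' probabilities with a warning.
#'
#' @param X Cells-by-genes numeric matrix.
#' @param y Per-cell labels.
#' @param w Per-gene weight vector.
#' @param sigma Positive kernel width.
#' @return A list with `P` (row-stochastic cells-by-cells matrix, zero
#'   diagonal), `sameLabel` (binary matrix \eqn{y_{ij}}), and
#'   `perCellAccuracy`.
#' @export
referenceProbabilities <- function(X, y, w = rep(1, ncol(X)), sigma = 1) {
  X <- .assertMatrix(X)
  if (nrow(X) < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  yi <- .checkLabels(y, nrow(X), requireTwo = FALSE)
  res <- .ncfsObjGrad(X, yi, as.numeric(w), sigma, 0, FALSE, TRUE)
  if (res$nUnderflow > 0)
    warning(res$nUnderflow,
            " cell(s) had fully degenerate kernel rows; uniform fallback used")
  same <- outer(yi, yi, "==") * 1
  diag(same) <- 0
  list(P = res$P, sameLabel = same, perCellAccuracy = res$accuracy)
}

#' NCFS objective value
#'
#' The regularized leave-one-out accuracy
#' \eqn{\xi(w) = \sum_i p_i - \lambda \sum_l w_l^2}; see
#' [referenceProbabilities()] for \eqn{p_i}. With `lambda = 0` the value
#' lies in \eqn{[0, n]} for \eqn{n} cells.
#'
#' @inheritParams referenceProbabilities
#' @param lambda Nonnegative regularization strength.
#' @return A single number.
#' @export
ncfsObjective <- function(X, y, w, sigma = 1, lambda = 1) {
  X <- .assertMatrix(X)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  yi <- .checkLabels(y, nrow(X), requireTwo = FALSE)
  .ncfsObjGrad(X, yi, as.numeric(w), sigma, lambda, FALSE, FALSE)$objective
}

#' Analytic gradient of the NCFS objective
#'
#' Componentwise,
#' \deqn{\partial\xi/\partial w_l = 2 w_l \left[\frac{1}{\sigma}\sum_i
#'   \left(p_i \sum_{j\neq i} p_{ij} |x_{il}-x_{jl}| -
#'   \sum_j y_{ij} p_{ij} |x_{il}-x_{jl}|\right) - \lambda\right].}
#' Every component carries a factor \eqn{w_l}, so the all-zero weight
#' vector is a stationary point; fits therefore initialize at all-ones.
#'
#' @inheritParams ncfsObjective
#' @return Numeric vector of the same length as `w`.
#' @export
ncfsGradient <- function(X, y, w, sigma = 1, lambda = 1) {
  X <- .assertMatrix(X)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  yi <- .checkLabels(y, nrow(X), requireTwo = FALSE)
  .ncfsObjGrad(X, yi, as.numeric(w), sigma, lambda, TRUE, FALSE)$gradient
}

#' Fit sparse gene weights by gradient ascent
#'
#' Maximizes the regularized leave-one-out accuracy \eqn{\xi(w)} (see
#' [ncfsObjective()]) by gradient ascent from \eqn{w = 1} with an adaptive
#' step: the step size grows by 1% after each accepted (non-decreasing)
#' step and is halved on a rejected one, so the objective trace is
#' monotone. Weights are clamped to be nonnegative after every step —
#' distances depend on \eqn{w^2} so the sign is unidentifiable, and
#' clamping keeps the conventional "informative genes exceed weight 1"
#' reading meaningful. On data where only a few genes separate the
#' labels, regularization drives the remaining weights to zero.
#'
#' Genes are min-max scaled to \eqn{[0, 1]} by default so a single kernel
#' width applies to all of them; pass `scale = "none"` if the matrix is
#' already on a common scale. The fit is deterministic: there is no
#' internal randomness.
#'
#' @param X Cells-by-genes numeric matrix (library-normalized,
#'   log-transformed expression).
#' @param y Per-cell cluster labels; at least 2 distinct values.
#' @param sigma Kernel width (default 1, matched to min-max scaling).
#' @param lambda Regularization strength (default 1).
#' @param eta0 Initial step size (default 0.01).
#' @param tol Convergence tolerance on the absolute objective change
#'   between accepted steps (default 1e-4).
#' @param maxIter Maximum number of accepted steps (default 1000).
#' @param scale Feature scaling: `"minmax"` (default) or `"none"`.
#' @return A [FeatureWeights-class] object.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 10), 60, 10)
#' X[31:60, 1] <- X[31:60, 1] + 4   # gene 1 separates the two groups
#' fw <- ncfsFit(X, rep(1:2, each = 30), maxIter = 100)
#' which(geneWeights(fw) > 1)
#' @export
ncfsFit <- function(X, y, sigma = 1, lambda = 1, eta0 = 0.01,
                    tol = 1e-4, maxIter = 1000L,
                    scale = c("minmax", "none")) {
  X <- .assertMatrix(X)
  scale <- match.arg(scale)
  yi <- .checkLabels(y, nrow(X), requireTwo = TRUE)
  if (!(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  Xs <- if (scale == "minmax") .minmaxScale(X) else X

  p <- ncol(Xs)
  w <- rep(1, p)
  lr <- eta0
  cur <- .ncfsObjGrad(Xs, yi, w, sigma, lambda, TRUE, FALSE)
  if (!is.finite(cur$objective))
    stop("non-finite objective at initialization", call. = FALSE)
  trace <- cur$objective
  converged <- FALSE
  iter <- 0L

  while (iter < maxIter) {
    accepted <- FALSE
    for (half in seq_len(30L)) {
      wNew <- pmax(w + lr * cur$gradient, 0)
      # weights this small contribute < 1e-6 to any distance and, with
      # gradient proportional to w, cannot recover; zeroing them shrinks
      # the active gene set and the per-iteration cost
      wNew[wNew < 1e-3] <- 0
      cand <- .ncfsObjGrad(Xs, yi, wNew, sigma, lambda, TRUE, FALSE)
      if (is.finite(cand$objective) &&
          cand$objective >= trace[length(trace)]) {
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!accepted) {  # no ascent direction at any admissible step size
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    delta <- cand$objective - trace[length(trace)]
    w <- wNew
    cur <- cand
    trace <- c(trace, cand$objective)
    lr <- lr * 1.01
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }

  names(w) <- colnames(X)
  new("FeatureWeights", weights = w, sigma = sigma, lambda = lambda,
      trace = trace, converged = converged, nIter = iter, scaling = scale)
}

#' Re-weight an expression matrix by learned gene weights
#'
#' Scales column \eqn{l} by \eqn{w_l^2}, so that the Manhattan distance
#' between rows of the transformed matrix equals [weightedDistance()]
#' exactly: \eqn{\sum_l |w_l^2 x_{il} - w_l^2 x_{jl}| =
#' \sum_l w_l^2 |x_{il} - x_{jl}|}. Downstream neighbor graphs built with
#' Manhattan distance on the transformed matrix therefore operate in the
#' learned metric.
#'
#' @param X Cells-by-genes numeric matrix.
#' @param w Per-gene weight vector or a [FeatureWeights-class] object.
#' @return A matrix of the same dimensions as `X`.
#' @export
applyGeneWeights <- function(X, w) {
  if (is(w, "FeatureWeights")) w <- geneWeights(w)
  X <- .assertMatrix(X)
  if (length(w) != ncol(X))
    stop("length(w) must equal ncol(X)", call. = FALSE)
  sweep(X, 2, w^2, "*")
}
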