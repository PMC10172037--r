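#' Per-gene feature weights learned by neighborhood component feature
#' selection
#'
#' Holds the nonnegative per-gene weight vector learned by [ncfsFit()],
#' together with the kernel and regularization parameters, the trace of the
#' objective over accepted gradient-ascent steps, and convergence state.
#' Squared weights rescale gene axes, so distances between cells in the
#' weighted space are dominated by the highly weighted (cluster-defining)
#' genes; regularization drives uninformative genes to weight zero.
#'
#' @slot weights Named nonnegative numeric vector, one entry per gene.
#' @slot sigma Kernel width used for the exponential distance kernel.
#' @slot lambda Regularization strength of the L2 penalty on the weights.
#' @slot trace Objective value at initialization and after each accepted
#'   ascent step; non-decreasing.
#' @slot converged Whether the objective change fell below tolerance.
#' @slot nIter Number of accepted ascent steps performed.
#' @slot scaling Feature scaling applied to the input before fitting
#'   (`"minmax"` or `"none"`).
#'
#' @seealso [ncfsFit()], [geneWeights()], [applyGeneWeights()]
#' @export
setClass("FeatureWeights",
  representation(
    weights = "numeric",
    sigma = "numeric",
    lambda = "numeric",
    trace = "numeric",
    converged = "logical",
    nIter = "integer",
    scaling = "character"
  )
)

setValidity("FeatureWeights", function(object) {
  msg <- NULL
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and nonnegative")
  if (length(object@sigma) != 1 || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (length(object@lambda) != 1 || object@lambda < 0)
    msg <- c(msg, "lambda must be a single nonnegative number")
  if (length(object@trace) && any(!is.finite(object@trace)))
    msg <- c(msg, "objective trace must be finite")
  if (length(object@trace) > 1 && any(diff(object@trace) < -1e-8))
    msg <- c(msg, "objective trace must be non-decreasing")
  if (is.null(msg)) TRUE else msg
})

#' Cell-state assignment across control and perturbed conditions
#'
#' Result container returned by [identifyStates()]. Control cells keep the
#' labels found by clustering controls alone (prefixed `"C"`); perturbed
#' cells either join a control state or form novel communities (prefixed
#' `"N"`), so condition-asymmetric states are self-evident in the output.
#'
#' @slot labels Named character vector of final state labels, one per cell.
#' @slot controlLabels Named character vector of the initial control-only
#'   clustering (control cells only).
#' @slot weights List of [FeatureWeights-class] objects, one per treatment
#'   used for feature weighting.
#' @slot pooledWeights Numeric vector: elementwise maximum of the
#'   per-treatment weight vectors, used to transform the expression matrix.
#' @slot graph The weighted-space k-nearest-neighbor `igraph` used for the
#'   final semisupervised clustering.
#' @slot provenance List echoing the fully resolved configuration and all
#'   derived per-stage seeds.
#'
#' @seealso [identifyStates()], [stateLabels()], [controlStates()]
#' @export
setClass("StateAssignment",
  representation(
    labels = "character",
    controlLabels = "character",
    weights = "list",
    pooledWeights = "numeric",
    graph = "ANY",
    provenance = "list"
  )
)

setValidity("StateAssignment", function(object) {
  msg <- NULL
  ctrl <- names(object@controlLabels)
  if (!all(ctrl %in% names(object@labels)))
    msg <- c(msg, "every control cell must appear in the final labels")
  else if (!all(object@labels[ctrl] == object@controlLabels))
    msg <- c(msg, "control cells must retain their control-clustering labels")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FeatureWeights-class Compact display of weight sparsity and
#'   convergence state.
#' @param object A `FeatureWeights` object.
#' @export
setMethod("show", "FeatureWeights", function(object) {
  w <- object@weights
  cat("FeatureWeights over", length(w), "genes\n")
  cat(sprintf("  sigma = %g, lambda = %g, scaling = %s\n",
              object@sigma, object@lambda, object@scaling))
  cat(sprintf("  %d weights > 1, %d weights < 0.1 (%.1f%% near zero)\n",
              sum(w > 1), sum(w < 0.1), 100 * mean(w < 0.1)))
  cat(sprintf("  objective %.4f after %d accepted steps (%sconverged)\n",
              tail0(object@trace), object@nIter,
              if (object@converged) "" else "not "))
  invisible(object)
})

tail0 <- function(x) if (length(x)) x[length(x)] else NA_real_

#' @describeIn StateAssignment-class Summary of states per condition.
#' @param object A `StateAssignment` object.
#' @export
setMethod("show", "StateAssignment", function(object) {
  cat("StateAssignment for", length(object@labels), "cells\n")
  cat("  control states:",
      paste(sort(unique(object@controlLabels)), collapse = ", "), "\n")
  novel <- setdiff(unique(object@labels), unique(object@controlLabels))
  cat("  novel states:",
      if (length(novel)) paste(sort(novel), collapse = ", ") else "(none)",
      "\n")
  print(table(object@labels))
  invisible(object)
})

#' Accessors for fitted feature weights and state assignments
#'
#' `geneWeights()` returns the per-gene weight vector, `objectiveTrace()`
#' the objective values over accepted ascent steps, and `isConverged()` the
#' convergence flag of a [FeatureWeights-class] fit. `stateLabels()` and
#' `controlStates()` return the final and the control-only labels of a
#' [StateAssignment-class]; `featureWeights()` its per-treatment fits and
#' `pooledWeights()` the max-pooled weight vector; `provenance()` the
#' resolved configuration.
#'
#' @param object A `FeatureWeights` or `StateAssignment` object.
#' @return The corresponding component (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
geneWeights <- function(object) object@weights

#' @rdname accessors
#' @export
objectiveTrace <- function(object) object@trace

#' @rdname accessors
#' @export
isConverged <- function(object) object@converged

#' @rdname accessors
#' @export
stateLabels <- function(object) object@labels

#' @rdname accessors
#' @export
controlStates <- function(object) object@controlLabels

#' @rdname accessors
#' @export
featureWeights <- function(object) object@weights

#' @rdname accessors
#' @export
pooledWeights <- function(object) object@pooledWeights

#' @rdname accessors
#' @export
provenance <- function(object) object@provenance
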