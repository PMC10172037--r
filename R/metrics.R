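# Cluster-evaluation suite: ARI, LISI, population-specific F1,
# Davies-Bouldin with 0-1 scaling, Gini coefficient, and compositional
# G-test / Fisher testing with FDR control. Every scaled score maps to
# [0, 1] with 1 meaning stronger performance.

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two labelings,
#' computed from the pair-count contingency table. Symmetric and
#' invariant to relabeling; 1 for identical partitions, around 0 for
#' independent ones (negative values possible).
#'
#' @param a,b Label vectors of equal length.
#' @param clip Clip negative values to 0 (the \eqn{[0, 1]} report scale);
#'   default `FALSE` returns the raw index.
#' @return A single number \eqn{\le 1}.
#' @examples
#' ariScore(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: relabel-invariant
#' @export
ariScore <- function(a, b, clip = FALSE) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  out <- (sumij - expected) / (maxidx - expected)
  if (clip) max(0, out) else out
}

# Perplexity-calibrated neighbor weights: binary-search the Gaussian
# precision so that the entropy of the weight distribution over the kNN
# matches log(perplexity). Same calibration as t-SNE / LISI.
.perplexityWeights <- function(d2, perplexity, iter = 50) {
  lo <- 0; hi <- Inf; beta <- 1
  target <- log(perplexity)
  for (it in seq_len(iter)) {
    wts <- exp(-d2 * beta)
    s <- sum(wts)
    if (s == 0) { beta <- beta / 2; hi <- beta * 2; next }
    p <- wts / s
    h <- -sum(ifelse(p > 0, p * log(p), 0))
    if (abs(h - target) < 1e-5) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- (beta + lo) / 2 }
  }
  wts / sum(wts)
}

#' Local inverse Simpson's index of condition mixing
#'
#' For each cell, label probabilities \eqn{p_c} are accumulated over its
#' `k` nearest neighbors using a perplexity-calibrated Gaussian kernel
#' (or uniform weights with `uniform = TRUE`), and the inverse Simpson
#' index \eqn{1/\sum_c p_c^2} gives the effective number of conditions
#' in the neighborhood: 1 when neighbors all share the cell's condition,
#' up to the number of conditions \eqn{L} under perfect mixing. The
#' summary is the mean over cells, scaled to \eqn{[0,1]} as
#' \eqn{(\bar{ISI} - 1)/(L - 1)}.
#'
#' @param X Cells-by-genes matrix (neighborhoods are Euclidean).
#' @param labels Per-cell condition labels.
#' @param perplexity Kernel perplexity (default 30).
#' @param k Neighborhood size (default 90, i.e. 3x perplexity).
#' @param uniform Use uniform neighbor weights instead of the kernel.
#' @return List with `perCell`, `mean` and `scaled`.
#' @export
lisiScore <- function(X, labels, perplexity = 30, k = 90,
                      uniform = FALSE) {
  X <- .assertMatrix(X)
  n <- nrow(X)
  if (length(labels) != n)
    stop("labels must have one entry per cell", call. = FALSE)
  labels <- as.factor(labels)
  L <- nlevels(labels)
  k <- min(k, n - 1)
  if (!uniform && perplexity >= k)
    stop("perplexity must be smaller than the neighborhood size",
         call. = FALSE)
  D <- as.matrix(dist(X))
  isi <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i][seq_len(k)]
    w <- if (uniform) rep(1 / k, k)
         else .perplexityWeights(D[i, o]^2, perplexity)
    pc <- tapply(w, labels[o], sum, default = 0)
    isi[i] <- 1 / sum(pc^2)
  }
  m <- mean(isi)
  list(perCell = isi, mean = m,
       scaled = if (L > 1) (m - 1) / (L - 1) else NA_real_)
}

#' Population-specific F1 score
#'
#' Measures how well one ground-truth population is recovered: the
#' predicted cluster with the largest overlap with the target set is
#' selected (ties break to the larger overlap, then the smaller cluster)
#' and \eqn{F1 = 2|P \cap \hat{c}| / (|P| + |\hat{c}|)}. Applied to the
#' condition-unique, stimulated, or rare population this yields the
#' F1-Unique, F1-Stim and F1-Rare scores.
#'
#' @param truth Ground-truth labels.
#' @param predicted Predicted cluster labels.
#' @param target The ground-truth population of interest.
#' @return F1 in \eqn{[0, 1]}; 1 iff some cluster equals the target set.
#' @export
populationF1 <- function(truth, predicted, target) {
  if (length(truth) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  P <- truth == target
  if (!any(P)) stop("target population is empty in truth", call. = FALSE)
  cl <- unique(predicted)
  overlap <- vapply(cl, function(c0) sum(P & predicted == c0), numeric(1))
  size <- vapply(cl, function(c0) sum(predicted == c0), numeric(1))
  best <- order(-overlap, size)[1]
  unname(2 * overlap[best] / (sum(P) + size[best]))
}

#' Davies-Bouldin index with 0-1 scaling
#'
#' Standard Davies-Bouldin cluster validity:
#' \eqn{DB = \frac{1}{K}\sum_i \max_{j \neq i} (s_i + s_j)/d_{ij}} with
#' \eqn{s_i} the mean Euclidean distance of cluster members to their
#' centroid and \eqn{d_{ij}} the centroid distance. Lower raw values are
#' better; the scaled score \eqn{1/(1 + DB)} maps to \eqn{(0, 1]} with 1
#' meaning better clustering.
#'
#' @param X Cells-by-features matrix.
#' @param labels Cluster label per row.
#' @return List with `raw` and `scaled`.
#' @export
daviesBouldin <- function(X, labels) {
  X <- .assertMatrix(X)
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2) stop("need at least 2 clusters", call. = FALSE)
  cent <- matrix(0, K, ncol(X))
  s <- numeric(K)
  for (ki in seq_len(K)) {
    idx <- which(labels == levels(labels)[ki])
    cent[ki, ] <- colMeans(X[idx, , drop = FALSE])
    s[ki] <- mean(sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2,
                                     cent[ki, ])^2)))
  }
  Dc <- as.matrix(dist(cent))
  R <- outer(s, s, "+") / Dc
  diag(R) <- -Inf
  raw <- mean(apply(R, 1, max))
  list(raw = raw, scaled = 1 / (1 + raw))
}

#' Gini coefficient of population sizes
#'
#' \eqn{G = \sum_i\sum_j |x_i - x_j| / (2 n^2 \bar{x})}: 0 for equal
#' sizes, approaching 1 as one population dominates.
#'
#' @param sizes Nonnegative population sizes (sum > 0).
#' @return Gini coefficient in \eqn{[0, 1]}.
#' @examples
#' giniCoefficient(c(50, 150))  # 0.25
#' @export
giniCoefficient <- function(sizes) {
  if (any(sizes < 0)) stop("sizes must be nonnegative", call. = FALSE)
  if (sum(sizes) == 0) stop("sizes must not be all zero", call. = FALSE)
  n <- length(sizes)
  sum(abs(outer(sizes, sizes, "-"))) / (2 * n^2 * mean(sizes))
}

#' Treatment-dependence tests of cluster composition
#'
#' For each cluster, an omnibus G-test (likelihood-ratio chi-squared) of
#' the cluster-vs-rest by treatment contingency table asks whether
#' membership depends on treatment; p-values are Benjamini-Hochberg
#' corrected across clusters. For FDR-significant clusters, pairwise
#' two-sided Fisher's exact tests between treatments localize the effect
#' (BH-corrected within the pairwise family), reporting the
#' enriched/depleted direction from the odds of cluster membership.
#' Clusters with a zero margin are skipped with a note.
#'
#' @param tab Clusters-by-treatments contingency matrix of nonnegative
#'   integer counts.
#' @param alpha FDR threshold (default 0.05).
#' @return List with `omnibus` (data.frame: cluster, G, df, p, q,
#'   significant, note) and `pairwise` (data.frame: cluster, treatment
#'   pair, odds ratio, p, q, direction).
#' @export
compositionTest <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (is.null(rownames(tab))) rownames(tab) <- seq_len(nrow(tab))
  if (is.null(colnames(tab))) colnames(tab) <- seq_len(ncol(tab))
  total <- colSums(tab)
  omni <- data.frame(cluster = rownames(tab), G = NA_real_,
                     df = NA_integer_, p = NA_real_, q = NA_real_,
                     significant = FALSE, note = "",
                     stringsAsFactors = FALSE)
  for (r in seq_len(nrow(tab))) {
    two <- rbind(tab[r, ], total - tab[r, ])
    if (any(rowSums(two) == 0) || any(colSums(two) == 0)) {
      omni$note[r] <- "zero margin; skipped"
      next
    }
    E <- outer(rowSums(two), colSums(two)) / sum(two)
    G <- 2 * sum(ifelse(two > 0, two * log(two / E), 0))
    omni$G[r] <- G
    omni$df[r] <- ncol(two) - 1L
    omni$p[r] <- pchisq(G, df = ncol(two) - 1L, lower.tail = FALSE)
  }
  tested <- !is.na(omni$p)
  omni$q[tested] <- p.adjust(omni$p[tested], method = "BH")
  omni$significant <- !is.na(omni$q) & omni$q < alpha

  pw <- data.frame(cluster = character(0), pair = character(0),
                   oddsRatio = numeric(0), p = numeric(0),
                   q = numeric(0), direction = character(0),
                   stringsAsFactors = FALSE)
  trts <- colnames(tab)
  for (r in which(omni$significant)) {
    for (i in seq_len(ncol(tab) - 1)) {
      for (j in seq((i + 1), ncol(tab))) {
        m <- matrix(c(tab[r, i], total[i] - tab[r, i],
                      tab[r, j], total[j] - tab[r, j]), 2, 2)
        ft <- fisher.test(m)
        prop <- c(tab[r, i] / total[i], tab[r, j] / total[j])
        dir <- if (prop[1] > prop[2])
          paste0("enriched in ", trts[i]) else paste0("enriched in ", trts[j])
        pw <- rbind(pw, data.frame(
          cluster = rownames(tab)[r],
          pair = paste(trts[i], "vs", trts[j]),
          oddsRatio = unname(ft$estimate), p = ft$p.value,
          q = NA_real_, direction = dir, stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(pw)) pw$q <- p.adjust(pw$p, method = "BH")
  list(omnibus = omni, pairwise = pw)
}

#' Score a clustering against ground truth and treatment mixing
#'
#' Convenience wrapper assembling the evaluation suite into one report:
#' raw and clipped ARI, mean and scaled LISI over treatments, optional
#' population-specific F1 scores, Davies-Bouldin (raw and scaled), and
#' the Gini coefficient of predicted cluster sizes. All scaled fields
#' lie in \eqn{[0, 1]} with 1 meaning stronger performance.
#'
#' @param truth Ground-truth state labels.
#' @param predicted Predicted cluster labels.
#' @param treatment Per-cell treatment labels (for LISI); `NULL` skips.
#' @param X Cells-by-genes matrix (for LISI/DB); `NULL` skips both.
#' @param f1Targets Named character vector of ground-truth populations to
#'   score with [populationF1()] (e.g. `c(unique = "pop4")`).
#' @param perplexity,k Passed to [lisiScore()].
#' @return Named list of scores.
#' @export
scoreClustering <- function(truth, predicted, treatment = NULL, X = NULL,
                            f1Targets = NULL, perplexity = 30, k = 90) {
  out <- list(ari = ariScore(truth, predicted),
              ariScaled = ariScore(truth, predicted, clip = TRUE))
  if (!is.null(X) && !is.null(treatment)) {
    li <- lisiScore(X, treatment, perplexity = perplexity, k = k)
    out$lisiMean <- li$mean
    out$lisiScaled <- li$scaled
  }
  if (!is.null(X) && length(unique(predicted)) > 1) {
    db <- daviesBouldin(X, predicted)
    out$dbRaw <- db$raw
    out$dbScaled <- db$scaled
  }
  if (!is.null(f1Targets)) {
    f1 <- vapply(f1Targets, function(t0) populationF1(truth, predicted, t0),
                 numeric(1))
    names(f1) <- paste0("f1_", names(f1Targets))
    out <- c(out, as.list(f1))
  }
  out$gini <- giniCoefficient(as.numeric(table(predicted)))
  out
}
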