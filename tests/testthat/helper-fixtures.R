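# Fixtures and independent oracles used across test files.

# Two Gaussian blobs separated only in the first `nInformative` genes.
makeBlobs <- function(n = 200, p = 100, nInformative = 5, shift = 3,
                      seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(1:2, length.out = n)
  X[y == 2, seq_len(nInformative)] <-
    X[y == 2, seq_len(nInformative)] + shift
  list(X = X, y = y)
}

# Independent brute-force evaluation of the NCFS objective: direct
# translation of the formula, no shared code with the package internals.
bruteObjective <- function(X, y, w, sigma, lambda) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    K <- vapply(seq_len(n), function(j) {
      if (j == i) return(0)
      exp(-sum(w^2 * abs(X[i, ] - X[j, ])) / sigma)
    }, numeric(1))
    p <- K / sum(K)
    total <- total + sum(p[y == y[i] & seq_len(n) != i])
  }
  total - lambda * sum(w^2)
}

# Two disconnected triangles: nodes 1:3 and 4:6.
twoTriangles <- function() {
  list(n = 6L,
       edges = cbind(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6), 1))
}

# All set partitions of 1..n as membership vectors (Bell(n) of them).
allPartitions <- function(n) {
  parts <- list(list(1L))
  if (n > 1) {
    for (k in 2:n) {
      nxt <- list()
      for (p in parts) {
        for (b in seq_along(p)) {
          q <- p
          q[[b]] <- c(q[[b]], k)
          nxt[[length(nxt) + 1]] <- q
        }
        nxt[[length(nxt) + 1]] <- c(p, list(k))
      }
      parts <- nxt
    }
  }
  lapply(parts, function(p) {
    memb <- integer(n)
    for (b in seq_along(p)) memb[p[[b]]] <- b
    memb
  })
}

# Direct-formula modularity, independent of the package implementation.
bruteModularity <- function(n, edges, memb, gamma = 1) {
  m <- sum(edges[, 3])
  k <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    if (i == j) k[i] <- k[i] + 2 * w
    else { k[i] <- k[i] + w; k[j] <- k[j] + w }
  }
  q <- 0
  for (c0 in unique(memb)) {
    inC <- memb == c0
    ec <- sum(edges[inC[edges[, 1]] & inC[edges[, 2]], 3])
    dc <- sum(k[inC])
    q <- q + ec / m - gamma * (dc / (2 * m))^2
  }
  q
}

# Exhaustive modularity optimum over all partitions (small n only).
bestModularity <- function(n, edges, gamma = 1) {
  max(vapply(allPartitions(n), function(memb)
    bruteModularity(n, edges, memb, gamma), numeric(1)))
}

# Random connected-ish graph as an edge list.
randomGraph <- function(n, pEdge = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < pEdge
  # ensure no isolated node: chain fallback
  edges <- rbind(pairs[keep, , drop = FALSE], cbind(1:(n - 1), 2:n))
  edges <- unique(edges)
  cbind(edges, 1)
}

# Brute-force ARI by explicit pair counting over all cell pairs.
bruteARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(1)
  (n11 - expected) / (maxidx - expected)
}

# Independent textbook Davies-Bouldin.
bruteDB <- function(X, labels) {
  labs <- unique(labels)
  K <- length(labs)
  cent <- t(vapply(labs, function(l)
    colMeans(X[labels == l, , drop = FALSE]), numeric(ncol(X))))
  s <- vapply(seq_len(K), function(i) {
    pts <- X[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cent[i, ], nrow(pts), ncol(X),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(K)) {
    ri <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      ri <- max(ri, (s[i] + s[j]) / d)
    }
    db <- db + ri
  }
  db / K
}
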