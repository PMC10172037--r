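# Semisupervised Louvain community detection: standard modularity
# optimization (local moving + aggregation) over an undirected weighted
# graph, restricted so that designated nodes hold immutable community
# labels. Immutable nodes never move; a community containing an immutable
# node carries that label through aggregation, so two distinct immutable
# labels can never merge. Mutable nodes start as singletons.

# Normalize graph input to list(n, edges, names). Edges: 3-column matrix
# (i, j, w) with 1-based ids, each unordered pair once, self-loops allowed.
.asEdgeList <- function(graph) {
  if (igraph::is_igraph(graph)) {
    n <- igraph::vcount(graph)
    if (n == 0) stop("empty graph", call. = FALSE)
    el <- igraph::as_edgelist(graph, names = FALSE)
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    nm <- igraph::V(graph)$name
    edges <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), w)
  } else if (is.list(graph) && !is.null(graph$n)) {
    n <- as.integer(graph$n)
    if (n == 0) stop("empty graph", call. = FALSE)
    e <- graph$edges
    if (is.null(e) || nrow(e) == 0) {
      edges <- matrix(numeric(0), 0, 3)
    } else {
      e <- as.matrix(e)
      if (ncol(e) == 2) e <- cbind(e, 1)
      if (any(e[, 1] < 1 | e[, 1] > n | e[, 2] < 1 | e[, 2] > n))
        stop("edge endpoints outside 1..n", call. = FALSE)
      if (any(e[, 3] < 0)) stop("edge weights must be >= 0", call. = FALSE)
      edges <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), e[, 3])
    }
    nm <- graph$names
  } else {
    stop("graph must be an igraph object or list(n, edges)", call. = FALSE)
  }
  # collapse duplicate pairs
  if (nrow(edges) > 1) {
    key <- edges[, 1] * (n + 1) + edges[, 2]
    if (anyDuplicated(key)) {
      w <- rowsum(edges[, 3], key)
      k <- as.numeric(rownames(w))
      edges <- cbind((k - k %% (n + 1)) / (n + 1), k %% (n + 1), w[, 1])
    }
  }
  list(n = n, edges = edges, names = nm)
}

# Node strengths (self-loops count twice) and self-loop weights.
.graphStrength <- function(n, edges) {
  k <- numeric(n)
  selfw <- numeric(n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
      if (i == j) {
        selfw[i] <- selfw[i] + w
        k[i] <- k[i] + 2 * w
      } else {
        k[i] <- k[i] + w
        k[j] <- k[j] + w
      }
    }
  }
  list(k = k, selfw = selfw)
}

#' Modularity of a graph partition
#'
#' Newman–Girvan modularity with a resolution parameter:
#' \deqn{Q = \sum_c \left[\frac{e_c}{m} -
#'   \gamma\left(\frac{d_c}{2m}\right)^2\right]}
#' where \eqn{e_c} is the total weight of edges inside community \eqn{c}
#' (self-loops counted once), \eqn{d_c} the total strength of its nodes
#' (self-loops counted twice), and \eqn{m} the total edge weight.
#'
#' @param graph An `igraph` object (edge attribute `weight` honored,
#'   default 1) or a `list(n, edges)` with a 3-column edge matrix.
#' @param membership Integer-like community id per node.
#' @param gamma Resolution parameter (default 1).
#' @return Modularity value in \eqn{[-1, 1]}; invariant to community
#'   relabeling.
#' @export
graphModularity <- function(graph, membership, gamma = 1) {
  g <- .asEdgeList(graph)
  if (length(membership) != g$n)
    stop("membership must have one entry per node", call. = FALSE)
  m <- sum(g$edges[, 3])
  if (m <= 0) stop("modularity undefined for a graph with no edge weight",
                   call. = FALSE)
  comm <- as.integer(factor(membership))
  st <- .graphStrength(g$n, g$edges)
  intra <- g$edges[comm[g$edges[, 1]] == comm[g$edges[, 2]], 3]
  ec <- sum(intra)
  dc2 <- tapply(st$k, comm, sum)^2
  ec / m - gamma * sum(dc2) / (4 * m^2)
}

# One full local-moving pass in seeded order. Only mutable nodes move;
# a move is accepted iff it strictly increases Q; ties between equal-gain
# target communities break to the lowest community id. Returns updated
# community vector, community strengths and the number of moves.
.localMovePass <- function(adj, adjw, k, m, comm, mutable, gamma,
                           ord, commTot) {
  moved <- 0L
  for (v in ord) {
    if (!mutable[v]) next
    nbrs <- adj[[v]]
    if (!length(nbrs)) next
    ws <- adjw[[v]]
    cv <- comm[v]
    commTot[cv] <- commTot[cv] - k[v]
    cc <- comm[nbrs]
    cand <- unique(c(cc, cv))
    kv2c <- vapply(cand, function(c0) sum(ws[cc == c0]), numeric(1))
    gain <- kv2c / m - gamma * k[v] * commTot[cand] / (2 * m^2)
    best <- cand[order(-gain, cand)][1]
    if (best != cv && gain[match(best, cand)] >
        gain[match(cv, cand)] + 1e-12) {
      comm[v] <- best
      commTot[best] <- commTot[best] + k[v]
      moved <- moved + 1L
    } else {
      commTot[cv] <- commTot[cv] + k[v]
    }
  }
  list(comm = comm, commTot = commTot, moved = moved)
}

# Collapse communities into super-nodes. Inter-community weights are
# summed; intra-community weight (including self-loops) becomes the
# super-node self-loop, so total weight m is preserved. A super-node is
# immutable iff its community contains an immutable node and carries that
# label; two distinct immutable labels in one community is asserted
# unreachable.
.aggregateGraph <- function(n, edges, comm, immLabel) {
  comms <- sort(unique(comm))
  map <- match(comm, comms)
  K <- length(comms)
  newImm <- rep(NA_integer_, K)
  for (c0 in seq_len(K)) {
    labs <- unique(immLabel[map == c0])
    labs <- labs[!is.na(labs)]
    if (length(labs) > 1)
      stop("internal error: two immutable labels merged into one community")
    if (length(labs) == 1) newImm[c0] <- labs
  }
  if (nrow(edges)) {
    ci <- map[edges[, 1]]
    cj <- map[edges[, 2]]
    lo <- pmin(ci, cj)
    hi <- pmax(ci, cj)
    key <- lo * (K + 1) + hi
    w <- rowsum(edges[, 3], key)
    kk <- as.numeric(rownames(w))
    newEdges <- cbind((kk - kk %% (K + 1)) / (K + 1), kk %% (K + 1), w[, 1])
  } else {
    newEdges <- matrix(numeric(0), 0, 3)
  }
  list(n = K, edges = newEdges, map = map, immLabel = newImm)
}

.buildAdj <- function(n, edges) {
  adj <- vector("list", n)
  adjw <- vector("list", n)
  off <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(off)) {
    both <- rbind(off, off[, c(2, 1, 3), drop = FALSE])
    sp <- split(seq_len(nrow(both)), both[, 1])
    for (nm in names(sp)) {
      v <- as.integer(nm)
      adj[[v]] <- as.integer(both[sp[[nm]], 2])
      adjw[[v]] <- both[sp[[nm]], 3]
    }
  }
  list(adj = adj, adjw = adjw)
}

#' Louvain clustering with immutable seed labels
#'
#' Optimizes modularity by the Louvain heuristic (repeated local moving
#' and graph aggregation) while holding seeded nodes' community labels
#' fixed. Nodes sharing a seed label start in one community and never
#' move; unseeded nodes start as singletons and may join a seeded
#' community or form novel ones. Communities carrying two distinct seed
#' labels can never merge, so every seed label survives to the output.
#' With no seeds this is plain Louvain clustering.
#'
#' Node traversal order in each local-moving pass is a random permutation
#' drawn from `seed`, so results are reproducible; equal-gain moves break
#' to the lowest community id.
#'
#' @param graph An `igraph` object or `list(n, edges)` (3-column edge
#'   matrix `i, j, weight`); undirected, weights nonnegative.
#' @param seeds Seed labels: a vector with one entry per node, `NA` for
#'   unseeded (mutable) nodes, or a named vector over a subset of vertex
#'   names. `NULL` (default) seeds nothing.
#' @param gamma Resolution parameter (default 1).
#' @param seed RNG seed for traversal order (default 0).
#' @param restarts Number of independent seeded runs; the partition with
#'   the highest modularity is returned (default 5). Local moving is
#'   greedy and can stall in a local optimum on some traversal orders;
#'   restarting from different seeded orders and keeping the best is a
#'   standard remedy that stays deterministic given `seed`.
#' @return A list with `labels` (character per node: seed labels
#'   propagated, novel communities `"N1"`, `"N2"`, ... in order of first
#'   appearance), `membership` (integer community ids), `modularity`, and
#'   `nCommunities`.
#' @examples
#' g <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6), directed = FALSE)
#' ssLouvain(g)$membership      # the two triangles
#' @export
ssLouvain <- function(graph, seeds = NULL, gamma = 1, seed = 0,
                      restarts = 5) {
  g <- .asEdgeList(graph)
  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    res <- .ssLouvainOnce(g, seeds = seeds, gamma = gamma,
                          seed = .childSeed(seed, 17 * r))
    if (is.null(best) || (!is.na(res$modularity) &&
                          res$modularity > best$modularity + 1e-12))
      best <- res
    if (is.na(best$modularity)) break  # no edges: nothing to optimize
  }
  best
}

.ssLouvainOnce <- function(g, seeds, gamma, seed) {
  n <- g$n

  seedVec <- rep(NA_character_, n)
  if (!is.null(seeds)) {
    if (!is.null(names(seeds)) && !is.null(g$names)) {
      idx <- match(names(seeds), g$names)
      if (anyNA(idx))
        stop("seed names not found among graph vertices", call. = FALSE)
      seedVec[idx] <- as.character(seeds)
    } else if (length(seeds) == n) {
      seedVec <- as.character(seeds)
    } else {
      stop("seeds must be length-n or named by vertex", call. = FALSE)
    }
  }
  seeded <- !is.na(seedVec)
  seedLevels <- unique(seedVec[seeded])

  m <- sum(g$edges[, 3])
  # initial node-level partition: one community per seed label, singletons
  comm <- integer(n)
  comm[seeded] <- match(seedVec[seeded], seedLevels)
  comm[!seeded] <- length(seedLevels) + seq_len(sum(!seeded))
  immLabel <- ifelse(seeded, comm, NA_integer_)

  if (m > 0) {
    nn <- n
    edges <- g$edges
    nodeOf <- seq_len(n)
    mutable <- !seeded
    level <- 0L
    repeat {
      level <- level + 1L
      st <- .graphStrength(nn, edges)
      a <- .buildAdj(nn, edges)
      commTot <- numeric(max(comm))
      agg0 <- rowsum(st$k, comm)
      commTot[as.integer(rownames(agg0))] <- agg0[, 1]
      totalMoved <- 0L
      pass <- 0L
      repeat {
        pass <- pass + 1L
        ord <- .withSeed(.childSeed(seed, level * 131 + pass),
                         sample.int(nn))
        res <- .localMovePass(a$adj, a$adjw, st$k, m, comm, mutable,
                              gamma, ord, commTot)
        comm <- res$comm
        commTot <- res$commTot
        totalMoved <- totalMoved + res$moved
        if (res$moved == 0L || pass >= 100L) break
      }
      if (totalMoved == 0L) break
      ag <- .aggregateGraph(nn, edges, comm, immLabel)
      nodeOf <- ag$map[nodeOf]        # supernode now holding each cell
      noReduce <- ag$n == nn
      nn <- ag$n
      edges <- ag$edges
      immLabel <- ag$immLabel
      mutable <- is.na(immLabel)
      comm <- seq_len(nn)
      if (noReduce) break
    }
    membership <- comm[nodeOf]
  } else {
    membership <- comm
  }

  # canonical ids and labels: seeded communities keep their seed label,
  # novel communities numbered in order of first appearance
  uniq <- unique(membership)
  membership <- match(membership, uniq)
  labels <- character(n)
  novel <- 0L
  labOfComm <- character(length(uniq))
  for (c0 in seq_along(uniq)) {
    members <- which(membership == c0)
    sl <- unique(seedVec[members][seeded[members]])
    if (length(sl) > 1)
      stop("internal error: distinct seed labels share a community")
    if (length(sl) == 1) {
      labOfComm[c0] <- sl
    } else {
      novel <- novel + 1L
      labOfComm[c0] <- paste0("N", novel)
    }
  }
  labels <- labOfComm[membership]
  if (!is.null(g$names)) names(labels) <- g$names
  Q <- if (m > 0) graphModularity(g, membership, gamma) else NA_real_
  list(labels = labels, membership = membership, modularity = Q,
       nCommunities = length(uniq))
}
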