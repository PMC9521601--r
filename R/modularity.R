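# Newman-Girvan modularity and its greedy agglomerative maximization.
# Q = (1/2m) * sum_ij [A_ij - k_i k_j / (2m)] * delta(c_i, c_j),
# the standard normalized form (the one community-detection libraries
# compute).  High Q of an inter-brain graph means the two subjects'
# channels separate into isolated groups, i.e. a LACK of cross-brain
# integration; low Q means coactivation.

# Weighted or binary symmetric adjacency for modularity computations.
.mod_adjacency <- function(graph, weighted = FALSE) {
  A <- .binary_adjacency(graph)
  if (weighted && nrow(graph$edges)) {
    ids <- graph$nodes$node
    i <- match(paste0("T:", graph$edges$teacher), ids)
    j <- match(paste0("C:", graph$edges$child), ids)
    w <- abs(graph$edges$rho)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Modularity of a partition
#'
#' @param graph an [interbrain_graph] with at least one edge.
#' @param partition named vector mapping every node id (`T:`/`C:`
#'   prefixed) to a community label.
#' @param weighted use `|rho|` edge weights instead of the binary graph.
#' @return Modularity Q (dimensionless, <= 1; 0 for the single-community
#'   partition).
#' @export
modularity <- function(graph, partition, weighted = FALSE) {
  if (n_edges(graph) == 0)
    stop("modularity is undefined on an edgeless graph")
  ids <- graph$nodes$node
  if (!all(ids %in% names(partition)))
    stop("partition must assign every node: missing ",
         paste(setdiff(ids, names(partition)), collapse = ", "))
  memb <- partition[ids]
  A <- .mod_adjacency(graph, weighted)
  k <- rowSums(A)
  m2 <- sum(k)                       # 2m
  S <- outer(memb, memb, "==")
  sum((A - outer(k, k) / m2) * S) / m2
}

#' Single-community and all-singleton partitions
#'
#' @param graph an [interbrain_graph].
#' @return Named vector over all nodes.
#' @export
singleton_partition <- function(graph)
  stats::setNames(graph$nodes$node, graph$nodes$node)

#' @rdname singleton_partition
#' @export
trivial_partition <- function(graph)
  stats::setNames(rep("all", nrow(graph$nodes)), graph$nodes$node)

#' Greedy modularity maximization
#'
#' Agglomerative search: every non-isolated node starts in its own
#' community; the pair of communities whose merge gives the largest Q
#' increase is merged repeatedly (ties broken by the lexicographically
#' smallest community-label pair, so the result is deterministic) until a
#' single community remains, and the best Q seen along the path is
#' returned.  Isolated nodes stay singleton communities.
#'
#' An edgeless graph has no modularity structure to optimize; it is the
#' extreme of the "no relevant inter-brain connections" scale and is
#' assigned the sentinel value `edgeless_q` (default 1, the supremum of
#' `1 - 1/m` over disjoint-edge graphs) with the all-singleton partition.
#'
#' @param graph an [interbrain_graph].
#' @param weighted use `|rho|` edge weights.
#' @param edgeless_q sentinel Q for edgeless graphs.
#' @return List with elements `partition` (named vector) and `q`.
#' @export
max_modularity <- function(graph, weighted = FALSE, edgeless_q = 1) {
  if (n_edges(graph) == 0)
    return(list(partition = singleton_partition(graph), q = edgeless_q))
  A_full <- .mod_adjacency(graph, weighted)
  deg <- rowSums(A_full)
  active <- which(deg > 0)
  A <- A_full[active, active, drop = FALSE]
  ids <- graph$nodes$node[active]
  n <- length(ids)
  k <- rowSums(A)
  m2 <- sum(k)
  # M[u, v] = sum of (A_ij - k_i k_j / 2m) / 2m over i in u, j in v;
  # merging u and v changes Q by 2 * M[u, v]; Q = sum over communities of
  # their diagonal entries.
  M <- (A - outer(k, k) / m2) / m2
  labels <- ids                      # community label = member node id (min)
  memb <- stats::setNames(ids, ids)  # node -> community label
  q <- sum(diag(M))                  # all-singleton Q (negative)
  best_q <- q
  best_memb <- memb
  alive <- rep(TRUE, n)
  while (sum(alive) > 1) {
    idx <- which(alive)
    Msub <- M[idx, idx, drop = FALSE]
    diag(Msub) <- -Inf
    dq <- 2 * Msub
    mx <- max(dq)
    cand <- which(dq == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    l1 <- labels[idx[cand[, 1]]]; l2 <- labels[idx[cand[, 2]]]
    lo <- pmin(l1, l2); hi <- pmax(l1, l2)
    pick <- order(lo, hi)[1]
    u <- idx[cand[pick, 1]]; v <- idx[cand[pick, 2]]
    # merge v into u
    M[u, ] <- M[u, ] + M[v, ]
    M[, u] <- M[, u] + M[, v]
    alive[v] <- FALSE
    new_lab <- min(labels[u], labels[v])
    memb[memb %in% c(labels[u], labels[v])] <- new_lab
    labels[u] <- new_lab
    q <- q + mx
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  # isolated nodes: singleton communities labelled by themselves
  part <- singleton_partition(graph)
  part[names(best_memb)] <- best_memb
  list(partition = part, q = best_q)
}
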