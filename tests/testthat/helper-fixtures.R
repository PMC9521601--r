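# Shared fixtures and independent oracles for the suite.

# small montages with generic channel names on a grid layout
toy_montage <- function(n, role) {
  channel_montage(paste0(toupper(substr(role, 1, 1)), seq_len(n)),
                  cbind(x = seq_len(n) / n, y = rep(0.5, n)), role)
}

# dyad of pure white-noise recordings (independent subjects)
noise_dyad <- function(tt = 300, nt = 18, nc = 18, seed = 1,
                       dyad_id = "noise") {
  set.seed(seed)
  tm <- if (nt == 18) default_montage("teacher") else toy_montage(nt, "teacher")
  cm <- if (nc == 18) default_montage("child") else toy_montage(nc, "child")
  validate_dyad(
    subject_recording(matrix(rnorm(tt * nt), tt, nt), tm),
    subject_recording(matrix(rnorm(tt * nc), tt, nc), cm),
    dyad_id)
}

# random bipartite inter-brain graph with nt + nc nodes
random_graph <- function(nt, nc, p_edge, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- toy_montage(nt, "teacher"); cm <- toy_montage(nc, "child")
  pairs <- expand.grid(teacher = tm$channels, child = cm$channels,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < p_edge
  interbrain_graph(tm$channels, cm$channels, pairs[keep, , drop = FALSE])
}

# graph from an explicit list of (teacher-index, child-index) pairs
pair_graph <- function(nt, nc, t_idx, c_idx) {
  tm <- toy_montage(nt, "teacher"); cm <- toy_montage(nc, "child")
  interbrain_graph(tm$channels, cm$channels,
                   data.frame(teacher = tm$channels[t_idx],
                              child = cm$channels[c_idx]))
}

# ---- independent oracles ----------------------------------------------

# Newman-Girvan modularity by direct double-sum over all node pairs
# (including i = j), written against the formula, not the implementation.
oracle_modularity <- function(graph, membership) {
  ids <- graph$nodes$node
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(graph$edges))) {
    i <- which(ids == paste0("T:", graph$edges$teacher[r]))
    j <- which(ids == paste0("C:", graph$edges$child[r]))
    A[i, j] <- A[j, i] <- 1
  }
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[[ids[i]]] == membership[[ids[j]]])
      q <- q + A[i, j] - k[i] * k[j] / m2
  unname(q / m2)
}

# all set partitions of n elements as restricted-growth membership vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive maximum modularity over every partition of the graph's nodes
oracle_max_modularity <- function(graph) {
  ids <- graph$nodes$node
  n <- length(ids)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- which(ids == paste0("T:", graph$edges$teacher[r]))
    j <- which(ids == paste0("C:", graph$edges$child[r]))
    A[i, j] <- A[j, i] <- 1
  }
  k <- rowSums(A); m2 <- sum(k)
  B <- (A - outer(k, k) / m2) / m2
  parts <- all_partitions(n)
  best <- -Inf
  for (p in parts) {
    q <- sum(B[outer(p, p, "==")])
    if (q > best) best <- q
  }
  best
}
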