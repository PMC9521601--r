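# Hub ranking: eigenvector centrality (dominant eigenvector of the binary
# adjacency) and cross-dyad aggregation of degree centrality into node
# count / node relevance.

# round-half-up to integer: 12.5 -> 13 (base round() is round-half-even)
.round_half_up <- function(x) floor(x + 0.5)

#' Eigenvector centrality by power iteration
#'
#' Scores are the nonnegative dominant eigenvector of the binary adjacency
#' normalized so the maximum is 1.  Iteration starts from the uniform
#' positive vector and runs on `A + I`: inter-brain graphs are bipartite,
#' whose spectra are symmetric about zero, and the unit shift removes the
#' resulting period-2 oscillation without changing any eigenvector.
#' Isolated nodes (and components of smaller spectral radius) score 0 in
#' the limit.
#'
#' @param graph an [interbrain_graph] with at least one edge.
#' @param tol convergence tolerance on the max absolute change of the
#'   normalized scores (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return Named numeric vector of scores in \[0, 1\], max exactly 1.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 10000) {
  if (n_edges(graph) == 0)
    stop("eigenvector centrality is undefined on an edgeless graph")
  A <- .binary_adjacency(graph)
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x       # (A + I) x
    y <- y / max(y)
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) {
      x[x < tol * 10] <- 0             # flush isolated-node residue
      return(stats::setNames(x / max(x), rownames(A)))
    }
  }
  stop("eigenvector centrality did not converge within ", max_iter,
       " iterations (residual ", signif(delta, 3), ")")
}

#' Aggregate node count and node relevance across dyad graphs
#'
#' Node count is a channel's summed degree over all graphs of a
#' collection; node relevance is that count as a percentage of the total
#' number of edges across the collection, rounded half-up to an integer
#' percent.  Because every edge joins one teacher and one child channel,
#' each side's node counts sum to the total edge count, so each side's
#' relevance column sums to ~100.
#'
#' @param graphs non-empty list of [interbrain_graph]s sharing montages.
#' @return List of class `centrality_summary`: data frames `teacher` and
#'   `child` (columns `channel`, `node_count`, `node_relevance`, sorted by
#'   decreasing count), and `total_edges`.
#' @export
aggregate_relevance <- function(graphs) {
  if (length(graphs) == 0) stop("empty graph collection")
  ref <- graphs[[1]]$nodes
  for (g in graphs)
    if (!identical(g$nodes$channel, ref$channel) ||
        !identical(g$nodes$subject, ref$subject))
      stop("all graphs must share the same teacher/child montages")
  counts <- Reduce(`+`, lapply(graphs, degree_centrality))
  total <- sum(vapply(graphs, n_edges, integer(1)))
  side <- function(subj) {
    sel <- ref$subject == subj
    ch <- ref$channel[sel]
    nc <- as.integer(counts[ref$node[sel]])
    rel <- if (total > 0) .round_half_up(100 * nc / total) else
      rep(0L, length(nc))
    df <- data.frame(channel = ch, node_count = nc,
                     node_relevance = as.integer(rel),
                     stringsAsFactors = FALSE)
    df[order(-df$node_count, df$channel), , drop = FALSE]
  }
  structure(list(teacher = side("teacher"), child = side("child"),
                 total_edges = total),
            class = "centrality_summary")
}

#' Export a centrality summary as TSV
#'
#' Two stacked blocks (teacher then child) with columns `subject`,
#' `channel`, `node_count`, `node_relevance`.
#'
#' @param summary a [aggregate_relevance()] result.
#' @param path output file.
#' @export
write_relevance <- function(summary, path) {
  df <- rbind(cbind(subject = "teacher", summary$teacher),
              cbind(subject = "child", summary$child))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.centrality_summary <- function(x, ...) {
  cat("<centrality_summary> ", x$total_edges, " edges total\n", sep = "")
  cat("top teacher channels:\n")
  print(utils::head(x$teacher, 3), row.names = FALSE)
  cat("top child channels:\n")
  print(utils::head(x$child, 3), row.names = FALSE)
  invisible(x)
}
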