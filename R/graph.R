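# Thresholded inter-brain graphs.  Nodes are the union of the two
# subjects' channels (prefixed "T:" / "C:" so identical channel names stay
# distinct); every edge joins a teacher node to a child node, so the graph
# is bipartite by construction.  Isolated nodes are kept.

.node_ids <- function(teacher_channels, child_channels)
  c(paste0("T:", teacher_channels), paste0("C:", child_channels))

#' Construct an inter-brain graph from an explicit edge list
#'
#' Lower-level constructor used by [threshold_graph()] and by fixtures:
#' takes retained teacher-child channel pairs directly.
#'
#' @param teacher_channels,child_channels ordered channel names per side.
#' @param edges data frame with columns `teacher`, `child` and optionally
#'   `rho`; one row per retained inter-brain edge.
#' @param threshold_used correlation threshold recorded as metadata.
#' @param dyad_id label.
#' @return An object of class `interbrain_graph` with elements `nodes`
#'   (data frame: `node`, `channel`, `subject`), `edges` (data frame:
#'   `teacher`, `child`, `rho`), `threshold_used`, `dyad_id`.
#' @export
interbrain_graph <- function(teacher_channels, child_channels, edges,
                             threshold_used = NA_real_, dyad_id = "dyad") {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0)
    edges <- data.frame(teacher = character(), child = character(),
                        rho = numeric())
  if (!all(c("teacher", "child") %in% names(edges)))
    stop("edges must have columns teacher, child")
  if (is.null(edges$rho)) edges$rho <- NA_real_
  bad_t <- setdiff(edges$teacher, teacher_channels)
  bad_c <- setdiff(edges$child, child_channels)
  if (length(bad_t) || length(bad_c))
    stop("edge endpoints not in montage: ",
         paste(c(bad_t, bad_c), collapse = ", "))
  if (anyDuplicated(edges[, c("teacher", "child")]))
    stop("duplicate edges")
  nodes <- data.frame(
    node = .node_ids(teacher_channels, child_channels),
    channel = c(teacher_channels, child_channels),
    subject = rep(c("teacher", "child"),
                  c(length(teacher_channels), length(child_channels))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = edges[, c("teacher", "child", "rho")],
                 threshold_used = threshold_used,
                 dyad_id = as.character(dyad_id)),
            class = "interbrain_graph")
}

#' Threshold an adjacency into an inter-brain graph
#'
#' Retains channel pairs with signed `rho >= threshold` (pairs exactly at
#' the threshold survive).  The comparison is one-sided by default —
#' anticorrelations are dropped; set `absolute = TRUE` to threshold on
#' `|rho|`.  Isolated nodes are kept, so the node count is always
#' `n_teacher + n_child`.
#'
#' @param adj an [build_adjacency()] result.
#' @param threshold correlation cut (default 0.15).
#' @param absolute threshold on `|rho|` instead of signed `rho`.
#' @return An [interbrain_graph].
#' @export
threshold_graph <- function(adj, threshold = 0.15, absolute = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < -1 || threshold > 1)
    stop("threshold must be a single correlation in [-1, 1]")
  tc <- attr(adj, "teacher_channels"); cc <- attr(adj, "child_channels")
  v <- if (absolute) abs(unclass(adj)) else unclass(adj)
  keep <- which(v >= threshold, arr.ind = TRUE)
  edges <- data.frame(teacher = tc[keep[, 1]], child = cc[keep[, 2]],
                      rho = unclass(adj)[keep])
  interbrain_graph(tc, cc, edges, threshold_used = threshold,
                   dyad_id = attr(adj, "dyad_id") %||% "dyad")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of edges
#' @param graph an [interbrain_graph].
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Dense symmetric binary adjacency over all nodes, in nodes$node order.
.binary_adjacency <- function(graph) {
  ids <- graph$nodes$node
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    i <- match(paste0("T:", graph$edges$teacher), ids)
    j <- match(paste0("C:", graph$edges$child), ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Degree centrality
#'
#' Number of direct connections of each node of the binary graph; isolated
#' nodes score 0.
#'
#' @param graph an [interbrain_graph].
#' @return Named integer vector over all nodes (`T:`/`C:` prefixed).
#' @export
degree_centrality <- function(graph) {
  ids <- graph$nodes$node
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(graph$edges)) {
    tt <- table(paste0("T:", graph$edges$teacher))
    ct <- table(paste0("C:", graph$edges$child))
    deg[names(tt)] <- as.integer(tt)
    deg[names(ct)] <- as.integer(ct)
  }
  deg
}

#' Convert to an igraph object
#'
#' Node attribute `subject` and edge attribute `rho` are carried over.
#' Used for interoperability and GraphML export; all package statistics
#' are computed natively.
#'
#' @param graph an [interbrain_graph].
#' @return An [igraph::graph] (undirected).
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes$node)
  g <- igraph::set_vertex_attr(g, "subject", value = graph$nodes$subject)
  if (nrow(graph$edges)) {
    ep <- rbind(paste0("T:", graph$edges$teacher),
                paste0("C:", graph$edges$child))
    g <- igraph::add_edges(g, as.vector(ep))
    g <- igraph::set_edge_attr(g, "rho", value = graph$edges$rho)
  }
  g
}

#' Export graph edges / GraphML
#'
#' `write_graph_edges()` writes a TSV edge list (`teacher`, `child`,
#' `rho`); `write_graphml()` writes GraphML with node attribute `subject`
#' and edge attribute `rho`.
#'
#' @param graph an [interbrain_graph].
#' @param path output file.
#' @export
write_graph_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_edges
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @export
print.interbrain_graph <- function(x, ...) {
  cat("<interbrain_graph> '", x$dyad_id, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " inter-brain edges (threshold ", x$threshold_used,
      ")\n", sep = "")
  invisible(x)
}
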