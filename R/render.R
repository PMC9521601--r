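# Scalp-layout figure of an inter-brain graph: teacher montage on the
# left, child on the right, inter-brain edges drawn between them, nodes
# colored red (low) -> green (high) by eigenvector centrality.  The SVG is
# assembled directly as text so the output is deterministic and its
# node/edge elements can be counted by tools and tests.

.svg_num <- function(x) formatC(x, format = "f", digits = 2)

.centrality_color <- function(score) {
  ramp <- grDevices::colorRamp(c("#d62728", "#ffdd55", "#2ca02c"))
  v <- ramp(max(0, min(1, score)))
  grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
}

#' Render an inter-brain graph to SVG
#'
#' Draws the two subjects' montages side by side (teacher left, child
#' right) using their layout coordinates, one line per inter-brain edge,
#' and one circle per channel colored by eigenvector centrality from red
#' (low) through yellow to green (high).  Isolated nodes (centrality 0)
#' are drawn in the red extreme.  Output is deterministic for fixed input.
#'
#' @param graph an [interbrain_graph].
#' @param teacher_montage,child_montage [channel_montage]s supplying the
#'   layout coordinates; default to [default_montage()].
#' @param centrality named per-node scores in \[0, 1\] (defaults to
#'   [eigenvector_centrality()] when the graph has edges, all-zero
#'   otherwise).
#' @param path output SVG file.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_graph <- function(graph,
                         teacher_montage = default_montage("teacher"),
                         child_montage = default_montage("child"),
                         centrality = NULL, path, width = 900,
                         height = 480) {
  if (is.null(centrality)) {
    centrality <- stats::setNames(numeric(nrow(graph$nodes)),
                                  graph$nodes$node)
    if (n_edges(graph) > 0) {
      ec <- eigenvector_centrality(graph)
      centrality[names(ec)] <- ec
    }
  }
  missing_coord <- c(
    setdiff(graph$nodes$channel[graph$nodes$subject == "teacher"],
            teacher_montage$channels),
    setdiff(graph$nodes$channel[graph$nodes$subject == "child"],
            child_montage$channels))
  if (length(missing_coord))
    stop("no layout coordinate for node(s): ",
         paste(unique(missing_coord), collapse = ", "))
  # map unit-head coordinates into two side-by-side panels
  panel <- function(montage, cx) {
    p <- montage$positions
    data.frame(channel = montage$channels,
               px = cx + p[, "x"] * (width / 4.6),
               py = height / 2 - p[, "y"] * (height / 2.6))
  }
  tp <- panel(teacher_montage, width * 0.25)
  cp <- panel(child_montage, width * 0.75)
  coords <- rbind(cbind(tp, node = paste0("T:", tp$channel)),
                  cbind(cp, node = paste0("C:", cp$channel)))
  rownames(coords) <- coords$node
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    sprintf('<title>inter-brain graph %s (threshold %s)</title>',
            graph$dyad_id, format(graph$threshold_used)),
    sprintf(paste0('<text x="%s" y="20" text-anchor="middle" ',
                   'font-size="14">teacher</text>'), .svg_num(width * 0.25)),
    sprintf(paste0('<text x="%s" y="20" text-anchor="middle" ',
                   'font-size="14">child</text>'), .svg_num(width * 0.75)))
  if (n_edges(graph) > 0) {
    e1 <- coords[paste0("T:", graph$edges$teacher), ]
    e2 <- coords[paste0("C:", graph$edges$child), ]
    lines <- c(lines, sprintf(
      paste0('<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" ',
             'stroke="#777777" stroke-width="1.5"/>'),
      .svg_num(e1$px), .svg_num(e1$py), .svg_num(e2$px), .svg_num(e2$py)))
  }
  cols <- vapply(coords$node,
                 function(id) .centrality_color(centrality[[id]] %||% 0),
                 character(1))
  lines <- c(lines,
             sprintf('<circle class="node" cx="%s" cy="%s" r="7" fill="%s" stroke="#333333"/>',
                     .svg_num(coords$px), .svg_num(coords$py), cols),
             sprintf('<text x="%s" y="%s" font-size="7" text-anchor="middle">%s</text>',
                     .svg_num(coords$px), .svg_num(coords$py - 9),
                     coords$channel),
             "</svg>")
  writeLines(lines, path)
  invisible(path)
}
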