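# Bundled reference summaries of a five-dyad teacher-child fNIRS
# hyperscanning study (18 channels per subject over PFC and rTPJ): the
# published per-dyad correlation-bin counts, the inter-brain channel
# pairs retained at rho >= 0.2, and the aggregated node-count /
# node-relevance table.  Used as worked examples and as consistency
# fixtures for the centrality arithmetic.

.extdata <- function(name)
  system.file("extdata", name, package = "interbrain", mustWork = TRUE)

#' Bundled study reference tables
#'
#' `study_correlation_bins()`: per-dyad counts of the 324 teacher-child
#' Spearman correlations in the conventional bins.
#' `study_retained_edges()`: the 24 inter-brain channel pairs retained at
#' `rho >= 0.2` across the four coactivated dyads.
#' `study_node_counts()`: the published aggregated node count and node
#' relevance per channel and side.
#'
#' @return A data frame.
#' @export
study_correlation_bins <- function()
  utils::read.table(.extdata("study_correlation_bins.tsv"), header = TRUE,
                    sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)

#' @rdname study_correlation_bins
#' @export
study_retained_edges <- function()
  utils::read.table(.extdata("study_retained_edges.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

#' @rdname study_correlation_bins
#' @export
study_node_counts <- function()
  utils::read.table(.extdata("study_node_counts.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

#' Reference inter-brain graphs of the coactivated study dyads
#'
#' Builds one [interbrain_graph] per coactivated dyad from the bundled
#' retained-edge list (`rho >= 0.2`), on the default montages.
#'
#' @return Named list of [interbrain_graph]s (`dyad2` ... `dyad5`).
#' @export
study_graphs <- function() {
  edges <- study_retained_edges()
  tm <- default_montage("teacher"); cm <- default_montage("child")
  lapply(split(edges, edges$dyad), function(e)
    interbrain_graph(tm$channels, cm$channels,
                     data.frame(teacher = e$teacher_channel,
                                child = e$child_channel),
                     threshold_used = 0.2, dyad_id = e$dyad[1]))
}
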