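# Inter-brain adjacency: Spearman correlations between every teacher
# channel and every child channel.  Intra-brain pairs are absent by
# construction (the matrix is teacher x child only).

#' Spearman rank correlation of two series
#'
#' Average ranks for ties; errors on zero-variance input rather than
#' silently returning 0 or NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("Spearman correlation needs length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance input series")
  stats::cor(x, y, method = "spearman")
}

# Column-standardized ranks such that crossprod(rt, rc) / (T - 1) is the
# Spearman correlation matrix.  Fast path shared by build_adjacency and the
# permutation loop of coactivation_test.
.scaled_ranks <- function(samples, who = "recording") {
  sds <- apply(samples, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: zero-variance channel(s) in ", who, ": ",
         paste(colnames(samples)[sds == 0], collapse = ", "))
  r <- apply(samples, 2, rank)      # average ranks on ties
  scale(r)
}

#' Build the inter-brain Spearman adjacency
#'
#' `rho[i, j]` is the Spearman correlation between teacher channel `i` and
#' child channel `j`.  With the default 18-channel montages this is an
#' 18 x 18 table of 324 channel pairs.  Intra-brain correlations are not
#' part of the table (equivalently: zeroed in the joint two-subject view).
#'
#' @param dyad a [dyad_recording].
#' @return An object of class `interbrain_adjacency`: the correlation
#'   matrix with attributes `teacher_channels`, `child_channels`,
#'   `dyad_id`.
#' @export
build_adjacency <- function(dyad) {
  stopifnot(inherits(dyad, "dyad_recording"))
  rt <- .scaled_ranks(dyad$teacher$samples, "teacher recording")
  rc <- .scaled_ranks(dyad$child$samples, "child recording")
  n <- nrow(dyad$teacher$samples)
  rho <- crossprod(rt, rc) / (n - 1)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1   # guard fp rounding
  structure(rho,
            teacher_channels = dyad$teacher$montage$channels,
            child_channels = dyad$child$montage$channels,
            dyad_id = dyad$dyad_id,
            class = c("interbrain_adjacency", "matrix"))
}

#' Bin the adjacency correlations
#'
#' Counts correlation values per half-open bin `[lo, hi)`; the lowest bin
#' is open below (everything under the first cut) and the top bin is
#' closed above at 1.  Counts always sum to the total number of channel
#' pairs (324 for the default montages).
#'
#' @param adj an [build_adjacency()] result (or plain numeric matrix).
#' @param cuts strictly increasing correlation cut points; defaults to the
#'   conventional summary bins `<0.1, 0.1-0.15, 0.15-0.2, 0.2-0.25,
#'   0.25-0.3, >0.3`.
#' @return Named integer vector of bin counts.
#' @export
bin_summary <- function(adj, cuts = c(0.1, 0.15, 0.2, 0.25, 0.3)) {
  if (is.unsorted(cuts, strictly = TRUE))
    stop("cuts must be strictly increasing")
  v <- as.numeric(adj)
  breaks <- c(-Inf, cuts, Inf)
  counts <- as.integer(table(cut(v, breaks, right = FALSE)))
  labels <- c(paste0("<", cuts[1]),
              if (length(cuts) > 1)
                paste0(cuts[-length(cuts)], "-", cuts[-1]),
              paste0(">", cuts[length(cuts)]))
  stats::setNames(counts, labels)
}

#' Export an adjacency as TSV
#'
#' Long format: `teacher_channel`, `child_channel`, `rho`.
#'
#' @param adj an `interbrain_adjacency`.
#' @param path output file.
#' @export
write_adjacency <- function(adj, path) {
  tc <- attr(adj, "teacher_channels"); cc <- attr(adj, "child_channels")
  df <- data.frame(
    teacher_channel = rep(tc, times = length(cc)),
    child_channel = rep(cc, each = length(tc)),
    rho = as.numeric(adj))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.interbrain_adjacency <- function(x, ...) {
  cat("<interbrain_adjacency> ", nrow(x), " teacher x ", ncol(x),
      " child channels (dyad '", attr(x, "dyad_id"), "')\n", sep = "")
  cat("  rho range: [", round(min(x), 3), ", ", round(max(x), 3), "]\n",
      sep = "")
  invisible(x)
}
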