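# The bootstrap modularity test: a permutation null for the modularity of
# the thresholded inter-brain graph.  Null hypothesis: the teacher's
# channels are independent of the child's channels.  Each permutation
# shuffles the teacher's TIME indices jointly across channels — this
# preserves the teacher's intra-brain correlation structure exactly while
# destroying teacher-child temporal alignment.  (Permuting channel labels
# instead would merely relabel graph nodes and leave every graph statistic
# unchanged, i.e. no test at all.)

#' Configuration of the coactivation test
#'
#' @param n_permutations number of permutations B (default 1000; >= 19).
#' @param threshold correlation cut passed to [threshold_graph()]
#'   (default 0.15), re-applied inside every permutation.
#' @param statistic `"max_modularity_binary"` (default) or
#'   `"modularity_weighted"` (greedy maximization on the `|rho|`-weighted
#'   graph).
#' @param permutation_scheme `"full_time_shuffle"` (default) or
#'   `"circular_shift"`.
#' @param tail `"low_is_coactivation"` (default: low modularity means the
#'   two brains integrate, the p-value counts null statistics <= observed)
#'   or `"high_is_coactivation"` (the complementary count).
#' @param seed integer RNG seed; every result records it.
#' @param absolute threshold on `|rho|` (see [threshold_graph()]).
#' @param edgeless_q sentinel statistic for edgeless graphs (see
#'   [max_modularity()]).
#' @return List of class `test_config`.
#' @export
test_config <- function(n_permutations = 1000, threshold = 0.15,
                        statistic = c("max_modularity_binary",
                                      "modularity_weighted"),
                        permutation_scheme = c("full_time_shuffle",
                                               "circular_shift"),
                        tail = c("low_is_coactivation",
                                 "high_is_coactivation"),
                        seed = 1L, absolute = FALSE, edgeless_q = 1) {
  statistic <- match.arg(statistic)
  permutation_scheme <- match.arg(permutation_scheme)
  tail <- match.arg(tail)
  if (n_permutations < 19)
    stop("n_permutations must be >= 19 (p-value floor 1/(B+1))")
  if (threshold < -1 || threshold > 1)
    stop("threshold must lie in [-1, 1]")
  structure(list(n_permutations = as.integer(n_permutations),
                 threshold = threshold, statistic = statistic,
                 permutation_scheme = permutation_scheme, tail = tail,
                 seed = as.integer(seed), absolute = absolute,
                 edgeless_q = edgeless_q),
            class = "test_config")
}

#' Permute the teacher's recording in time
#'
#' Applies one random time-index permutation (or circular shift) jointly
#' to all teacher channels; the child is untouched.  Draws from the
#' current RNG state unless an explicit permutation is supplied.
#'
#' @param dyad a [dyad_recording].
#' @param scheme `"full_time_shuffle"` or `"circular_shift"`.
#' @param perm optional explicit permutation of `1:T` (full shuffle) or a
#'   single offset (circular shift).
#' @return A [dyad_recording] with permuted teacher samples.
#' @export
permute_teacher <- function(dyad, scheme = c("full_time_shuffle",
                                             "circular_shift"),
                            perm = NULL) {
  scheme <- match.arg(scheme)
  tt <- nrow(dyad$teacher$samples)
  idx <- .permutation_indices(tt, scheme, perm)
  teacher <- dyad$teacher
  teacher$samples <- teacher$samples[idx, , drop = FALSE]
  validate_dyad(teacher, dyad$child, dyad$dyad_id)
}

.permutation_indices <- function(tt, scheme, perm = NULL) {
  if (scheme == "full_time_shuffle") {
    if (is.null(perm)) perm <- sample.int(tt)
    stopifnot(length(perm) == tt)
    perm
  } else {
    if (is.null(perm)) perm <- sample.int(tt, 1) - 1L
    (seq_len(tt) + perm - 1L) %% tt + 1L
  }
}

# statistic on a rho matrix (shared by observed and permuted evaluations)
.graph_statistic <- function(rho, tc, cc, config) {
  g <- threshold_graph(
    structure(rho, teacher_channels = tc, child_channels = cc,
              dyad_id = "perm", class = c("interbrain_adjacency", "matrix")),
    threshold = config$threshold, absolute = config$absolute)
  max_modularity(g, weighted = config$statistic == "modularity_weighted",
                 edgeless_q = config$edgeless_q)$q
}

#' Permutation ("bootstrap") modularity test of dyad coactivation
#'
#' Computes the maximized modularity of the observed thresholded
#' inter-brain graph, then `B` replicates under the null (teacher time
#' indices permuted, adjacency rebuilt, same threshold re-applied).  With
#' the default tail, `p = (1 + #\{q_null <= q_observed\}) / (B + 1)`; small
#' p means the observed graph is less modular — more integrated across
#' brains — than chance, i.e. coactivation.  Deterministic given the seed.
#'
#' @param dyad a [dyad_recording].
#' @param config a [test_config].
#' @return Object of class `modularity_test`: `q_observed`, `q_null`
#'   (length B), `p_value`, `degenerate_null` flag, `config`, `dyad_id`.
#' @export
coactivation_test <- function(dyad, config = test_config()) {
  stopifnot(inherits(dyad, "dyad_recording"))
  set.seed(config$seed)
  rt <- .scaled_ranks(dyad$teacher$samples,
                      paste0("teacher recording (dyad '", dyad$dyad_id, "')"))
  rc <- .scaled_ranks(dyad$child$samples,
                      paste0("child recording (dyad '", dyad$dyad_id, "')"))
  tt <- nrow(rt)
  tc <- dyad$teacher$montage$channels
  cc <- dyad$child$montage$channels
  rho_obs <- crossprod(rt, rc) / (tt - 1)
  q_obs <- .graph_statistic(rho_obs, tc, cc, config)
  q_null <- vapply(seq_len(config$n_permutations), function(b) {
    idx <- .permutation_indices(tt, config$permutation_scheme)
    rho <- crossprod(rt[idx, , drop = FALSE], rc) / (tt - 1)
    .graph_statistic(rho, tc, cc, config)
  }, numeric(1))
  eps <- 1e-12
  hits <- if (config$tail == "low_is_coactivation")
    sum(q_null <= q_obs + eps) else sum(q_null >= q_obs - eps)
  p <- (1 + hits) / (config$n_permutations + 1)
  structure(list(q_observed = q_obs, q_null = q_null, p_value = p,
                 degenerate_null = length(unique(round(q_null, 12))) == 1L,
                 config = config, dyad_id = dyad$dyad_id),
            class = "modularity_test")
}

#' Screen a dyad collection for coactivation
#'
#' Runs [coactivation_test()] per dyad (seeds derived as `seed + i - 1`)
#' and retains dyads with `p <= alpha`.
#'
#' @param dyads non-empty list of [dyad_recording]s.
#' @param config a [test_config].
#' @param alpha significance level (default 0.05).
#' @return List of class `dyad_screen`: `results` (per-dyad
#'   `modularity_test`, named by dyad id), `retained` (dyad ids with
#'   `p <= alpha`), `alpha`.
#' @export
screen_dyads <- function(dyads, config = test_config(), alpha = 0.05) {
  if (length(dyads) == 0) stop("need at least one dyad")
  results <- lapply(seq_along(dyads), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    tryCatch(coactivation_test(dyads[[i]], cfg_i),
             error = function(e)
               stop("dyad '", dyads[[i]]$dyad_id, "': ",
                    conditionMessage(e), call. = FALSE))
  })
  names(results) <- vapply(dyads, `[[`, character(1), "dyad_id")
  p <- vapply(results, `[[`, numeric(1), "p_value")
  structure(list(results = results, retained = names(results)[p <= alpha],
                 alpha = alpha),
            class = "dyad_screen")
}

#' Write a test result as JSON
#'
#' @param result a [coactivation_test()] result.
#' @param path output file.
#' @export
write_test_json <- function(result, path) {
  qn <- result$q_null
  obj <- list(dyad_id = result$dyad_id,
              q_observed = result$q_observed,
              p_value = result$p_value,
              n_permutations = result$config$n_permutations,
              seed = result$config$seed,
              threshold = result$config$threshold,
              statistic = result$config$statistic,
              scheme = result$config$permutation_scheme,
              tail = result$config$tail,
              degenerate_null = result$degenerate_null,
              null_summary = list(min = min(qn),
                                  q1 = as.numeric(stats::quantile(qn, 0.25)),
                                  median = stats::median(qn),
                                  q3 = as.numeric(stats::quantile(qn, 0.75)),
                                  max = max(qn)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.modularity_test <- function(x, ...) {
  cat("<modularity_test> dyad '", x$dyad_id, "': Q_obs = ",
      round(x$q_observed, 4), ", p = ", signif(x$p_value, 3), " (B = ",
      x$config$n_permutations, ", threshold ", x$config$threshold,
      ", ", x$config$tail, ")\n", sep = "")
  if (x$degenerate_null) cat("  [flag] degenerate null: all permutation ",
                             "statistics identical\n", sep = "")
  invisible(x)
}

#' @export
print.dyad_screen <- function(x, ...) {
  p <- vapply(x$results, `[[`, numeric(1), "p_value")
  cat("<dyad_screen> alpha = ", x$alpha, "\n", sep = "")
  for (id in names(x$results))
    cat(sprintf("  %-10s p = %-7.4g %s\n", id, p[[id]],
                if (id %in% x$retained) "retained" else "excluded"))
  invisible(x)
}
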