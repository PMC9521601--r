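# Simulation-based operating characteristics of the coactivation screen:
# type-I error on null cohorts, power/screening accuracy on planted
# coupled dyads, and planted-hub recovery.  These drive the package's own
# validation suite and let users audit the screen under conditions close
# to their own recordings.

#' Type-I error rate of the coactivation test on null dyads
#'
#' Generates `n_replicates` independent dyads with coupling 0 and runs
#' [coactivation_test()] on each; returns the fraction rejected at
#' `alpha`.  For a well-calibrated test this is at most `alpha` (the
#' permutation construction guarantees validity; discreteness of the
#' statistic on sparse graphs makes it conservative).
#'
#' @param n_replicates number of null dyads.
#' @param n_permutations permutations per test.
#' @param alpha rejection level.
#' @param config a [synth_config] template (coupling forced to 0).
#' @param test_cfg a [test_config] template (its seed is re-derived per
#'   replicate).
#' @param seed master seed; replicate seeds are derived from it.
#' @return Rejection rate in \[0, 1\], with attribute `p_values`.
#' @export
type1_error_rate <- function(n_replicates = 200, n_permutations = 99,
                             alpha = 0.05, config = synth_config(),
                             test_cfg = test_config(
                               n_permutations = n_permutations),
                             seed = 1L) {
  pvals <- vapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$coupling <- 0
    cfg$seed <- seed + i
    tc <- test_cfg
    tc$seed <- seed + 500000L + i
    coactivation_test(generate_dyad(cfg, paste0("null", i)), tc)$p_value
  }, numeric(1))
  structure(mean(pvals <= alpha), p_values = pvals)
}

#' Screening accuracy on a planted 4-coupled + 1-null cohort
#'
#' Each run simulates four coupled dyads (latent coupling calibrated so
#' planted channel pairs reach `target_spearman`) and one null dyad,
#' screens them with [screen_dyads()], and scores the run a success when
#' exactly the four coupled dyads are retained.
#'
#' @param n_runs number of simulated screens.
#' @param n_permutations permutations per dyad test.
#' @param alpha screening level.
#' @param target_spearman planted coupled-pair Spearman correlation.
#' @param config a [synth_config] template.
#' @param seed master seed.
#' @return List: `success_rate` (exactly-correct screens),
#'   `coupled_retention_rate` (per-dyad power), `null_exclusion_rate`.
#' @export
screen_success_rate <- function(n_runs = 50, n_permutations = 199,
                                alpha = 0.05, target_spearman = 0.5,
                                config = synth_config(), seed = 1L) {
  a <- calibrate_coupling(target_spearman, config)
  success <- logical(n_runs)
  coupled_kept <- null_kept <- 0
  for (r in seq_len(n_runs)) {
    dyads <- c(lapply(1:4, function(i) {
      cfg <- config
      cfg$coupling <- a
      cfg$seed <- seed + 10L * r + i
      generate_dyad(cfg, paste0("coupled", i))
    }), list({
      cfg <- config
      cfg$coupling <- 0
      cfg$seed <- seed + 10L * r + 5L
      generate_dyad(cfg, "null")
    }))
    tc <- test_config(n_permutations = n_permutations,
                      seed = seed + 600000L + r)
    scr <- screen_dyads(dyads, tc, alpha = alpha)
    success[r] <- setequal(scr$retained, paste0("coupled", 1:4))
    coupled_kept <- coupled_kept +
      sum(paste0("coupled", 1:4) %in% scr$retained)
    null_kept <- null_kept + ("null" %in% scr$retained)
  }
  list(success_rate = mean(success),
       coupled_retention_rate = coupled_kept / (4 * n_runs),
       null_exclusion_rate = 1 - null_kept / n_runs)
}

#' Planted-hub recovery rate
#'
#' Each run simulates four coupled dyads, thresholds their adjacencies
#' and aggregates node counts; the run counts as recovered when the top
#' node-count channel on each side belongs to the planted coupled set.
#'
#' @param n_runs number of runs.
#' @param threshold correlation cut for the graphs.
#' @param config a [synth_config] template (its default coupling is
#'   used).
#' @param seed master seed.
#' @return Recovery rate in \[0, 1\].
#' @export
hub_recovery_rate <- function(n_runs = 50, threshold = 0.15,
                              config = synth_config(), seed = 1L) {
  hits <- vapply(seq_len(n_runs), function(r) {
    graphs <- lapply(1:4, function(i) {
      cfg <- config
      cfg$seed <- seed + 10L * r + i
      threshold_graph(build_adjacency(generate_dyad(cfg, paste0("d", i))),
                      threshold)
    })
    summ <- aggregate_relevance(graphs)
    summ$teacher$channel[1] %in% config$teacher_coupled &&
      summ$child$channel[1] %in% config$child_coupled
  }, logical(1))
  mean(hits)
}
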