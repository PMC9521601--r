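test_that("teacher permutation preserves intra-brain structure", {
  d <- noise_dyad(tt = 60, seed = 3)
  # identity permutation leaves the dyad unchanged
  same <- permute_teacher(d, "full_time_shuffle", perm = 1:60)
  expect_identical(same$teacher$samples, d$teacher$samples)
  # any permutation leaves teacher intra-brain correlations unchanged
  set.seed(9)
  shuf <- permute_teacher(d, "full_time_shuffle")
  expect_false(identical(shuf$teacher$samples, d$teacher$samples))
  expect_equal(cor(shuf$teacher$samples, method = "spearman"),
               cor(d$teacher$samples, method = "spearman"),
               tolerance = 1e-12)
  expect_identical(shuf$child$samples, d$child$samples)
  # circular shift: same multiset of rows, order rotated
  rot <- permute_teacher(d, "circular_shift", perm = 5)
  expect_equal(rot$teacher$samples[1, ], d$teacher$samples[6, ])
  expect_equal(unname(rot$teacher$samples),
               unname(d$teacher$samples[c(6:60, 1:5), ]))
})

test_that("time shuffling drives coupled correlations to the null scale", {
  cfg <- synth_config(n_samples = 400, seed = 11,
                      one_over_f_sd = 0, sinusoid_amps = c(0, 0, 0))
  d <- generate_dyad(cfg)
  rho_pre <- unclass(build_adjacency(d))["FP2-AF8", "CP4-CP6"]
  expect_gt(rho_pre, 0.3)
  set.seed(13)
  post <- replicate(30, {
    unclass(build_adjacency(
      permute_teacher(d, "full_time_shuffle")))["FP2-AF8", "CP4-CP6"]
  })
  expect_lt(abs(mean(post)), 3 / sqrt(399))
  expect_lt(sd(post), 2 / sqrt(399))
})

test_that("test configuration enforces its invariants", {
  expect_error(test_config(n_permutations = 10), ">= 19")
  expect_error(test_config(threshold = 1.2), "\\[-1, 1\\]")
  expect_s3_class(test_config(n_permutations = 19), "test_config")
})

test_that("the permutation test is reproducible and internally consistent", {
  d <- noise_dyad(tt = 120, seed = 17)
  cfg <- test_config(n_permutations = 49, seed = 23)
  r1 <- coactivation_test(d, cfg)
  r2 <- coactivation_test(d, cfg)
  expect_identical(r1$q_null, r2$q_null)
  expect_identical(r1$p_value, r2$p_value)
  # p respects its defining formula and bounds
  expect_equal(r1$p_value,
               (1 + sum(r1$q_null <= r1$q_observed + 1e-12)) / 50)
  expect_gte(r1$p_value, 1 / 50)
  expect_lte(r1$p_value, 1)
  # opposite tail counts the complementary event
  cfg_hi <- cfg; cfg_hi$tail <- "high_is_coactivation"
  r3 <- coactivation_test(d, cfg_hi)
  expect_equal(r3$p_value,
               (1 + sum(r3$q_null >= r3$q_observed - 1e-12)) / 50)
  # a different seed gives a different null sample
  cfg2 <- cfg; cfg2$seed <- 99L
  expect_false(identical(coactivation_test(d, cfg2)$q_null, r1$q_null))
})

test_that("p-values are valid (conservative) under the null", {
  # independent white-noise dyads; rejection rate at alpha must not
  # exceed alpha by more than binomial noise
  set.seed(31)
  pvals <- vapply(1:30, function(i) {
    d <- noise_dyad(tt = 150, seed = 1000 + i)
    coactivation_test(d, test_config(n_permutations = 39,
                                     seed = 2000 + i))$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.10, 0.25))
    expect_lte(mean(pvals <= alpha),
               alpha + 2 * sqrt(alpha * (1 - alpha) / 30))
  expect_gte(min(pvals), 1 / 40)
})

test_that("evidence strengthens with coupling (median p non-increasing)", {
  set.seed(37)
  med_p <- vapply(c(0, 0.5, 0.9), function(a) {
    ps <- vapply(1:8, function(i) {
      cfg <- synth_config(coupling = a, seed = 100 * a + i,
                          n_samples = 200)
      coactivation_test(generate_dyad(cfg),
                        test_config(n_permutations = 49,
                                    seed = 500 + i))$p_value
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_lte(med_p[2], med_p[1] + 0.15)
  expect_lte(med_p[3], med_p[2] + 0.15)
  expect_lt(med_p[3], med_p[1])
})

test_that("screening returns per-dyad results and applies alpha", {
  dyads <- generate_null_cohort(3, synth_config(n_samples = 120, seed = 41))
  scr <- screen_dyads(dyads, test_config(n_permutations = 19, seed = 43),
                      alpha = 0.05)
  expect_named(scr$results, c("null1", "null2", "null3"))
  expect_true(all(scr$retained %in% names(scr$results)))
  # alpha = 0 retains nothing because p >= 1/(B+1) > 0
  scr0 <- screen_dyads(dyads, test_config(n_permutations = 19, seed = 43),
                       alpha = 0)
  expect_length(scr0$retained, 0)
  # errors are tagged with the offending dyad
  bad <- dyads
  bad[[2]]$teacher$samples[, 3] <- 1
  expect_error(screen_dyads(bad, test_config(n_permutations = 19)),
               "null2")
})

test_that("result JSON carries provenance and a null summary", {
  d <- noise_dyad(tt = 80, seed = 47)
  res <- coactivation_test(d, test_config(n_permutations = 19, seed = 53))
  f <- withr::local_tempfile(fileext = ".json")
  write_test_json(res, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$seed, 53)
  expect_equal(obj$n_permutations, 19)
  expect_equal(obj$p_value, res$p_value)
  expect_equal(obj$null_summary$max, max(res$q_null))
  expect_equal(obj$scheme, "full_time_shuffle")
})
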