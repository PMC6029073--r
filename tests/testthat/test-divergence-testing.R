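test_that("a single-replicate pool is that replicate, and pool length is additive", {
  spec <- synthetic_spec(n_days = 1, reps_per_day = 4, n_events = 50000,
                         seed = 2)
  wt <- gen_wt_experiment(spec)
  pool <- pool_wt(wt, "d1")
  expect_equal(length(pool$intensities), 200000L)
  expect_equal(length(pool$source_replicates), 4L)
  one <- wt[wt$condition == "induced", ][1, ]
  expect_warning(p1 <- pool_wt(one, "d1"), "replicates")
  expect_identical(p1$intensities, one$intensities[[1]])
  expect_error(pool_wt(wt, "d9"), "no wild-type")
})

test_that("a replicate that is its own whole pool has zero divergence", {
  spec <- synthetic_spec(n_days = 1, reps_per_day = 1, n_events = 2000,
                         seed = 3)
  wt <- gen_wt_experiment(spec)
  pools <- suppressWarnings(hogflow:::pool_wt_by_day(wt))
  recs <- compute_divergences(wt, pools, leave_one_out = FALSE)
  expect_lt(abs(recs$kl_nats), 1e-3)
  # with exclusion requested, the degenerate one-replicate pool is kept
  expect_warning(compute_divergences(wt, pools), "full pool")
})

test_that("divergence records carry the right design counts and fail on day mismatch", {
  # 11 WT days of 3-4 replicates giving 38 records, one mutant on 2 days
  reps <- c(4, 3, 4, 3, 4, 3, 4, 3, 4, 3, 3)
  wt <- dplyr::bind_rows(lapply(seq_len(11), function(d) {
    spec <- synthetic_spec(n_days = 1, reps_per_day = reps[d],
                           n_events = 150, seed = d)
    out <- gen_wt_experiment(spec)
    out$day <- paste0("day", d)
    out
  }))
  expect_equal(sum(wt$condition == "induced"), 38L)
  mspec <- synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 150,
                          seed = 50)
  mut <- gen_effect_mutant(mspec, mutant_effect("graded", 0.3),
                           strain = "opy2_like")
  mut$day <- sub("^d", "day", mut$day)  # 6 induced across two days
  pools <- hogflow:::pool_wt_by_day(wt)
  recs <- compute_divergences(dplyr::bind_rows(wt, mut), pools,
                              method = "ecdf")
  expect_equal(sum(recs$strain == "WT"), 38L)
  expect_equal(sum(recs$strain == "opy2_like"), 6L)
  bad <- mut
  bad$day <- "day99"
  expect_error(compute_divergences(bad, pools), "day99")
})

test_that("graded mutants separate from wild type across seeds", {
  hits <- sapply(1:20, function(s) {
    spec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 1500,
                           seed = s)
    wt <- gen_wt_experiment(spec)
    pools <- hogflow:::pool_wt_by_day(wt)
    wt_kl <- compute_divergences(wt, pools)$kl_nats
    mut <- gen_effect_mutant(
      synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 1500,
                     seed = s + 500),
      mutant_effect("graded", 0.5), strain = "m")
    mut_kl <- compute_divergences(mut, pools)$kl_nats
    median(mut_kl) > median(wt_kl)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("rank-sum p-values match exhaustive enumeration", {
  mut <- c(3, 4, 5); wt <- c(1, 2, 2.5)
  res <- compare_to_wt(mut, wt, m_tests = 17)
  expect_equal(res$p_raw, 1 / 20)
  expect_equal(res$p_raw, enumerate_wrs_greater(mut, wt))
  expect_equal(res$p_corrected, min(1, 17 * res$p_raw))
  expect_false(res$significant)
  # a random, less extreme configuration
  set.seed(8)
  x <- rexp(5); y <- rexp(6)
  r2 <- compare_to_wt(x, y, m_tests = 1)
  expect_equal(r2$p_raw, enumerate_wrs_greater(x, y))
})

test_that("identical divergence groups are never significant", {
  z <- c(0.01, 0.02, 0.03, 0.04)
  res <- compare_to_wt(z, z, m_tests = 17)
  expect_gte(res$p_raw, 0.5)
  expect_false(res$significant)
  expect_error(compare_to_wt(numeric(0), z), "non-empty")
  expect_warning(compare_to_wt(c(1, 2), z), "exact")
})

test_that("day-matched pooling absorbs day batch effects", {
  spec <- synthetic_spec(n_days = 3, reps_per_day = 3, n_events = 4000,
                         day_batch_sd = 0.25, seed = 21)
  wt <- gen_wt_experiment(spec)
  pools <- hogflow:::pool_wt_by_day(wt)
  matched <- compute_divergences(wt, pools)$kl_nats
  # cross-day reference: every replicate scored against another day's pool
  days <- names(pools)
  swapped <- pools[c(2, 3, 1)]
  names(swapped) <- days
  crossed <- compute_divergences(wt, swapped)$kl_nats
  expect_lt(median(matched), median(crossed))
})

test_that("the full pipeline flags graded mutants and not wild-type-law strains", {
  spec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 2000,
                         seed = 31)
  wt <- gen_wt_experiment(spec)
  null_strain <- gen_wt_experiment(
    synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 2000,
                   seed = 32), strain = "null_mut")
  eff <- gen_effect_mutant(
    synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 2000,
                   seed = 33),
    mutant_effect("graded", 0.5), strain = "strong_mut")
  res <- divergence_test(dplyr::bind_rows(wt, null_strain, eff),
                         m_tests = 17)
  tests <- res$tests
  expect_true(tests$significant[tests$strain == "strong_mut"])
  expect_false(tests$significant[tests$strain == "null_mut"])
  expect_true(all(tests$p_corrected >=
                    pmin(1, tests$p_raw * 17) - 1e-12))
})
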