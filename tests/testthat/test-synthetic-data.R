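test_that("invalid specifications and effects are rejected", {
  expect_error(synthetic_spec(n_events = 0), "n_events")
  expect_error(synthetic_spec(n_events = 50), "n_events")
  expect_error(synthetic_spec(induced_law = c(6, 0)), "log-sd")
  expect_error(synthetic_spec(reps_per_day = 0), "reps_per_day")
  expect_error(mutant_effect("graded", 1.5), "magnitude")
  expect_error(mutant_effect("graded", -0.1), "magnitude")
})

test_that("generation is a deterministic function of spec and seed", {
  spec <- synthetic_spec(n_days = 2, n_events = 300, seed = 9)
  a <- gen_wt_experiment(spec)
  b <- gen_wt_experiment(spec)
  expect_identical(a, b)
  spec2 <- synthetic_spec(n_days = 2, n_events = 300, seed = 10)
  expect_false(identical(gen_wt_experiment(spec2)$intensities[[1]],
                         a$intensities[[1]]))
})

test_that("replicates per day are drawn from {3, 4} by default", {
  spec <- synthetic_spec(n_days = 6, n_events = 200, seed = 3)
  wt <- gen_wt_experiment(spec)
  per_day <- table(wt$day[wt$condition == "induced"])
  expect_true(all(per_day %in% c(3, 4)))
  expect_gt(length(unique(per_day)), 0)
})

test_that("a zero-magnitude graded mutant reproduces wild type exactly", {
  spec <- synthetic_spec(n_days = 1, reps_per_day = 3, n_events = 400,
                         seed = 4)
  wt <- gen_wt_experiment(spec)
  mut <- gen_effect_mutant(spec, mutant_effect("graded", 0), strain = "WT")
  expect_identical(mut, wt)
})

test_that("graded effects interpolate the induction gap", {
  spec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 20000,
                         day_batch_sd = 0, rep_batch_sd = 0, seed = 8)
  mut <- gen_effect_mutant(spec, mutant_effect("graded", 0.5))
  ind <- unlist(mut$intensities[mut$condition == "induced"])
  lm_obs <- mean(log(ind))
  se <- sd(log(ind)) / sqrt(length(ind))
  expect_lt(abs(lm_obs - 5.0), 3 * se)  # midpoint of log-means 4 and 6
})

test_that("induced sample mean is non-increasing in graded magnitude", {
  spec <- synthetic_spec(n_days = 1, reps_per_day = 3, n_events = 20000,
                         seed = 12)
  means <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(m) {
    s <- gen_effect_mutant(spec, mutant_effect("graded", m))
    mean(unlist(s$intensities[s$condition == "induced"]))
  })
  expect_true(all(diff(means) < 0))
})

test_that("bimodal mutants are detectably two-component mixtures", {
  spec <- synthetic_spec(n_days = 1, reps_per_day = 3, n_events = 50000,
                         seed = 6)
  mut <- gen_effect_mutant(spec, mutant_effect("bimodal", 0.5,
                                               weak_mode_attenuation = 0.5))
  x <- log(mut$intensities[[2]])  # induced replicate
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this unqualified
  fit <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$G, 2)
  expect_true(all(fit$parameters$pro > 0.25))
  # and the two component means bracket the mixture design
  mu <- sort(fit$parameters$mean)
  expect_lt(abs(mu[1] - 4), 0.3)
  expect_lt(abs(mu[2] - 5), 0.3)
  # wild type, by contrast, stays single-component
  wt <- gen_wt_experiment(spec)
  fw <- mclust::Mclust(log(wt$intensities[[2]]), G = 1:2, modelNames = "V",
                       verbose = FALSE)
  if (fw$G == 2) expect_lt(min(fw$parameters$pro), 0.25)
})

test_that("wild-type self-divergence sits well below moderate mutant divergence", {
  # rank-sum separation (8 vs 8) of WT self-divergences vs
  # magnitude-0.2 mutants over a 20-seed battery
  hits <- sapply(1:20, function(s) {
    spec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 2000,
                           seed = s)
    wt <- gen_wt_experiment(spec)
    pools <- hogflow:::pool_wt_by_day(wt)
    wt_kl <- compute_divergences(wt, pools)$kl_nats
    mspec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 2000,
                            seed = s + 1000)
    mut <- gen_effect_mutant(mspec, mutant_effect("graded", 0.2),
                             strain = "mut")
    mut_kl <- compute_divergences(mut, pools)$kl_nats
    wilcox.test(mut_kl, wt_kl, alternative = "greater")$p.value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("replicate-to-pool divergence of wild type sits in the replicate-noise band", {
  meds <- sapply(1:3, function(s) {
    spec <- synthetic_spec(n_days = 2, reps_per_day = 4,
                           n_events = 50000, seed = s)
    wt <- gen_wt_experiment(spec)
    median(compute_divergences(wt, hogflow:::pool_wt_by_day(wt))$kl_nats)
  })
  expect_gte(median(meds), 0.005)
  expect_lte(median(meds), 0.05)
  expect_true(all(meds < 0.1))
})

test_that("model-truth mutants record their generating fraction and respond to it", {
  p <- hog_params()
  full <- gen_model_truth_mutant(p, "activity", 1, n_cells = 5000, seed = 3)
  low <- gen_model_truth_mutant(p, "activity", 0.25, n_cells = 5000,
                                seed = 3)
  expect_equal(full$truth_fraction, 1)
  expect_equal(low$truth_group, "activity")
  m1 <- mean(full$intensities[[1]]); m2 <- mean(low$intensities[[1]])
  se <- sqrt(var(full$intensities[[1]]) / 5000 +
               var(low$intensities[[1]]) / 5000)
  expect_gt(m1 - m2, 3 * se)
  # fraction 1.0 equals the unperturbed model sample at the same seed
  base <- simulate_population(p, 5000, seed = 3)
  ref <- add_basal(base$protein, seed = hogflow:::derive_seed(3, 211L))
  expect_identical(full$intensities[[1]], ref)
  expect_error(gen_model_truth_mutant(p, "activity", 1.2, n_cells = 500),
               "fraction")
})
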