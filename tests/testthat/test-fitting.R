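p_base <- hog_params()

make_truth_reps <- function(group, fraction, n_reps = 3, n_cells = 4000,
                            seed = 1) {
  dplyr::bind_rows(lapply(seq_len(n_reps), function(r) {
    gen_model_truth_mutant(p_base, group, fraction, n_cells = n_cells,
                           seed = seed * 100 + r,
                           replicate = paste0("r", r), day = "d1")
  }))
}

wt_ref_sample <- function(n_cells = 4000, seed = 5555) {
  sim <- simulate_population(p_base, n_cells, seed = seed)
  add_basal(sim$protein, seed = seed + 1)
}

test_that("sweep input validation catches bad grids and missing controls", {
  reps <- make_truth_reps("activity", 0.5, n_reps = 2, n_cells = 500)
  ctrl <- make_uninduced_controls(c("r1", "r2"), c("d1", "d1"),
                                  n_cells = 500)
  expect_error(sweep_parameter(p_base, "activity", numeric(0), reps, ctrl,
                               wt_ref_sample(500)), "empty")
  expect_error(sweep_parameter(p_base, "activity", c(0.5, 0.2), reps, ctrl,
                               wt_ref_sample(500)), "increasing")
  expect_error(sweep_parameter(p_base, "activity", c(0.5, 1.2), reps, ctrl,
                               wt_ref_sample(500)), "\\[0, 1\\]")
  bad_ctrl <- make_uninduced_controls("r9", "d1", n_cells = 500)
  expect_error(sweep_parameter(p_base, "activity", c(0.5, 1), reps,
                               bad_ctrl, wt_ref_sample(500)),
               "missing uninduced control")
})

test_that("the fraction-1.0 column reproduces the unperturbed wild-type fit", {
  reps <- make_truth_reps("activity", 1, n_reps = 3, n_cells = 2000,
                          seed = 7)
  ctrl <- make_uninduced_controls(paste0("r", 1:3), rep("d1", 3),
                                  n_cells = 2000)
  ref <- wt_ref_sample(2000)
  sw <- sweep_parameter(p_base, "remodeling", fractions = c(0.5, 1),
                        mutant_replicates = reps,
                        uninduced_controls = ctrl,
                        wt_reference_induced = ref, n_cells = 2000,
                        seed = 9)
  wt_kls <- wt_model_fit(p_base, reps, ctrl, ref, n_cells = 2000, seed = 9)
  expect_identical(sw$kl_nats[sw$fraction == 1], wt_kls)
  # flexibility: the grid minimum cannot exceed the baseline column
  summ <- tidy(sw)
  expect_lte(min(summ$mean_kl), summ$mean_kl[summ$fraction == 1])
})

test_that("wild-type data fit themselves at full scale and are explained", {
  reps <- make_truth_reps("activity", 1, n_reps = 4, n_cells = 4000,
                          seed = 11)
  ctrl <- make_uninduced_controls(paste0("r", 1:4), rep("d1", 4),
                                  n_cells = 3000)
  ref <- wt_ref_sample(4000)
  sw <- sweep_parameter(p_base, "activity",
                        fractions = c(0.6, 0.8, 1),
                        mutant_replicates = reps,
                        uninduced_controls = ctrl,
                        wt_reference_induced = ref, n_cells = 4000,
                        seed = 13)
  wt_kls <- wt_model_fit(p_base,
                         make_truth_reps("activity", 1, 4, 4000, seed = 17),
                         ctrl, ref, n_cells = 4000, seed = 13)
  fit <- best_fit_and_classify(sw, wt_kls, strain = "WT")
  expect_gte(fit$best_fraction, 0.8)  # within one grid step of 1.0
  expect_true(fit$explained)
})

test_that("an activity-0.5 truth mutant is recovered and explained", {
  reps <- make_truth_reps("activity", 0.5, n_reps = 4, n_cells = 5000,
                          seed = 19)
  ctrl <- make_uninduced_controls(paste0("r", 1:4), rep("d1", 4),
                                  n_cells = 3000)
  ref <- wt_ref_sample(5000)
  sw_a <- sweep_parameter(p_base, "activity",
                          fractions = seq(0.3, 0.7, by = 0.05),
                          mutant_replicates = reps,
                          uninduced_controls = ctrl,
                          wt_reference_induced = ref, n_cells = 5000,
                          seed = 23)
  sw_r <- sweep_parameter(p_base, "remodeling",
                          fractions = seq(0.3, 0.7, by = 0.05),
                          mutant_replicates = reps,
                          uninduced_controls = ctrl,
                          wt_reference_induced = ref, n_cells = 5000,
                          seed = 23)
  wt_kls <- wt_model_fit(p_base,
                         make_truth_reps("activity", 1, 4, 5000, seed = 29),
                         ctrl, ref, n_cells = 5000, seed = 23)
  fit <- best_fit_and_classify(list(sw_a, sw_r), wt_kls, strain = "act05")
  expect_equal(fit$best_group, "activity")
  expect_lte(abs(fit$best_fraction - 0.5), 0.1)
  expect_true(fit$explained)
  expect_false(is.na(fit$p_attribution))
})

test_that("a mutant with modes the model cannot produce is not explained", {
  # non-responding mode at basal plus a responding mode far above the
  # wild-type reference maximum: no single-parameter perturbation can
  # reach this shape
  ref <- wt_ref_sample(4000)
  set.seed(31)
  make_wide <- function(r) {
    comp <- rbinom(4000, 1, 0.5)
    x <- ifelse(comp == 1, rlnorm(4000, 2.5, 0.6),
                rlnorm(4000, log(max(ref) * 3), 0.25))
    flow_sample("wide", paste0("r", r), "d1", "induced", x)
  }
  reps <- dplyr::bind_rows(lapply(1:4, make_wide))
  ctrl <- make_uninduced_controls(paste0("r", 1:4), rep("d1", 4),
                                  n_cells = 3000)
  sw <- sweep_parameter(p_base, "activity",
                        fractions = seq(0.2, 1, by = 0.2),
                        mutant_replicates = reps,
                        uninduced_controls = ctrl,
                        wt_reference_induced = ref, n_cells = 4000,
                        seed = 37)
  wt_kls <- wt_model_fit(p_base,
                         make_truth_reps("activity", 1, 4, 4000, seed = 41),
                         ctrl, ref, n_cells = 4000, seed = 37)
  fit <- best_fit_and_classify(sw, wt_kls, strain = "wide")
  expect_false(fit$explained)
  expect_gt(fit$best_mean_kl, mean(wt_kls))
})

test_that("attribution handles identical, separated, and mismatched sets", {
  ident <- attribute_parameter(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(ident$identifiable)
  expect_equal(ident$p_attribution, 1)
  a <- c(0.01, 0.02, 0.02, 0.03)
  b <- c(0.50, 0.60, 0.70, 0.80)
  at <- attribute_parameter(a, b)
  expect_true(at$identifiable)
  expect_equal(at$p_attribution, enumerate_wrs_two_sided(a, b))
  expect_equal(at$direction, "activity")
  expect_error(attribute_parameter(1:3, 1:4), "size mismatch")
})
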