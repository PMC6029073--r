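test_that("parameter validation catches invalid model settings", {
  expect_error(hog_params(k_tx = -1), "non-negative")
  expect_error(hog_params(t_end = 0), "t_end")
  expect_error(hog_params(activity_scale = 1.5), "\\[0, 1\\]")
  expect_error(hog_params(bogus = 1), "unknown")
  expect_error(simulate_population(hog_params(), n_cells = 0), "positive")
})

test_that("without any activation source nothing is ever expressed", {
  p <- hog_params(k_basal = 0, stress = 0)
  sim <- simulate_population(p, n_cells = 200, seed = 1)
  expect_true(all(sim$protein == 0))
  expect_true(all(sim$mrna == 0))
  tr <- simulate_trajectory(p, cell = 0, seed = 1)
  expect_true(all(tr$hog1p == 0))
})

test_that("simulation is deterministic given parameters and seed", {
  p <- hog_params()
  a <- simulate_population(p, 300, seed = 42)
  b <- simulate_population(p, 300, seed = 42)
  expect_identical(a$protein, b$protein)
  c <- simulate_population(p, 300, seed = 43)
  expect_false(identical(a$protein, c$protein))
  # cell i depends only on (seed, i): a longer run extends, not reshuffles
  d <- simulate_population(p, 400, seed = 42)
  expect_identical(d$protein[1:300], a$protein)
})

test_that("conservation laws hold at every event of a trajectory", {
  p <- hog_params()
  for (cell in 0:4) {
    tr <- simulate_trajectory(p, cell = cell, seed = 7)
    g <- tr$gene_state
    bound_hog <- as.numeric(g >= 2)
    bound_tf <- as.numeric(g >= 1)
    bound_rem <- as.numeric(g >= 3)
    bound_pol <- as.numeric(g == 4)
    expect_true(all(tr$hog1 + tr$hog1p + bound_hog == p$hog1_total))
    expect_true(all(tr$tf_free + bound_tf == p$tf_total))
    expect_true(all(tr$rem_free + bound_rem == p$remodeler_total))
    expect_true(all(tr$pol_free + bound_pol == p$polymerase_total))
    expect_true(all(g %in% 0:4))
    # protein only accumulates
    expect_true(all(diff(tr$protein) >= 0))
    # counts stay non-negative
    expect_true(all(tr$mrna >= 0))
  }
})

test_that("mean protein responds monotonically to stress and both scales", {
  n <- 5000
  mean_se <- function(...) {
    s <- simulate_population(hog_params(...), n, seed = 5)
    c(mean(s$protein), sd(s$protein) / sqrt(n))
  }
  lo_s <- mean_se(stress = 4); hi_s <- mean_se(stress = 18)
  expect_gt(hi_s[1] - lo_s[1], -3 * sqrt(lo_s[2]^2 + hi_s[2]^2))
  lo_a <- mean_se(activity_scale = 0.3); hi_a <- mean_se()
  expect_gt(hi_a[1] - lo_a[1], 3 * sqrt(lo_a[2]^2 + hi_a[2]^2))
  lo_r <- mean_se(remodeling_scale = 0.2); hi_r <- mean_se()
  expect_gt(hi_r[1] - lo_r[1], 3 * sqrt(lo_r[2]^2 + hi_r[2]^2))
})

test_that("mean-field solution is zero without activation and matches the birth-death limit", {
  p0 <- hog_params(k_basal = 0, stress = 0)
  mf <- mean_field_solution(p0)
  expect_true(all(mf$hog1p == 0))
  expect_true(all(mf$mrna == 0))
  expect_true(all(mf$protein == 0))
  # constitutively active gene: assembly instantaneous-ish, no off/dephos
  pc <- hog_params(k_basal = 1, stress = 0, k_dephos = 0,
                   c_tfon = 10, c_hogon = 10, c_remon = 10, c_polon = 10,
                   k_off_tf = 0, k_off_hog = 0, k_off_rem = 0,
                   k_off_pol = 0, k_tx = 0.05, k_deg_mrna = 1e-3,
                   t_end = 20000)
  mfc <- mean_field_solution(pc, times = c(0, 20000))
  expect_equal(mfc$mrna[2], pc$k_tx / pc$k_deg_mrna, tolerance = 1e-3)
})

test_that("stochastic population means agree with the mean-field oracle", {
  # large copy numbers damp species correlations; n = 2000 cells
  p10 <- hog_params(hog1_total = 1000, tf_total = 500,
                    remodeler_total = 300, polymerase_total = 300)
  sim <- simulate_population(p10, 2000, seed = 31)
  mf <- mean_field_solution(p10, times = c(0, p10$t_end))
  z_p <- (mean(sim$protein) - mf$protein[2]) /
    (sd(sim$protein) / sqrt(2000))
  z_m <- (mean(sim$mrna) - mf$mrna[2]) / (sd(sim$mrna) / sqrt(2000))
  expect_lt(abs(z_p), 3)
  expect_lt(abs(z_m), 3)
})
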