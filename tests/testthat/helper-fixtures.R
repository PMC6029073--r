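# shared fixtures built in code

# closed-form KL between two normals, in nats
kl_normal <- function(mu1, sd1, mu2, sd2) {
  log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5
}

# exhaustive one-sided rank-sum p-value: P(sum of mutant ranks >= observed)
# over all assignments of the pooled ranks
enumerate_wrs_greater <- function(x, y) {
  pooled <- rank(c(x, y))
  n <- length(x)
  obs <- sum(pooled[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(idx) sum(pooled[idx]))
  mean(stats >= obs)
}

# exhaustive two-sided rank-sum p-value (doubled smaller tail, capped at 1)
enumerate_wrs_two_sided <- function(x, y) {
  pooled <- rank(c(x, y))
  n <- length(x)
  obs <- sum(pooled[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(idx) sum(pooled[idx]))
  min(1, 2 * min(mean(stats >= obs), mean(stats <= obs)))
}

# small uninduced-control flow tibble matching given replicate/day pairs,
# built from the model's no-stress population
make_uninduced_controls <- function(reps, days, n_cells = 3000,
                                    seed = 77L, strain = "ctrl") {
  p0 <- hog_params(stress = 0)
  rows <- lapply(seq_along(reps), function(i) {
    sim <- simulate_population(p0, n_cells = n_cells, seed = seed + i)
    flow_sample(strain, reps[i], days[i], "uninduced",
                add_basal(sim$protein, seed = seed + 100L + i))
  })
  dplyr::bind_rows(rows)
}
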