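#' Two-group perturbation signature of the activation model
#'
#' Runs the computational experiment distinguishing the two
#' phenomenological parameter groups: for each seed, simulates the
#' unperturbed model and populations with the activity scale reduced and
#' with each downstream assembly on-rate reduced, then summarises each
#' population with [summarize_modes()]. Activity reductions move the
#' responding-mode location (and its mass); downstream on-rate reductions
#' move mass out of the responding component while leaving its location
#' approximately unchanged.
#'
#' The Hog1 on-rate `c_hogon` is not part of the downstream battery: its
#' propensity enters only through the product of the rate and the Hog1-P
#' level, which makes it kinetically indistinguishable from the activity
#' scale in this network (see the package vignette).
#'
#' @param params Base [hog_params()].
#' @param n_cells Cells per population (default 10000).
#' @param activity_fractions Scales applied to the activity group.
#' @param downstream_fraction Scale applied to each downstream on-rate.
#' @param seeds Integer vector of master seeds.
#' @param basal_mu,basal_sigma Basal fluorescence constants added before
#'   summarisation.
#' @return A tibble with one row per (seed, perturbation): columns
#'   `seed`, `perturbation`, `fraction`, `responding_mass`,
#'   `responding_mode`, `mode_ratio` and `mass_drop` (relative to the
#'   same seed's unperturbed run).
#' @export
two_group_signature <- function(params = hog_params(), n_cells = 10000,
                                activity_fractions = c(0.5, 0.25),
                                downstream_fraction = 0.5,
                                seeds = 1:5,
                                basal_mu = 2.5, basal_sigma = 0.6) {
  run <- function(seed, group, fraction) {
    p <- if (is.null(group)) params else scale_group(params, group, fraction)
    sim <- simulate_population(p, n_cells, seed = seed)
    x <- add_basal(sim$protein, basal_mu, basal_sigma,
                   seed = derive_seed(seed, 31L))
    s <- summarize_modes(x)
    tibble::tibble(
      seed = seed,
      perturbation = if (is.null(group)) "none" else group,
      fraction = if (is.null(group)) 1 else fraction,
      responding_mass = s$mass[s$component == "responding"],
      responding_mode = s$mode[s$component == "responding"]
    )
  }
  downstream <- c("c_tfon", "remodeling", "c_polon")
  rows <- purrr::map(seeds, function(s) {
    base <- run(s, NULL, 1)
    pert <- dplyr::bind_rows(
      purrr::map(activity_fractions, ~run(s, "activity", .x)),
      purrr::map(downstream, ~run(s, .x, downstream_fraction))
    )
    pert$mode_ratio <- pert$responding_mode / base$responding_mode
    pert$mass_drop <- base$responding_mass - pert$responding_mass
    dplyr::bind_rows(base, pert)
  })
  dplyr::bind_rows(rows)
}

#' Parameter-recovery battery on ground-truth model mutants
#'
#' For each seed, generates ground-truth mutants from the model itself at
#' the given fractions of the activity and remodeling scales (4 induced
#' replicates each), then runs the full fitting pipeline: a sweep of each
#' parameter group over `grid` (one simulated population per fraction,
#' reused across replicates; per-replicate calibration against the
#' replicate's uninduced control, a wild-type reference maximum, and
#' linear extension) and selection of the divergence-minimising fraction.
#' Records whether the matching-group sweep recovers the true fraction
#' within one grid step, and, where both sweeps were run, whether the
#' overall best group matches the truth.
#'
#' @param params Base [hog_params()].
#' @param seeds Integer vector of battery seeds.
#' @param truth_fractions Fractions at which truth mutants are generated.
#' @param grid Sweep grid (default `seq(0.15, 0.85, by = 0.05)`, 15
#'   points with every truth fraction interior to the grid, so the
#'   argmin is not handicapped at a boundary).
#' @param n_cells_grid Cells per sweep population (default 10000).
#' @param n_events_rep Events per truth replicate (default 25000).
#' @param n_replicates Truth replicates per mutant (default 4).
#' @param attribution_fractions Truth fractions at which both groups are
#'   swept and best-group attribution is recorded (default 0.25).
#' @return A tibble with one row per (seed, group, fraction): columns
#'   `seed`, `truth_group`, `truth_fraction`, `best_fraction`,
#'   `recovered` (within one grid step), `best_group`, `attr_correct`
#'   (NA where only the matching group was swept).
#' @export
recovery_battery <- function(params = hog_params(), seeds = 1:20,
                             truth_fractions = c(0.25, 0.5, 0.75),
                             grid = seq(0.15, 0.85, by = 0.05),
                             n_cells_grid = 10000, n_events_rep = 25000,
                             n_replicates = 4,
                             attribution_fractions = 0.25) {
  step <- if (length(grid) > 1) min(diff(grid)) else 0.05
  groups <- c("activity", "remodeling")
  out <- purrr::map(seeds, function(s) {
    ref <- add_basal(
      simulate_population(params, n_events_rep,
                          seed = derive_seed(s, 900L))$protein,
      seed = derive_seed(s, 901L))
    ctrl <- dplyr::bind_rows(purrr::map(seq_len(n_replicates), function(r) {
      p0 <- params; p0$stress <- 0
      sim <- simulate_population(p0, n_cells_grid,
                                 seed = derive_seed(s, 910L + r))
      flow_sample("ctrl", paste0("r", r), "d1", "uninduced",
                  add_basal(sim$protein, seed = derive_seed(s, 920L + r)))
    }))
    # truth replicates for every (group, fraction), labelled so one sweep
    # per group scores them all against a shared simulation grid
    truths <- dplyr::bind_rows(purrr::map(groups, function(g) {
      dplyr::bind_rows(purrr::map(truth_fractions, function(f) {
        dplyr::bind_rows(purrr::map(seq_len(n_replicates), function(r) {
          gen_model_truth_mutant(
            params, g, f, n_cells = n_events_rep,
            seed = derive_seed(s, round(1e4 * f) + 40L * r +
                                 ifelse(g == "activity", 0L, 7L)),
            strain = paste0(g, "_", f), replicate = paste0(g, f, "r", r),
            day = "d1")
        }))
      }))
    }))
    ctrl_all <- dplyr::bind_rows(purrr::map(
      unique(truths$replicate), function(rid) {
        i <- (match(rid, unique(truths$replicate)) - 1) %% n_replicates + 1
        c2 <- ctrl[i, ]
        c2$replicate <- rid
        c2
      }))
    sweeps <- purrr::map(groups, function(g) {
      # the 0.999-quantile alignment is used instead of the strict
      # maximum: it is independent of sample size (reference replicates
      # and model populations differ in size) and far less noisy, so it
      # does not tilt or shift the divergence-vs-fraction profile
      sweep_parameter(params, g, fractions = grid,
                      mutant_replicates = truths,
                      uninduced_controls = ctrl_all,
                      wt_reference_induced = ref,
                      n_cells = n_cells_grid, max_quantile = 0.999,
                      seed = derive_seed(s, if (g == "activity") 5L else 6L))
    })
    names(sweeps) <- groups

    dplyr::bind_rows(purrr::map(groups, function(g) {
      dplyr::bind_rows(purrr::map(truth_fractions, function(f) {
        strain_reps <- truths$replicate[truths$truth_group == g &
                                          truths$truth_fraction == f]
        pick <- function(sw) sw[sw$replicate %in% strain_reps, ]
        own <- pick(sweeps[[g]])
        own_summ <- own |>
          dplyr::group_by(.data$fraction) |>
          dplyr::summarise(mean_kl = mean(.data$kl_nats),
                           .groups = "drop")
        best_own <- own_summ$fraction[which.min(own_summ$mean_kl)]
        attr_ok <- NA
        best_group <- NA_character_
        if (f %in% attribution_fractions) {
          other <- pick(sweeps[[setdiff(groups, g)]])
          other_summ <- other |>
            dplyr::group_by(.data$fraction) |>
            dplyr::summarise(mean_kl = mean(.data$kl_nats),
                             .groups = "drop")
          best_group <- if (min(own_summ$mean_kl) <=
                              min(other_summ$mean_kl)) g else
            setdiff(groups, g)
          attr_ok <- best_group == g
        }
        tibble::tibble(seed = s, truth_group = g, truth_fraction = f,
                       best_fraction = best_own,
                       recovered = abs(best_own - f) <= step + 1e-9,
                       best_group = best_group, attr_correct = attr_ok)
      }))
    }))
  })
  dplyr::bind_rows(out)
}

#' Family-wise error of the testing pipeline on null experiments
#'
#' Generates fully null synthetic batteries - a day-structured wild-type
#' experiment plus `n_strains` additional strains drawn from the same
#' wild-type law - runs the complete pooling/divergence/rank-sum pipeline
#' with Bonferroni correction, and reports, for each battery, whether any
#' strain was (falsely) called significant.
#'
#' @param n_batteries Number of independent null batteries (default 200).
#' @param n_strains Null strains tested per battery (default 17, also the
#'   Bonferroni family size).
#' @param n_events Events per sample (default 2000; calibration of the
#'   null does not depend on the event count).
#' @param n_wt_days Wild-type days per battery (default 11, giving about
#'   38 wild-type records).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed.
#' @return Logical vector of length `n_batteries`: battery produced at
#'   least one false positive.
#' @export
null_fwer_battery <- function(n_batteries = 200, n_strains = 17,
                              n_events = 2000, n_wt_days = 11,
                              alpha = 0.05, seed = 1L) {
  vapply(seq_len(n_batteries), function(b) {
    base_seed <- derive_seed(seed, 131L * b)
    wt <- gen_wt_experiment(synthetic_spec(
      n_days = n_wt_days, n_events = n_events, seed = base_seed))
    muts <- dplyr::bind_rows(purrr::map(seq_len(n_strains), function(k) {
      # same day_seed as the wild type: strains of one experiment share
      # their day-level batch effects
      gen_wt_experiment(synthetic_spec(
        n_days = 2, reps_per_day = 3, n_events = n_events,
        seed = derive_seed(base_seed, k), day_seed = base_seed),
        strain = paste0("null", k))
    }))
    res <- divergence_test(dplyr::bind_rows(wt, muts),
                           m_tests = n_strains, alpha = alpha)
    any(res$tests$significant)
  }, logical(1))
}
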