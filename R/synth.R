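#' Specification of a synthetic flow-cytometry experiment
#'
#' Describes the generative law used to emulate a day-structured reporter
#' experiment: per-cell fluorescence is lognormal (positive and
#' right-skewed, as reporter intensities are), with a common day-level
#' batch shift applied to all replicates of a day and a smaller
#' replicate-level shift giving realistic replicate-to-pool divergence.
#'
#' Defaults place uninduced and induced log-means two natural-log units
#' apart (a ~7-fold induction) with log-sd 0.5; the replicate jitter
#' (`rep_batch_sd = 0.12`) is calibrated so that the median divergence of
#' a wild-type replicate from its same-day pool is of order 0.01-0.02
#' nats, matching the replicate-noise scale such assays exhibit.
#'
#' @param n_days Number of experiment days.
#' @param reps_per_day Replicates per day; `NULL` (default) draws 3 or 4
#'   per day, the usual design.
#' @param n_events Events (cells) per sample, default 50000.
#' @param uninduced_law,induced_law Length-2 numeric `(log-mean, log-sd)`.
#' @param day_batch_sd Log-scale sd of the shared day shift.
#' @param rep_batch_sd Log-scale sd of the per-replicate shift.
#' @param seed Integer seed; all generation is a pure function of the spec.
#' @param day_seed Seed for the day-level batch shifts (default: `seed`).
#'   Strains measured in the same experiment share their day effects, so
#'   when generating several strains for one experiment give them all
#'   the same `day_seed` (and distinct `seed`s): each day's shift is a
#'   function of `(day_seed, day)` only and is then identical across the
#'   strains, as a shared batch effect must be.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_days = 3L, reps_per_day = NULL,
                           n_events = 50000L,
                           uninduced_law = c(4.0, 0.5),
                           induced_law = c(6.0, 0.5),
                           day_batch_sd = 0.05, rep_batch_sd = 0.12,
                           seed = 1L, day_seed = NULL) {
  spec <- list(n_days = as.integer(n_days), reps_per_day = reps_per_day,
               n_events = as.integer(n_events),
               uninduced_law = as.numeric(uninduced_law),
               induced_law = as.numeric(induced_law),
               day_batch_sd = as.numeric(day_batch_sd),
               rep_batch_sd = as.numeric(rep_batch_sd),
               seed = as.integer(seed),
               day_seed = if (is.null(day_seed)) as.integer(seed) else
                 as.integer(day_seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  if (!is.numeric(spec$n_days) || spec$n_days < 1) {
    stop("synthetic_spec(): `n_days` must be >= 1")
  }
  if (!is.null(spec$reps_per_day) &&
      (!is.numeric(spec$reps_per_day) || any(spec$reps_per_day < 1))) {
    stop("synthetic_spec(): `reps_per_day` must be >= 1")
  }
  if (!is.numeric(spec$n_events) || length(spec$n_events) != 1 ||
      is.na(spec$n_events) || spec$n_events < 100) {
    stop("synthetic_spec(): `n_events` must be >= 100")
  }
  for (nm in c("uninduced_law", "induced_law")) {
    v <- spec[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[2] <= 0) {
      stop("synthetic_spec(): `", nm, "` must be (log-mean, log-sd > 0)")
    }
  }
  if (spec$day_batch_sd < 0 || spec$rep_batch_sd < 0) {
    stop("synthetic_spec(): batch sds must be non-negative")
  }
  invisible(spec)
}

#' Describe a mutant's effect on the induced reporter distribution
#'
#' Two phenomenological effect classes are supported, mirroring what is
#' seen in reporter assays of signaling mutants: `"graded"` mutants shift
#' the whole induced population toward the uninduced state by a fraction
#' `magnitude` of the wild-type induction gap (log scale), while
#' `"bimodal"` mutants split the population into a non-responding
#' component, identical in law to the uninduced state, with mixture weight
#' `magnitude`, and a weakly responding component whose induction gap is
#' reduced by `weak_mode_attenuation`.
#'
#' @param kind `"graded"` or `"bimodal"`.
#' @param magnitude In `[0, 1]`: fraction of the induction gap removed
#'   (graded) or mixture weight of non-responders (bimodal).
#' @param weak_mode_attenuation In `[0, 1]`, bimodal only: fraction of the
#'   gap removed in the responding component.
#' @return A list of class `"mutant_effect"`.
#' @export
mutant_effect <- function(kind = c("graded", "bimodal"), magnitude,
                          weak_mode_attenuation = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || length(magnitude) != 1 ||
      is.na(magnitude) || magnitude < 0 || magnitude > 1) {
    stop("mutant_effect(): `magnitude` must lie in [0, 1]")
  }
  if (weak_mode_attenuation < 0 || weak_mode_attenuation > 1) {
    stop("mutant_effect(): `weak_mode_attenuation` must lie in [0, 1]")
  }
  structure(list(kind = kind, magnitude = magnitude,
                 weak_mode_attenuation = weak_mode_attenuation),
            class = "mutant_effect")
}

# shared generator: WT and effect mutants differ only in the induced
# log-mean (graded) or in a per-cell mixture relabeling (bimodal), and the
# random number stream is consumed identically for a given spec + seed, so
# a zero-magnitude mutant reproduces the WT sample exactly.
generate_experiment <- function(spec, strain, effect = NULL) {
  validate_synthetic_spec(spec)
  u <- spec$uninduced_law
  i <- spec$induced_law
  gap <- i[1] - u[1]
  # day effects are a function of (day_seed, day) alone, so strains
  # generated for the same experiment share them exactly
  day_shifts <- vapply(seq_len(spec$n_days), function(d) {
    withr::with_seed(derive_seed(spec$day_seed, 7000L + d),
                     stats::rnorm(1, 0, spec$day_batch_sd))
  }, numeric(1))
  withr::with_seed(spec$seed, {
    rows <- list()
    for (d in seq_len(spec$n_days)) {
      nrep <- if (is.null(spec$reps_per_day)) sample(3:4, 1) else
        spec$reps_per_day
      day_shift <- day_shifts[d]
      for (r in seq_len(nrep)) {
        rep_shift_u <- stats::rnorm(1, 0, spec$rep_batch_sd)
        rep_shift_i <- stats::rnorm(1, 0, spec$rep_batch_sd)
        z_u <- stats::rnorm(spec$n_events)
        z_i <- stats::rnorm(spec$n_events)
        mix <- stats::runif(spec$n_events)
        unind <- exp(u[1] + day_shift + rep_shift_u + u[2] * z_u)
        if (is.null(effect)) {
          ind_lmean <- i[1]
          ind <- exp(ind_lmean + day_shift + rep_shift_i + i[2] * z_i)
        } else if (effect$kind == "graded") {
          ind_lmean <- u[1] + (1 - effect$magnitude) * gap
          ind <- exp(ind_lmean + day_shift + rep_shift_i + i[2] * z_i)
        } else {
          weak_lmean <- u[1] + (1 - effect$weak_mode_attenuation) * gap
          non_resp <- mix < effect$magnitude
          lmean <- ifelse(non_resp, u[1], weak_lmean)
          lsd <- ifelse(non_resp, u[2], i[2])
          ind <- exp(lmean + day_shift + rep_shift_i + lsd * z_i)
        }
        rid <- paste0("d", d, "r", r)
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          flow_sample(strain, rid, paste0("d", d), "uninduced", unind),
          flow_sample(strain, rid, paste0("d", d), "induced", ind)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic wild-type experiment
#'
#' For each day and replicate of the design in `spec`, draws one uninduced
#' and one induced sample. Induced samples are unimodal and right-shifted
#' from uninduced; the replicate-level jitter produces replicate-to-pool
#' divergences on the order of 0.01 nats.
#'
#' @param spec A [synthetic_spec()].
#' @param strain Strain label for the generated samples (default `"WT"`).
#' @return A flow-sample tibble.
#' @export
gen_wt_experiment <- function(spec, strain = "WT") {
  generate_experiment(spec, strain, effect = NULL)
}

#' Generate a synthetic mutant experiment
#'
#' Same design as [gen_wt_experiment()] (and, for a given `spec` seed,
#' the same random draws), with the induced law altered per `effect`.
#' Uninduced samples are identical in law to wild type. A graded effect of
#' magnitude 0 reproduces the wild-type samples exactly at the same seed.
#'
#' @param spec A [synthetic_spec()].
#' @param effect A [mutant_effect()].
#' @param strain Strain label.
#' @return A flow-sample tibble.
#' @export
gen_effect_mutant <- function(spec, effect, strain = "mutant") {
  stopifnot(inherits(effect, "mutant_effect"))
  generate_experiment(spec, strain, effect = effect)
}

#' Generate a ground-truth model mutant from the stochastic model
#'
#' Simulates the HOG activation model with one parameter group scaled to
#' `fraction`, adds the lognormal basal-expression constant, and returns
#' an induced flow sample whose true generating group and fraction are
#' recorded in columns `truth_group` and `truth_fraction`. Used for
#' parameter-recovery tests of the fitting pipeline.
#'
#' @param params Base [hog_params()].
#' @param which `"activity"` or `"remodeling"`.
#' @param fraction Scale in `[0, 1]` applied to the group's rate.
#' @param n_cells Events to simulate (default 25000).
#' @param basal_mu,basal_sigma Lognormal basal-expression parameters
#'   (defaults 2.5, 0.6).
#' @param seed Integer seed.
#' @param strain,replicate,day Metadata for the generated sample.
#' @return A one-row flow-sample tibble with truth columns.
#' @export
gen_model_truth_mutant <- function(params, which = c("activity", "remodeling"),
                                   fraction, n_cells = 25000,
                                   basal_mu = 2.5, basal_sigma = 0.6,
                                   seed = 1L, strain = "model_mutant",
                                   replicate = "r1", day = "d1") {
  which <- match.arg(which)
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("gen_model_truth_mutant(): `fraction` must lie in [0, 1]")
  }
  p <- params
  if (which == "activity") p$activity_scale <- fraction
  else p$remodeling_scale <- fraction
  sim <- simulate_population(p, n_cells = n_cells, seed = seed)
  fluor <- add_basal(sim$protein, basal_mu = basal_mu,
                     basal_sigma = basal_sigma,
                     seed = derive_seed(seed, 211L))
  out <- flow_sample(strain, replicate, day, "induced", fluor)
  out$truth_group <- which
  out$truth_fraction <- fraction
  out
}

# fold (seed, stream) into a valid 32-bit R seed
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}
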