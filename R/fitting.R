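#' Sweep one parameter-group scale and score the model against replicates
#'
#' For each fraction of the grid, simulates a population with the chosen
#' parameter group scaled to that fraction, converts counts to
#' fluorescence, and estimates the divergence of every mutant replicate
#' from the calibrated model prediction. One population is simulated per
#' fraction and reused across replicates.
#'
#' The molecule-to-fluorescence transform is a property of the reporter
#' and instrument, not of the perturbation, so it is fitted per replicate
#' from the *unperturbed* model (lognormal basal constant added, maximum
#' aligned to the wild-type reference replicate, uninduced-simulation
#' mean aligned to the replicate's uninduced control) and then held fixed
#' across the whole fraction grid; each perturbed population is mapped
#' through the same transform and extended to the replicate's range
#' before the divergence is estimated. Refitting the maximum alignment on
#' every perturbed population would rescale the perturbation away and
#' flatten the divergence profile.
#'
#' @param base_params Unperturbed [hog_params()].
#' @param parameter_group One of `"activity"`, `"remodeling"`,
#'   `"c_tfon"`, `"c_hogon"`, `"c_polon"`: the rate whose scale is swept.
#' @param fractions Strictly increasing grid of scales in `[0, 1]`. The
#'   default, `seq(0.05, 1, by = 0.05)`, spans 20 perturbations per
#'   parameter; pass `seq(0, 0.5, by = 0.05)` to restrict to strong
#'   perturbations.
#' @param mutant_replicates Flow-sample tibble of induced mutant
#'   replicates.
#' @param uninduced_controls Flow-sample tibble of the matching uninduced
#'   controls (matched to replicates by `replicate` + `day`).
#' @param wt_reference_induced Numeric vector (or one-row flow tibble):
#'   wild-type induced replicate used for maximum alignment; it must be
#'   excluded from any divergence comparison elsewhere.
#' @param n_cells Cells per simulated population (default 10000).
#' @param seed Master seed; fraction i uses substream (seed, i).
#' @param basal_mu,basal_sigma Basal-expression constants.
#' @param max_quantile Quantile used as the "maximum" in the alignment
#'   constraint (default 1, the strict maximum; a robust quantile such
#'   as 0.999 is sample-size-independent and less noisy).
#' @param method KL estimator variant.
#' @return A tibble of class `"hog_sweep"` with columns
#'   `parameter_group`, `fraction`, `replicate`, `day`, `kl_nats`, plus
#'   attributes `summary` (per-fraction mean/SE) and `n_cells`.
#' @export
sweep_parameter <- function(base_params, parameter_group, fractions = seq(0, 1, by = 0.05),
                            mutant_replicates, uninduced_controls,
                            wt_reference_induced, n_cells = 10000,
                            seed = 1L, basal_mu = 2.5, basal_sigma = 0.6,
                            max_quantile = 1, method = "ecdf") {
  parameter_group <- match.arg(parameter_group,
                               c("activity", "remodeling", "c_tfon",
                                 "c_hogon", "c_polon"))
  if (length(fractions) == 0) stop("sweep_parameter(): empty fraction grid")
  if (any(fractions < 0 | fractions > 1)) {
    stop("sweep_parameter(): fractions must lie in [0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("sweep_parameter(): fractions must be strictly increasing")
  }
  validate_flow_samples(mutant_replicates)
  validate_flow_samples(uninduced_controls)
  wt_ref <- if (is.numeric(wt_reference_induced)) wt_reference_induced else
    wt_reference_induced$intensities[[1]]
  ind <- dplyr::filter(mutant_replicates, .data$condition == "induced")
  if (nrow(ind) == 0) stop("sweep_parameter(): no induced mutant replicates")
  ctrl_key <- paste(uninduced_controls$replicate, uninduced_controls$day)
  ctrl_of <- function(rep, day) {
    i <- match(paste(rep, day), ctrl_key)
    if (is.na(i)) {
      stop("sweep_parameter(): missing uninduced control for replicate ",
           rep, " day ", day)
    }
    uninduced_controls$intensities[[i]]
  }

  # uninduced model population: no stress, shared across fractions
  p0 <- base_params
  p0$stress <- 0
  sim_unind <- simulate_population(p0, n_cells = n_cells,
                                   seed = derive_seed(seed, 101L))
  unind_fluor <- add_basal(sim_unind$protein, basal_mu, basal_sigma,
                           seed = derive_seed(seed, 102L))

  # unperturbed population: anchors the fluorescence transform; its
  # substream is the one the 1.0 grid column uses, so the baseline column
  # of any grid reproduces the unperturbed wild-type model fit exactly
  base_fluor <- add_basal(
    simulate_population(base_params, n_cells = n_cells,
                        seed = derive_seed(seed, 10000L))$protein,
    basal_mu, basal_sigma, seed = derive_seed(seed, 510000L))
  calibs <- purrr::map2(ind$replicate, ind$day, function(rep, day) {
    fit_calibration(base_fluor, unind_fluor, wt_ref, ctrl_of(rep, day),
                    max_quantile = max_quantile)
  })

  # every fraction reuses the unperturbed population's random substreams
  # (common random numbers): per-point sampling noise is then shared
  # along the grid and cancels when fractions are compared, smoothing the
  # divergence profile without biasing any single point
  rows <- purrr::map(fractions, function(f) {
    fluor <- if (f == 1) base_fluor else {
      p <- scale_group(base_params, parameter_group, f)
      add_basal(
        simulate_population(p, n_cells = n_cells,
                            seed = derive_seed(seed, 10000L))$protein,
        basal_mu, basal_sigma, seed = derive_seed(seed, 510000L))
    }
    purrr::pmap(list(ind$replicate, ind$day, ind$intensities,
                     calibs),
                function(rep, day, x, calib) {
      model <- calibrate_simulation(fluor, calib, x)
      tibble::tibble(parameter_group = parameter_group, fraction = f,
                     replicate = rep, day = day,
                     kl_nats = as.numeric(estimate_kl(x, model,
                                                      method = method)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summ <- rows |>
    dplyr::group_by(.data$parameter_group, .data$fraction) |>
    dplyr::summarise(mean_kl = mean(.data$kl_nats),
                     se_kl = stats::sd(.data$kl_nats) /
                       sqrt(dplyr::n()),
                     n_replicates = dplyr::n(), .groups = "drop")
  attr(rows, "summary") <- summ
  attr(rows, "n_cells") <- n_cells
  attr(rows, "seed") <- seed
  class(rows) <- c("hog_sweep", class(rows))
  rows
}

# apply a fraction to the chosen parameter group
scale_group <- function(params, group, fraction) {
  p <- params
  switch(group,
         activity = { p$activity_scale <- fraction },
         remodeling = { p$remodeling_scale <- fraction },
         { p[[group]] <- p[[group]] * fraction })
  p
}

#' Per-fraction summary of a sweep
#'
#' @param sweep A `"hog_sweep"` tibble.
#' @return Tibble with `parameter_group`, `fraction`, `mean_kl`, `se_kl`,
#'   `n_replicates`.
#' @export
sweep_summary <- function(sweep) {
  attr(sweep, "summary")
}

#' Select the best-fitting perturbation and classify the mutant
#'
#' Finds the (parameter group, fraction) minimising the mean divergence
#' over all sweeps, then asks whether the best fit is as good as the
#' wild-type fit of the unperturbed model: the mutant is *explained* by
#' the model unless a one-sided rank-sum test finds the mutant's best-fit
#' divergences significantly greater than the wild-type-to-model
#' divergences. When both an activity and a remodeling sweep are present,
#' the two groups' best divergence sets are also compared two-sidedly to
#' ask whether the affected parameter is identifiable.
#'
#' @param sweeps A `"hog_sweep"` tibble or list of them (typically one per
#'   parameter group).
#' @param wt_model_divergences Numeric vector (or divergence-record
#'   tibble) of wild-type replicate divergences from the unperturbed,
#'   identically calibrated model.
#' @param alpha Significance level (default 0.05).
#' @param strain Strain label for the result.
#' @return An object of class `"hog_fit"`: a list with `strain`,
#'   `best_group`, `best_fraction`, `best_mean_kl`, `explained`,
#'   `p_explained`, `parameter_identifiable`, `p_attribution`,
#'   `best_kls` (per-replicate divergences at the optimum), `summary`
#'   (per group x fraction means), and `wt_model_kls`.
#' @export
best_fit_and_classify <- function(sweeps, wt_model_divergences,
                                  alpha = 0.05, strain = "mutant") {
  if (inherits(sweeps, "hog_sweep")) sweeps <- list(sweeps)
  if (length(sweeps) == 0) stop("best_fit_and_classify(): no sweeps given")
  all_rows <- dplyr::bind_rows(lapply(sweeps, tibble::as_tibble))
  wt_kls <- if (is.numeric(wt_model_divergences)) wt_model_divergences else
    wt_model_divergences$kl_nats

  summ <- all_rows |>
    dplyr::group_by(.data$parameter_group, .data$fraction) |>
    dplyr::summarise(mean_kl = mean(.data$kl_nats),
                     se_kl = stats::sd(.data$kl_nats) / sqrt(dplyr::n()),
                     .groups = "drop")
  usable <- dplyr::filter(summ, is.finite(.data$mean_kl))
  if (nrow(usable) == 0) {
    stop("best_fit_and_classify(): all sweep columns are degenerate ",
         "(non-finite divergence)")
  }
  # argmin; ties broken toward the fraction closest to 1 (most
  # conservative perturbation)
  best <- usable |>
    dplyr::filter(.data$mean_kl <= min(.data$mean_kl) + 1e-12) |>
    dplyr::arrange(dplyr::desc(.data$fraction)) |>
    dplyr::slice(1)
  best_kls <- all_rows$kl_nats[
    all_rows$parameter_group == best$parameter_group &
      all_rows$fraction == best$fraction]

  p_explained <- wrs_p(best_kls, wt_kls, "greater")
  explained <- !(p_explained < alpha)

  ident <- NA
  p_attr <- NA_real_
  groups <- unique(all_rows$parameter_group)
  if (all(c("activity", "remodeling") %in% groups)) {
    bg <- function(g) {
      s <- dplyr::filter(usable, .data$parameter_group == g)
      bf <- s$fraction[which.min(s$mean_kl)]
      all_rows$kl_nats[all_rows$parameter_group == g &
                         all_rows$fraction == bf]
    }
    at <- attribute_parameter(bg("activity"), bg("remodeling"),
                              alpha = alpha)
    ident <- at$identifiable
    p_attr <- at$p_attribution
  }

  structure(list(
    strain = strain,
    best_group = best$parameter_group,
    best_fraction = best$fraction,
    best_mean_kl = best$mean_kl,
    explained = explained,
    p_explained = p_explained,
    parameter_identifiable = ident,
    p_attribution = p_attr,
    alpha = alpha,
    best_kls = best_kls,
    wt_model_kls = wt_kls,
    summary = summ
  ), class = "hog_fit")
}

#' Test whether the affected parameter group is identifiable
#'
#' Two-sided Wilcoxon rank-sum comparison of the per-replicate divergences
#' achieved by the best activity-perturbed model against those achieved by
#' the best remodeling-perturbed model. If the two sets differ
#' significantly, the data identify which group the mutation perturbs.
#'
#' @param activity_best_kls,remodeling_best_kls Numeric vectors of equal
#'   length: per-replicate divergences at each group's best fraction.
#' @param alpha Significance level.
#' @return A list: `identifiable` (logical), `p_attribution`, `direction`
#'   (`"activity"` or `"remodeling"`, the better-fitting group when
#'   identifiable, else `NA`).
#' @export
attribute_parameter <- function(activity_best_kls, remodeling_best_kls,
                                alpha = 0.05) {
  if (length(activity_best_kls) != length(remodeling_best_kls)) {
    stop("attribute_parameter(): divergence sets must come from the same ",
         "replicates (size mismatch: ", length(activity_best_kls), " vs ",
         length(remodeling_best_kls), ")")
  }
  if (identical(activity_best_kls, remodeling_best_kls)) {
    return(list(identifiable = FALSE, p_attribution = 1,
                direction = NA_character_))
  }
  p <- wrs_p(activity_best_kls, remodeling_best_kls, "two.sided")
  ident <- p < alpha
  dir <- if (!ident) NA_character_ else if (
    stats::median(activity_best_kls) < stats::median(remodeling_best_kls))
    "activity" else "remodeling"
  list(identifiable = ident, p_attribution = p, direction = dir)
}

#' Wild-type fit of the unperturbed model
#'
#' Convenience wrapper: runs a single-fraction (1.0) sweep of the
#' unperturbed model against wild-type replicates, giving the reference
#' divergence set used to classify mutants.
#'
#' @inheritParams sweep_parameter
#' @param wt_replicates Induced wild-type replicates (excluding the
#'   maximum-alignment reference replicate).
#' @return Numeric vector of per-replicate divergences.
#' @export
wt_model_fit <- function(base_params, wt_replicates, uninduced_controls,
                         wt_reference_induced, n_cells = 10000, seed = 1L,
                         basal_mu = 2.5, basal_sigma = 0.6,
                         max_quantile = 1, method = "ecdf") {
  sw <- sweep_parameter(base_params, "activity", fractions = 1,
                        mutant_replicates = wt_replicates,
                        uninduced_controls = uninduced_controls,
                        wt_reference_induced = wt_reference_induced,
                        n_cells = n_cells, seed = seed,
                        basal_mu = basal_mu, basal_sigma = basal_sigma,
                        max_quantile = max_quantile, method = method)
  sw$kl_nats
}
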