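#' Pool wild-type induced replicates of one experiment day
#'
#' Concatenates the induced intensities of all wild-type replicates
#' measured on one experiment day into the day's reference pool (the Q
#' distribution for divergence estimates). The usual design has 3-4
#' replicates per day; other counts are accepted with a warning.
#'
#' @param wt_samples Flow-sample tibble of wild-type samples (only
#'   `condition == "induced"` rows of the requested day are used).
#' @param experiment_day Day identifier to pool.
#' @return A list of class `"wt_pool"`: `day`, `intensities`,
#'   `source_replicates`.
#' @export
pool_wt <- function(wt_samples, experiment_day) {
  validate_flow_samples(wt_samples)
  sel <- wt_samples$day == experiment_day &
    wt_samples$condition == "induced"
  if (!any(sel)) {
    stop("pool_wt(): no wild-type induced samples for day ", experiment_day)
  }
  nrep <- sum(sel)
  if (nrep < 3 || nrep > 4) {
    warning("pool_wt(): day ", experiment_day, " has ", nrep,
            " replicates (3-4 expected under the default design)")
  }
  structure(list(
    day = experiment_day,
    strain = wt_samples$strain[sel][1],
    intensities = unlist(wt_samples$intensities[sel], use.names = FALSE),
    source_replicates = wt_samples$replicate[sel],
    source_lengths = wt_samples$n_events[sel]
  ), class = "wt_pool")
}

# pools for every day present in a WT sample tibble
pool_wt_by_day <- function(wt_samples) {
  days <- unique(wt_samples$day[wt_samples$condition == "induced"])
  pools <- lapply(days, function(d) suppressWarnings(pool_wt(wt_samples, d)))
  names(pools) <- days
  pools
}

#' Replicate-level divergences from same-day wild-type pools
#'
#' For every induced sample, estimates the Kullback-Leibler divergence of
#' the replicate (P) from the wild-type pool of the same experiment day
#' (Q). Wild-type replicates are, by default, compared against pools that
#' include themselves, matching the pooling-then-comparing procedure of
#' day-structured designs; set `leave_one_out = TRUE` to drop the
#' replicate's own events from its reference pool.
#'
#' @param samples Flow-sample tibble (induced rows are analysed).
#' @param pools Named list of `"wt_pool"` objects keyed by day, e.g. from
#'   [pool_wt()].
#' @param reference Label recorded in the output (default `"wt_pool"`).
#' @param leave_one_out Drop a wild-type replicate's own events from its
#'   reference pool (default `TRUE`). Comparing a replicate against a
#'   pool containing its own events damps its divergence by roughly
#'   `(1 - 1/n_replicates)^2` relative to strains not in the pool, which
#'   biases the downstream rank-sum test anticonservatively; excluding
#'   the replicate restores exchangeability between wild-type and null
#'   strains. If exclusion would leave fewer than 100 pool events, the
#'   full pool is used with a warning.
#' @param method KL estimator variant, passed to [estimate_kl()].
#' @return A tibble of divergence records: `strain`, `replicate`, `day`,
#'   `reference`, `kl_nats`, `n_p`, `n_q`.
#' @export
compute_divergences <- function(samples, pools, reference = "wt_pool",
                                leave_one_out = TRUE, method = "ecdf") {
  validate_flow_samples(samples)
  ind <- dplyr::filter(samples, .data$condition == "induced")
  recs <- purrr::pmap(
    list(ind$strain, ind$replicate, ind$day, ind$intensities),
    function(strain, replicate, day, x) {
      pool <- pools[[day]]
      if (is.null(pool)) {
        stop("compute_divergences(): no wild-type pool for day ", day,
             " (replicate ", strain, "/", replicate, ")")
      }
      q <- pool$intensities
      if (leave_one_out && identical(strain, pool$strain) &&
          replicate %in% pool$source_replicates) {
        # remove this replicate's own block from the concatenated pool
        idx <- which(pool$source_replicates == replicate)[1]
        off <- cumsum(c(0, pool$source_lengths))[idx]
        drop <- seq.int(off + 1, off + pool$source_lengths[idx])
        if (length(q) - length(drop) >= 100) {
          q <- q[-drop]
        } else {
          warning("compute_divergences(): leave-one-out would leave too ",
                  "few pool events for ", strain, "/", replicate,
                  "; using the full pool")
        }
      }
      tibble::tibble(
        strain = strain, replicate = replicate, day = day,
        reference = reference,
        kl_nats = as.numeric(estimate_kl(x, q, method = method)),
        n_p = length(x), n_q = length(q)
      )
    })
  dplyr::bind_rows(recs)
}

#' Test whether a mutant's divergences exceed wild-type self-divergence
#'
#' One-sided Wilcoxon rank-sum test of the mutant's replicate-to-pool
#' divergences against the wild-type replicates' divergences from their
#' own pools (alternative: mutant greater), with Bonferroni correction
#' for `m_tests` strains.
#'
#' @param mutant_records,wt_records Divergence-record tibbles (or numeric
#'   vectors of divergences).
#' @param m_tests Number of tests in the family for the Bonferroni
#'   correction (default 17).
#' @param alpha Family-wise significance level (default 0.05).
#' @param strain Optional strain label for the output (taken from
#'   `mutant_records` when available).
#' @return A one-row tibble: `strain`, `n_mutant`, `n_wt`,
#'   `median_mutant_kl`, `median_wt_kl`, `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
compare_to_wt <- function(mutant_records, wt_records, m_tests = 17L,
                          alpha = 0.05, strain = NULL) {
  mk <- if (is.numeric(mutant_records)) mutant_records else
    mutant_records$kl_nats
  wk <- if (is.numeric(wt_records)) wt_records else wt_records$kl_nats
  if (length(mk) == 0 || length(wk) == 0) {
    stop("compare_to_wt(): both record groups must be non-empty")
  }
  if (is.null(strain)) {
    strain <- if (!is.numeric(mutant_records) &&
                  "strain" %in% names(mutant_records)) {
      mutant_records$strain[1]
    } else "mutant"
  }
  if (length(mk) < 3 || length(wk) < 3) {
    warning("compare_to_wt(): fewer than 3 records in a group; ",
            "exact rank-sum test enforced")
  }
  p_raw <- wrs_p(mk, wk, "greater")
  p_corr <- min(1, m_tests * p_raw)
  tibble::tibble(
    strain = strain,
    n_mutant = length(mk), n_wt = length(wk),
    median_mutant_kl = stats::median(mk),
    median_wt_kl = stats::median(wk),
    p_raw = p_raw,
    p_corrected = p_corr,
    significant = p_corr < alpha
  )
}

#' Full divergence-testing pipeline over a set of strains
#'
#' Pools wild-type induced replicates by day, computes every replicate's
#' divergence from its same-day pool, and tests each non-wild-type strain
#' against the wild-type divergence records.
#'
#' @param samples Flow-sample tibble containing the wild-type strain and
#'   any number of mutant strains.
#' @param wt_strain Label of the wild-type strain (default `"WT"`).
#' @param m_tests Bonferroni family size (default 17; set to the number of
#'   strains actually tested if preferred).
#' @param alpha Significance level.
#' @param method KL estimator variant.
#' @param leave_one_out Passed to [compute_divergences()].
#' @return A list with `records` (all divergence records) and `tests`
#'   (one row per mutant strain, as from [compare_to_wt()]).
#' @export
divergence_test <- function(samples, wt_strain = "WT", m_tests = 17L,
                            alpha = 0.05, method = "ecdf",
                            leave_one_out = TRUE) {
  validate_flow_samples(samples)
  wt <- dplyr::filter(samples, .data$strain == wt_strain)
  if (nrow(wt) == 0) stop("divergence_test(): no samples for wild-type ",
                          "strain '", wt_strain, "'")
  pools <- pool_wt_by_day(wt)
  records <- compute_divergences(samples, pools, method = method,
                                 leave_one_out = leave_one_out)
  wt_recs <- dplyr::filter(records, .data$strain == wt_strain)
  tests <- records |>
    dplyr::filter(.data$strain != wt_strain) |>
    dplyr::group_by(.data$strain) |>
    dplyr::group_map(function(g, key) {
      compare_to_wt(g$kl_nats, wt_recs$kl_nats, m_tests = m_tests,
                    alpha = alpha, strain = key$strain)
    }) |>
    dplyr::bind_rows()
  list(records = records, tests = tests)
}
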