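#' Add lognormal basal expression to simulated protein counts
#'
#' Simulated reporter counts start at zero in unactivated cells, while real
#' cells show a positive basal fluorescence. A small lognormally
#' distributed constant (default parameters mu = 2.5, sigma = 0.6 of the
#' underlying normal of the logarithm) is added to each cell's count to
#' represent basal gene expression, making every value positive.
#'
#' @param protein_counts Non-negative numeric vector of per-cell counts.
#' @param basal_mu,basal_sigma Lognormal parameters (log scale); `basal_sigma`
#'   may be 0, in which case exactly `exp(basal_mu)` is added to every cell.
#' @param seed Integer seed for the basal draws.
#' @return Numeric vector, `protein_counts + lognormal noise`, all > 0.
#' @export
add_basal <- function(protein_counts, basal_mu = 2.5, basal_sigma = 0.6,
                      seed = 1L) {
  if (any(protein_counts < 0)) {
    stop("add_basal(): protein counts must be non-negative")
  }
  if (!is.numeric(basal_sigma) || length(basal_sigma) != 1 ||
      is.na(basal_sigma) || basal_sigma < 0) {
    stop("add_basal(): `basal_sigma` must be a non-negative number")
  }
  n <- length(protein_counts)
  basal <- if (basal_sigma == 0) {
    rep(exp(basal_mu), n)
  } else {
    withr::with_seed(seed, stats::rlnorm(n, basal_mu, basal_sigma))
  }
  protein_counts + basal
}

#' Fit the linear transform from simulation scale to fluorescence scale
#'
#' Solves the slope `a` and intercept `b` of the affine map `y = a x + b`
#' from two constraints: (1) the maximum intensity of the induced
#' simulation maps onto the maximum of a designated wild-type reference
#' replicate (that replicate is then excluded from divergence
#' comparisons); (2) the mean of the uninduced simulation maps onto the
#' mean of the uninduced experimental control of the replicate under
#' comparison.
#'
#' @param sim_induced,sim_uninduced Numeric vectors of simulated
#'   fluorescence (counts plus basal) under stress and without stress.
#' @param wt_reference_induced Numeric vector: the wild-type induced
#'   replicate used for maximum alignment.
#' @param experimental_uninduced_control Numeric vector: the uninduced
#'   control of the experimental replicate being compared.
#' @param max_quantile Quantile used as the "maximum" (default 1, the
#'   strict sample maximum; a value such as 0.999 gives an
#'   outlier-robust variant).
#' @param reference_id Optional identifier of the reference replicate,
#'   carried in the result for bookkeeping/exclusion.
#' @return A list of class `"hog_calibration"` with elements `a`, `b`,
#'   `max_quantile`, `reference_id`.
#' @export
fit_calibration <- function(sim_induced, sim_uninduced,
                            wt_reference_induced,
                            experimental_uninduced_control,
                            max_quantile = 1, reference_id = NULL) {
  for (v in list(sim_induced, sim_uninduced, wt_reference_induced,
                 experimental_uninduced_control)) {
    if (length(v) == 0) stop("fit_calibration(): empty input sample")
  }
  qmax <- function(x) {
    if (max_quantile >= 1) max(x) else
      stats::quantile(x, max_quantile, names = FALSE)
  }
  x1 <- qmax(sim_induced)
  x2 <- mean(sim_uninduced)
  y1 <- qmax(wt_reference_induced)
  y2 <- mean(experimental_uninduced_control)
  if (x1 == x2) {
    stop("fit_calibration(): degenerate constraints ",
         "(max of induced simulation equals mean of uninduced simulation)")
  }
  a <- (y1 - y2) / (x1 - x2)
  b <- y2 - a * x2
  if (a <= 0) {
    stop("fit_calibration(): fitted slope is not positive (a = ",
         signif(a, 4), "); constraints are inconsistent")
  }
  structure(list(a = a, b = b, max_quantile = max_quantile,
                 reference_id = reference_id),
            class = "hog_calibration")
}

#' Apply a fitted calibration and extend support to the experimental range
#'
#' Maps simulated values through the fitted affine transform and appends
#' the experimental replicate's minimum and maximum intensity as support
#' anchors (a linear extension of the empirical CDF), so that the
#' calibrated sample's support covers the experimental replicate's range
#' and divergence estimates do not saturate at the tails.
#'
#' @param sim_values Numeric vector of simulated fluorescence values.
#' @param calib A `"hog_calibration"` from [fit_calibration()].
#' @param experimental_replicate Numeric vector: the experimental
#'   replicate whose range anchors the extension.
#' @return Numeric vector of length `length(sim_values) + 2`.
#' @export
calibrate_simulation <- function(sim_values, calib, experimental_replicate) {
  stopifnot(inherits(calib, "hog_calibration"))
  if (length(sim_values) == 0 || length(experimental_replicate) == 0) {
    stop("calibrate_simulation(): empty input")
  }
  y <- calib$a * sim_values + calib$b
  c(y, min(experimental_replicate), max(experimental_replicate))
}
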