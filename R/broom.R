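#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutant model fit
#'
#' One row per (parameter group, fraction) with the mean divergence and
#' its standard error across replicates.
#'
#' @param x A `"hog_fit"` object from [best_fit_and_classify()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hog_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a mutant model fit
#'
#' @param x A `"hog_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with the best group/fraction, the best mean
#'   divergence, and the classification p-values and flags.
#' @export
glance.hog_fit <- function(x, ...) {
  tibble::tibble(
    strain = x$strain,
    best_group = x$best_group,
    best_fraction = x$best_fraction,
    best_mean_kl = x$best_mean_kl,
    explained = x$explained,
    p_explained = x$p_explained,
    parameter_identifiable = x$parameter_identifiable,
    p_attribution = x$p_attribution
  )
}

#' @export
print.hog_fit <- function(x, ...) {
  cat("HOG model fit for strain", x$strain, "\n")
  cat(sprintf("  best perturbation : %s scale = %.2f (mean KL %.4f)\n",
              x$best_group, x$best_fraction, x$best_mean_kl))
  cat(sprintf("  explained by model: %s (p = %.3g, one-sided vs WT fit)\n",
              x$explained, x$p_explained))
  if (!is.na(x$parameter_identifiable)) {
    cat(sprintf("  group identifiable: %s (p = %.3g, two-sided)\n",
                x$parameter_identifiable, x$p_attribution))
  }
  invisible(x)
}

#' Tidy a parameter sweep
#'
#' @param x A `"hog_sweep"` tibble.
#' @param ... Unused.
#' @return Per-fraction summary tibble (mean, SE, n).
#' @export
tidy.hog_sweep <- function(x, ...) {
  attr(x, "summary")
}
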