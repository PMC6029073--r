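#' Read a run configuration from YAML
#'
#' A configuration file groups the tunable settings of a full analysis
#' run: a `model` section with [hog_params()] overrides, a `calibration`
#' section (`basal_mu`, `basal_sigma`, `max_quantile`), a `testing`
#' section (`m_tests`, `alpha`, `leave_one_out`) and a `grid` section
#' (`from`, `to`, `by` for the sweep fractions). Missing sections fall
#' back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (a `"hog_params"` object),
#'   `calibration`, `testing`, and `fractions`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config(): no such file: ", path)
  cfg <- yaml::read_yaml(path)
  params <- do.call(hog_params, as.list(cfg$model %||% list()))
  calib <- utils::modifyList(
    list(basal_mu = 2.5, basal_sigma = 0.6, max_quantile = 1),
    as.list(cfg$calibration %||% list()))
  testing <- utils::modifyList(
    list(m_tests = 17L, alpha = 0.05, leave_one_out = TRUE),
    as.list(cfg$testing %||% list()))
  g <- utils::modifyList(list(from = 0, to = 1, by = 0.05),
                         as.list(cfg$grid %||% list()))
  list(params = params, calibration = calib, testing = testing,
       fractions = seq(g$from, g$to, by = g$by))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
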