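#' Parameters of the stochastic HOG transcriptional activation model
#'
#' Builds the parameter set for the two-stage model of stress-driven
#' reporter expression: (i) Hog1 phospho-activation with a basal rate plus a
#' stress-proportional term, balanced by dephosphorylation; (ii) activation
#' of a single reporter gene by sequential assembly of transcription factor,
#' phosphorylated Hog1, chromatin remodeler and polymerase, transcription
#' while the full complex is assembled, disassembly to the gene-TF state
#' when the gene-bound Hog1 is dephosphorylated, first-order mRNA decay,
#' and a stable reporter protein that accumulates until `t_end`.
#'
#' The default rate constants and copy numbers are this package's own
#' calibration, chosen so that the unperturbed model produces a unimodal
#' responding population at stress 18 while partial reduction of the
#' downstream assembly rates produces a responding/non-responding bimodal
#' population; see the package vignette for the reasoning. All values can
#' be overridden.
#'
#' @param ... Named overrides of any default, e.g. `stress = 0`,
#'   `activity_scale = 0.5`.
#' @return A named list of class `"hog_params"`.
#' @details
#' `activity_scale` multiplies `c_active` (the stress-dependent Hog1
#' activation coefficient) and `remodeling_scale` multiplies `c_remon` (the
#' remodeler on-rate); both default to 1 and represent the fractional
#' parameter values explored when fitting mutants. `stress` is the
#' dimensionless stress level applied as a step at t = 0 (default 18, the
#' level matching a 0.4 M NaCl step); `t_end` is the simulated horizon in
#' seconds (default 3600, i.e. 60 min of induction).
#' @examples
#' p <- hog_params(stress = 0)
#' p$stress
#' @export
hog_params <- function(...) {
  p <- list(
    hog1_total = 100,
    tf_total = 50,
    remodeler_total = 30,
    polymerase_total = 30,
    gene_copies = 1L,
    k_basal = 1e-06,
    c_active = 1.2e-05,
    stress = 18,
    k_dephos = 4e-03,
    c_tfon = 2.4e-05,
    c_hogon = 1.6e-03,
    c_remon = 1.3e-03,
    c_polon = 2.2e-03,
    k_off_tf = 1e-05,
    k_off_hog = 1e-04,
    k_off_rem = 1e-04,
    k_off_pol = 1e-03,
    k_tx = 0.05,
    k_deg_mrna = 1e-03,
    k_tl = 0.025,
    t_end = 3600,
    activity_scale = 1,
    remodeling_scale = 1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("hog_params(): unknown or unnamed parameter(s): ",
           paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_hog_params(p)
  structure(p, class = "hog_params")
}

validate_hog_params <- function(p) {
  counts <- c("hog1_total", "tf_total", "remodeler_total",
              "polymerase_total", "gene_copies")
  rates <- c("k_basal", "c_active", "stress", "k_dephos", "c_tfon",
             "c_hogon", "c_remon", "c_polon", "k_off_tf", "k_off_hog",
             "k_off_rem", "k_off_pol", "k_tx", "k_deg_mrna", "k_tl")
  for (nm in c(counts, rates)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("hog_params(): `", nm, "` must be a single non-negative number")
    }
  }
  for (nm in c("activity_scale", "remodeling_scale")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop("hog_params(): `", nm, "` must lie in [0, 1]")
    }
  }
  if (p$t_end <= 0) stop("hog_params(): `t_end` must be positive")
  if (p$gene_copies < 1) stop("hog_params(): `gene_copies` must be >= 1")
  if (p$gene_copies > 5) {
    stop("hog_params(): at most 5 gene copies are supported")
  }
  invisible(p)
}

#' Simulate a population of cells with the exact SSA
#'
#' Runs `n_cells` independent exact (direct-method Gillespie) trajectories
#' of the HOG activation network from t = 0 to `params$t_end` and returns
#' the per-cell reporter protein and mRNA counts at the end point. Each
#' cell uses an independent random substream derived from `(seed, cell)`,
#' so the result is reproducible and independent of `n_cells` ordering.
#'
#' @param params A [hog_params()] object.
#' @param n_cells Number of cells (trajectories), default 50000.
#' @param seed Integer master seed.
#' @return A tibble of class `"hog_sim"` with columns `cell`, `mrna`,
#'   `protein`, and attributes `params` and `seed`.
#' @export
simulate_population <- function(params, n_cells = 50000, seed = 1L) {
  stopifnot(inherits(params, "hog_params"))
  validate_hog_params(params)
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    stop("simulate_population(): `n_cells` must be a positive count")
  }
  n_cells <- as.integer(n_cells)
  res <- ssa_population_cpp(unclass(params), n_cells, as.numeric(seed))
  out <- tibble::tibble(
    cell = seq_len(n_cells),
    mrna = res$mrna,
    protein = res$protein
  )
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("hog_sim", class(out))
  out
}

#' Event-level trajectory of a single simulated cell
#'
#' Returns the full event record (every reaction firing) of one cell's
#' exact-SSA trajectory, for inspection of conservation laws and
#' monotonicity. Only the single-reporter-locus configuration
#' (`gene_copies = 1`) is supported at event-level resolution.
#'
#' @inheritParams simulate_population
#' @param cell Index of the cell substream to simulate (default 0).
#' @return A tibble with one row per event: `t`, free `hog1` and `hog1p`,
#'   free `tf_free`, `rem_free`, `pol_free`, the gene state (0 bare, 1 TF
#'   bound, 2 +Hog1P, 3 +remodeler, 4 fully assembled/transcribing),
#'   `mrna` and `protein`.
#' @export
simulate_trajectory <- function(params, cell = 0L, seed = 1L) {
  stopifnot(inherits(params, "hog_params"))
  validate_hog_params(params)
  if (params$gene_copies != 1L) {
    stop("simulate_trajectory(): event-level records require gene_copies = 1")
  }
  m <- ssa_trajectory_cpp(unclass(params), as.integer(cell), as.numeric(seed))
  tibble::as_tibble(as.data.frame(m))
}

#' Mean-field (mass-action ODE) solution of the HOG activation model
#'
#' Numerically integrates the deterministic rate equations matching the
#' stochastic network: expected free Hog1/Hog1-P, occupancy probabilities
#' of the five gene states, and expected mRNA and protein. Serves as an
#' independent oracle for the stochastic simulator in the regime of large
#' copy numbers, where species correlations become negligible.
#'
#' @param params A [hog_params()] object.
#' @param times Numeric vector of output times (default 100 points spanning
#'   `[0, t_end]`).
#' @return A tibble with columns `time`, `hog1`, `hog1p`, `g0`..`g4`
#'   (expected gene-state occupancies, summing to `gene_copies`),
#'   `active_gene` (= `g4`), `mrna`, `protein`.
#' @export
mean_field_solution <- function(params, times = NULL) {
  stopifnot(inherits(params, "hog_params"))
  validate_hog_params(params)
  p <- params
  if (is.null(times)) times <- seq(0, p$t_end, length.out = 101)
  k_act <- p$k_basal + p$activity_scale * p$c_active * p$stress
  c_rem <- p$remodeling_scale * p$c_remon
  y0 <- c(H = p$hog1_total, Hp = 0,
          g0 = p$gene_copies, g1 = 0, g2 = 0, g3 = 0, g4 = 0,
          M = 0, P = 0)
  deriv <- function(t, y, parms) {
    H <- y[1]; Hp <- y[2]
    g0 <- y[3]; g1 <- y[4]; g2 <- y[5]; g3 <- y[6]; g4 <- y[7]
    M <- y[8]
    tf_free <- p$tf_total - (g1 + g2 + g3 + g4)
    rem_free <- p$remodeler_total - (g3 + g4)
    pol_free <- p$polymerase_total - g4
    bound_hp <- g2 + g3 + g4
    act <- k_act * H
    dep <- p$k_dephos * Hp
    f1 <- p$c_tfon * g0 * tf_free
    b1 <- p$k_off_tf * g1
    f2 <- p$c_hogon * g1 * Hp
    b2 <- p$k_off_hog * g2
    f3 <- c_rem * g2 * rem_free
    b3 <- p$k_off_rem * g3
    f4 <- p$c_polon * g3 * pol_free
    b4 <- p$k_off_pol * g4
    r8 <- p$k_dephos * bound_hp
    list(c(
      H = -act + dep + r8,
      Hp = act - dep - f2 + b2,
      g0 = -f1 + b1,
      g1 = f1 - b1 - f2 + b2 + r8,
      g2 = f2 - b2 - f3 + b3 - p$k_dephos * g2,
      g3 = f3 - b3 - f4 + b4 - p$k_dephos * g3,
      g4 = f4 - b4 - p$k_dephos * g4,
      M = p$k_tx * g4 - p$k_deg_mrna * M,
      P = p$k_tl * M
    ))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda")
  if (attr(sol, "istate")[1L] < 0) {
    stop("mean_field_solution(): ODE solver failed to converge")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out$active_gene <- out$g4
  out$hog1 <- out$H
  out$hog1p <- out$Hp
  out$H <- NULL
  out$Hp <- NULL
  dplyr::select(out, "time", "hog1", "hog1p", dplyr::starts_with("g"),
                "active_gene", "mrna" = "M", "protein" = "P")
}
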