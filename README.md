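# hogflow

Quantitative analysis of single-cell reporter distributions for the
budding-yeast high-osmolarity glycerol (HOG) MAPK pathway — for
researchers who measure pathway output by flow cytometry (a
Hog1-responsive promoter such as pSTL1 driving GFP, ~50,000 cells per
replicate, induced with 0.4 M NaCl for 60 min) and want to ask two
questions quantitatively:

1. **Does a mutation change the reporter distribution?** Distributions
   are compared with the Kullback–Leibler divergence
   $D_{KL}(P\|Q)=\int p(x)\log\frac{p(x)}{q(x)}\,dx$ (nats), estimated
   nonparametrically from the two samples via piecewise-linear empirical
   CDFs. Each mutant replicate is scored against the pooled same-day
   wild-type reference; a one-sided Wilcoxon rank-sum test against the
   wild-type replicates' own divergences, Bonferroni-corrected across
   strains, flags significant mutants.
2. **Can a stochastic model explain the change?** A two-stage model of
   HOG transcriptional activation (stress-dependent Hog1
   phosphorylation; sequential assembly of TF, Hog1-P, chromatin
   remodeler and polymerase on the reporter gene; transcription until
   the gene-bound Hog1-P is dephosphorylated; mRNA decay; stable
   reporter protein) is simulated exactly (next-reaction method), mapped
   onto the fluorescence scale, and fitted to each mutant by sweeping
   one parameter-group scale over fractions of its reference value. The
   divergence-minimising fraction, an "explained by the model" flag, and
   an activity-vs-remodeling attribution test are reported.

A synthetic-data module generates day-structured, replicate-jittered
flow experiments (graded and bimodal mutants, plus ground-truth mutants
drawn from the model itself), so the whole pipeline is testable with
known truth.

## Worked example

```r
library(hogflow)
library(dplyr)

# a synthetic two-day experiment: wild type plus two mutant phenotypes
spec <- synthetic_spec(n_days = 2, reps_per_day = 4, n_events = 20000, seed = 1)
wt <- gen_wt_experiment(spec)
graded <- gen_effect_mutant(
  synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 20000, seed = 2),
  mutant_effect("graded", 0.25), strain = "graded_mutant")
bimodal <- gen_effect_mutant(
  synthetic_spec(n_days = 2, reps_per_day = 3, n_events = 20000, seed = 3),
  mutant_effect("bimodal", 0.5), strain = "bimodal_mutant")

res <- divergence_test(bind_rows(wt, graded, bimodal), m_tests = 17)
res$tests
#> # A tibble: 2 × 8
#>   strain        n_mutant  n_wt median_mutant_kl median_wt_kl   p_raw p_corrected
#>   <chr>            <int> <int>            <dbl>        <dbl>   <dbl>       <dbl>
#> 1 bimodal_muta…        6     8            4.26        0.0259 3.33e-4     0.00566
#> 2 graded_mutant        6     8            0.450       0.0259 3.33e-4     0.00566
```

Each row compares one strain's six replicate divergences against the
eight wild-type self-divergences. The wild-type baseline (median 0.026
nats) is the irreducible replicate noise; the graded mutant sits ~17×
above it and the bimodal mutant ~160× above it, and both survive the
17-test Bonferroni correction (`p_corrected < 0.05`).

Fitting a ground-truth mutant generated from the model with its
activity parameter halved:

```r
p <- hog_params()
mut <- bind_rows(lapply(1:4, function(r)
  gen_model_truth_mutant(p, "activity", 0.5, n_cells = 10000, seed = 10 + r,
                         replicate = paste0("r", r), day = "d1")))
# ... uninduced controls + wild-type reference as in ?sweep_parameter ...
sweeps <- lapply(c("activity", "remodeling"), function(g)
  sweep_parameter(p, g, fractions = seq(0.2, 1, by = 0.05),
                  mutant_replicates = mut, uninduced_controls = ctrl,
                  wt_reference_induced = ref, n_cells = 10000, seed = 5,
                  max_quantile = 0.999))
fit <- best_fit_and_classify(sweeps, wt_kls, strain = "act_half")
fit
#> HOG model fit for strain act_half
#>   best perturbation : activity scale = 0.50 (mean KL -0.0002)
#>   explained by model: TRUE (p = 0.657, one-sided vs WT fit)
#>   group identifiable: FALSE (p = 0.686, two-sided)
```

The sweep recovers the generating fraction (0.50) exactly; the best-fit
divergences are indistinguishable from the wild-type model fit
(`explained`), and — as is typical for this model — the two parameter
groups fit almost equally well, so the affected group is not formally
identifiable from the distribution alone. `tidy(fit)`, `glance(fit)`
and `autoplot(sweeps[[1]])` give the long table, the one-row summary,
and the divergence-vs-fraction curve with ±3 SE bands.

`summarize_modes()`, `two_group_signature()`, `recovery_battery()` and
`null_fwer_battery()` expose the package's validation experiments; the
vignette (`vignettes/hog-reporter-analysis.Rmd`) explains the model,
the estimator, the calibration choices and their limitations.

A thin command-line wrapper with `synth`, `simulate`, `divergence` and
`fit` subcommands is installed at `inst/scripts/hogflow-cli.R`.

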