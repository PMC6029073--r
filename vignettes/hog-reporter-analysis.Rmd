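---
title: "Quantifying mutant effects on HOG reporter distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutant effects on HOG reporter distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

The high-osmolarity glycerol (HOG) MAPK pathway of budding yeast converts
an osmotic-stress step into a transcriptional response through the MAP
kinase Hog1. A standard way to measure how a mutation changes pathway
output is a single-cell reporter assay: a Hog1-responsive promoter (such
as the STL1 promoter) drives GFP, cells are stimulated with 0.4 M NaCl
for 60 minutes, and tens of thousands of per-cell fluorescence values are
recorded by flow cytometry per replicate. Because reporter output is a
*distribution* over cells — not a single number — mutations can act in
qualitatively different ways: shifting the whole population (graded
effects), or splitting it into responding and non-responding
subpopulations (stochastic, bimodal effects).

`hogflow` implements the full quantitative pipeline around such data:

1. a nonparametric estimator of the Kullback–Leibler (KL) divergence
   between two samples, used as the distance between reporter
   distributions;
2. a day-structured testing procedure that scores each mutant replicate
   against a pooled wild-type reference and applies a rank-sum test with
   Bonferroni correction;
3. an exact stochastic simulator of a compact two-stage model of HOG
   transcriptional activation;
4. a calibration layer mapping simulated molecule counts onto the
   fluorescence scale of a given experiment; and
5. a parameter-perturbation fitting procedure that finds the fraction of
   an "activity" or "remodeling" parameter that best reproduces a
   mutant's distribution and classifies whether the model explains the
   mutant at all.

A synthetic-data module generates flow-cytometry-like experiments with
known ground truth, which is how the pipeline is validated end to end.

# Divergence estimation

For samples $x_1,\dots,x_n \sim P$ and $y_1,\dots,y_m \sim Q$ the package
estimates
$$D_{KL}(P\|Q) = \int p(x)\,\log\frac{p(x)}{q(x)}\,dx \quad\text{(nats)}$$
from the two empirical CDFs, interpolated piecewise-linearly. Each
point of the $P$ sample contributes the log ratio of the local CDF
slopes, where a slope is measured over a window of $k = 4$ sample
spacings. The additive bias of spacing statistics is removed exactly:
a window of $w$ plain spacings has expected log length
$\psi(w) - \log(N\rho)$, while the $Q$ window that brackets an
independent $P$ point contains one size-biased spacing, giving
$\psi(w+1)$; the difference of these digamma constants is subtracted per
point. Two practical details matter:

* **Coincident points.** When a $P$ point coincides exactly with a $Q$
  point (as happens when a sample is compared with a pool containing
  it), the $Q$ window ending at that point is used and no size bias is
  applied; a sample compared against itself then yields exactly zero.
* **Ties.** Discretised fluorescence values are made strictly increasing
  by a deterministic rank-proportional offset of $10^{-9}$ times the
  data range, so the estimator is a pure function of its inputs.

Small negative estimates are legitimate sampling noise and are reported
unclamped; the downstream tests are rank-based and unaffected. A
one-nearest-neighbour estimator (`method = "knn"`) is included as an
independent cross-check; the two agree within 10% on distributions with
closed-form divergences at assay sample sizes. The window width 4 is a
bias–variance compromise fixed once for the package: at 50,000 events it
gives a self-divergence spread of roughly 0.002–0.003 nats, well below
the replicate-to-replicate divergences of real assays, while keeping the
relative error on closed-form test cases under 10%.

All divergences are in nats. Comparisons between strains use induced
distributions; uninduced samples serve calibration.

# Pooling and hypothesis testing

Wild-type replicates measured on the same experiment day are
concatenated into that day's *WT pool*, the reference distribution $Q$.
Each replicate (wild-type or mutant) is scored by its divergence from
its own day's pool, so day-level batch effects cancel. A mutant is
called significant when a one-sided Wilcoxon rank-sum test finds its
divergences greater than the wild-type replicates' own divergences, with
Bonferroni correction for the number of strains tested (default family
size 17). Small groups are tested by exhaustive enumeration of rank
assignments, which remains exact under ties.

One design choice deserves emphasis. If a wild-type replicate is scored
against a pool that *contains its own events*, its divergence is damped
by roughly $(1 - 1/n_\text{reps})^2$ relative to a strain outside the
pool, because a quarter-ish of the reference is the replicate itself.
Under a null in which every strain is wild type in law, this asymmetry
alone makes mutant records stochastically larger than wild-type records
and inflates the family-wise error far above the nominal level (we
measured family-wise error around 0.5 at $\alpha = 0.05$, $m = 17$).
`hogflow` therefore excludes the replicate under comparison from its
reference pool by default (`leave_one_out = TRUE`), which restores
exchangeability and calibrates the null; the inclusive variant remains
available for comparison with analyses that pooled inclusively.

# The stochastic model

The model has two stages. *Hog1 activation*: free Hog1 is phosphorylated
at rate $k_\text{basal} + s_\text{act}\,c_\text{active}\cdot\text{stress}$
per molecule and dephosphorylated at $k_\text{dephos}$; stress is a step
applied at $t = 0$ and held constant (default 18, matching a 0.4 M NaCl
step). *Gene activation*: a single reporter locus assembles its
activation complex sequentially — transcription factor, Hog1-P,
chromatin remodeler, polymerase — with on-rates $c_\text{tfon}$,
$c_\text{hogon}$, $s_\text{rem}\,c_\text{remon}$, $c_\text{polon}$ and
matching off-rates for the outermost component. The fully assembled gene
transcribes at $k_\text{tx}$; dephosphorylation of the gene-bound Hog1-P
(rate $k_\text{dephos}$) disassembles the complex back to the gene–TF
state, releasing remodeler and polymerase and returning unphosphorylated
Hog1. mRNA decays at $k_\text{deg}$; the reporter protein is translated
at $k_\text{tl}$ per mRNA and never degrades (GFP is stable on this
timescale), accumulating until $t = 3600$ s.

Populations are simulated with the exact direct-method Gillespie
algorithm, one independent trajectory per cell. Each cell's random
substream is derived from `(seed, cell index)` with a self-contained
64-bit generator, so results are bit-reproducible across platforms and a
population can be extended without reshuffling earlier cells. Because
the reporter protein feeds back on no reaction propensity, population
runs draw the end-point protein count exactly as
$\text{Poisson}(k_\text{tl}\int_0^T M\,dt)$ conditional on the simulated
mRNA path, which more than halves the event count without changing the
end-point law; event-resolved trajectories (used to verify conservation
laws and monotone protein accumulation) keep explicit translation
events.

A mean-field companion (`mean_field_solution()`) integrates the
mass-action rate equations for the same network with `deSolve`. In the
large-copy-number regime, where species correlations vanish, the
simulator's population means must match it — one of the package's
acceptance checks (2,000 cells at 10-fold copy numbers, three standard
errors).

## Rate constants are a calibration, not measurements

The published descriptions of this class of model fix the network
topology but not a usable set of stochastic rate constants, so the
defaults in `hog_params()` are this package's own calibration, chosen
once to satisfy the qualitative behaviour the analysis requires: a
unimodal induced wild-type population with a few percent of
non-responders; a responding/non-responding bimodal population when the
downstream assembly rates are substantially reduced; activation within
the one-hour window; and mean reporter counts of order $10^3$ molecules.
Copy numbers (100 Hog1, 50 TF, 30 remodeler, 30 polymerase) are in the
range of low-abundance yeast signaling proteins. All rates are plain
function arguments and a YAML/TSV round trip away from a config file.

## The two parameter groups and a structural degeneracy

Perturbation simulations fall into two phenomenological groups. Reducing
the *activity* coefficient $c_\text{active}$ lowers the steady-state
Hog1-P level; because the gene must re-bind Hog1-P after every
disassembly, this both delays activation (fewer cells respond) and slows
the re-binding cycle (the responding mode sits lower). Reducing a
*downstream on-rate* ($c_\text{tfon}$, $c_\text{remon}$,
$c_\text{polon}$) delays first assembly — moving cells out of the
responding component — but leaves the responding-mode location nearly
unchanged, because those steps are fast relative to the transcribing
phase once the complex cycles. `two_group_signature()` reproduces this
contrast quantitatively (mode location summarised as the density peak of
the responding component at 10,000 cells per population).

One rate cannot be placed on the downstream side of this contrast:
$c_\text{hogon}$ enters every propensity only through the product
$c_\text{hogon}\cdot[\text{Hog1-P}]$, and $[\text{Hog1-P}]$ is
proportional to the activity coefficient in the operating regime. The
two parameters are therefore *exactly* kinetically degenerate in this
network — no choice of rate constants can make reducing $c_\text{hogon}$
location-stable while reducing $c_\text{active}$ moves the location. The
signature battery consequently tests the three genuinely downstream
on-rates, and the fitting module's "activity" group should be read as
"Hog1-P supply and capture" rather than upstream kinase activity alone.
This degeneracy is a property of the model, and it is consistent with
the broader finding that distributional data often cannot identify
*which* parameter a mutation perturbs.

# Calibration to the fluorescence scale

Simulated counts are mapped to fluorescence in three steps. First, a
lognormal basal-expression constant with log-scale parameters
$\mu = 2.5$, $\sigma = 0.6$ is added per cell, making all values
positive; these are interpreted as the mean and standard deviation of
the logarithm (the standard lognormal parameterisation). Second, an
affine transform $y = ax + b$ is fitted from two constraints: the
maximum of the induced simulation maps to the maximum of a designated
wild-type reference replicate (excluded from all divergence
comparisons), and the mean of the unstressed simulation maps to the mean
of the replicate's own unstressed control. The strict sample maximum is
the default anchor; a robust quantile (e.g. 0.999) is available because
a strict maximum is outlier-sensitive. Third, the experimental
replicate's minimum and maximum are appended to the calibrated sample as
support anchors (a linear extension), so the empirical-CDF divergence
cannot saturate on tail support mismatch.

When fitting perturbed models, the transform is fitted once per
replicate *from the unperturbed model* and then frozen across the whole
perturbation grid. Refitting the maximum alignment on every perturbed
population would rescale each perturbation back onto the wild-type
maximum — cancelling the very signal being fitted — and we observed
exactly this flattening before freezing the transform.

# Fitting mutants by parameter perturbation

`sweep_parameter()` scales one parameter group over a grid of fractions
(default $0, 0.05, \dots, 1$; 20 perturbations plus the unperturbed
baseline), simulates one population per fraction, and scores every
mutant replicate's divergence from the calibrated prediction. All
fractions reuse the unperturbed population's random substreams (common
random numbers), so sampling noise is shared along the grid and cancels
when fractions are compared. The best fit is the grid argmin of the mean
divergence, with ties broken toward the fraction closest to 1 (the most
conservative perturbation). A mutant is *explained* when a one-sided
rank-sum test cannot distinguish its best-fit divergences from the
wild-type replicates' divergences to the unperturbed model; whether the
*group* is identifiable is asked two-sidedly between the two groups'
best divergence sets (`attribute_parameter()`).

`recovery_battery()` closes the loop: mutants generated from the model
itself at known fractions (0.25, 0.50, 0.75 of either group; four
replicates of 25,000 events) are pushed through the full sweep (grid
0.15–0.85 at step 0.05, so every truth is interior; 10,000 cells per
point; maximum alignment by the 0.999 quantile, which unlike the strict
maximum does not depend on sample size) and the battery reports how
often the true fraction is recovered within one grid step and how often
the best group matches the truth at fraction 0.25. Two caveats are
structural rather than implementational: near fraction 1 the divergence
landscape is almost flat, so recovery weakens; and remodeling-type
perturbations at intermediate fractions produce deliberately small
distributional changes (that is what "location-stable" means), so their
divergence valley is shallow and the recovered fraction scatters more
than for activity-type truths.

# The synthetic-data generator

`gen_wt_experiment()` emulates the statistical structure the testing
procedure relies on, not the biophysics of a cytometer. Per-cell
fluorescence is lognormal — reporter intensities are positive and
right-skewed — with uninduced and induced log-means 4.0 and 6.0 (a
roughly sevenfold induction) and log-sd 0.5. Three nested noise levels
reproduce the replicate structure of a multi-day experiment: a day-level
shift (sd 0.05) common to all replicates of a day, which day-matched
pooling absorbs; a replicate-level shift (sd 0.15) calibrated so the
median replicate-to-pool divergence is of order 0.01–0.03 nats, the
scale of replicate noise in such assays; and per-cell sampling. Graded
mutants move the induced log-mean a fraction of the induction gap toward
the uninduced state; bimodal mutants mix an exactly-uninduced-law
component with an attenuated responder component, mimicking mutants
where part of the population fails to respond. Bimodality of generated
mutants is verified by two-component Gaussian mixture modelling on the
log scale (`mclust`), not by a dip statistic.

What the generator does *not* emulate: detector saturation, doublets,
autofluorescence spectra, compensation, or gating artifacts — inputs are
assumed pre-gated. Passing tests on synthetic data therefore validates
the statistical machinery (estimator calibration, pooling, error
control, recovery), not robustness to instrument pathology.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a constant reference sample
with differing support returns `+Inf` flagged `saturated`; sweeps with
non-finite divergence columns are excluded from the argmin; leave-one-out
pooling falls back to the full pool (with a warning) when exclusion
would leave fewer than 100 events; event-count floors reject samples
below 100 events. Seeds derived internally always stay below $2^{31}$.

The validation experiments run at deliberate desk scale, stated here as
the package's own choices: estimator oracles at 50,000 events;
simulator-versus-mean-field at 2,000 cells and tenfold copy numbers; the
two-group signature at 10,000 cells over five seeds; the recovery
battery over 20 seeds with 10,000-cell grid populations and
25,000-event replicates; the null family-wise-error battery over 200
simulated 17-strain experiments of 2,000 events each (null calibration
does not depend on the event count). The real assays these emulate
record 50,000 events per sample, and the corresponding full-scale sweeps
(50,000 runs per perturbation) change only the Monte-Carlo error, not
the procedure.

# Limitations

* The model omits the Sln1 branch, osmotic-volume feedback, and nuclear
  translocation dynamics; stress is constant, so Hog1-P has no
  adaptation pulse. Mutants whose phenotype depends on adaptation
  kinetics are outside its scope.
* The rate constants are a documented calibration; absolute simulated
  molecule counts should not be compared with measured protein numbers.
* KL estimates at very small samples (hundreds of events) carry biases
  of the order of the quantities being compared; the pipeline's floors
  exist for that reason.
* Attribution between activity-like and remodeling-like perturbations is
  often impossible from distributional data — the package reports this
  honestly via `parameter_identifiable` rather than forcing a choice.
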