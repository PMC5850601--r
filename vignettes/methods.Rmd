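---
title: "Estimating selection from Pool-Seq time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection from Pool-Seq time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seltraj)
```

This vignette documents the models behind `seltraj`, the choices made where
the methodology left room, and what the package's simulation-based checks do
and do not establish.

## Selection model

A biallelic locus with alleles $A$ and $a$ evolves in a panmictic population
of constant effective size $N_e$ over discrete, non-overlapping generations.
Relative fitnesses are $w_A = 1+s$, $w_a = 1$ in haploids and
$w_{AA} = 1+s$, $w_{Aa} = 1+hs$, $w_{aa} = 1$ in diploids, with genotypes at
Hardy–Weinberg proportions each generation (no inbreeding parameter). The
deterministic one-generation update is the standard fitness-weighted mean
(`wf_step()`); iterating it gives the discrete trajectory
(`wf_traj_det()`). The constraint $s > -1$ (positive fitness) is enforced at
construction of `sel_params()`, not per step. Dominance values outside
$[0, 1]$ (over-/underdominance) are accepted with a warning: the machinery
works but none of the validation experiments cover that regime.

Under weak selection, overlapping generations and codominance, the
trajectory has the logistic closed form implemented in `traj_continuous()`,
equivalent to a logit-linear trajectory with slope $s$ (haploid) or $s/2$
(diploid). For general $h$ no closed form is available and the discrete
recursion is used directly.

## Wright–Fisher simulator

Each generation applies the deterministic update and then resamples
$n_g = N_e$ (haploid) or $2N_e$ (diploid) allele copies binomially; loci are
unlinked and replicate populations evolve independently from a shared
starting frequency. Pool-Seq noise draws the per-sample coverage from a
Poisson distribution and then the focal-allele read count binomially at the
population frequency; a sample whose drawn coverage is 0 is recorded as
missing, not an error. An optional intermediate binomial stage with a finite
`pool_size` models the number of pooled individuals; the default draws
reads directly from the population frequency, matching the two-step
Poisson–binomial recipe. Linked loci, recombination, mutation, clonal
interference and time-varying $N_e$ are out of scope.

The simulator is vectorised across loci, replicates and bootstrap draws (one
binomial call per generation for the whole batch), which is what makes the
per-locus parametric bootstrap affordable at genome scale in plain R. A
consequence is that determinism is defined by the tuple (seed, number of
loci, design): changing the locus count reshuffles the shared RNG stream.
Per-locus derived streams were considered and rejected as they would force a
per-locus simulation loop, an order of magnitude slower.

## From replicates to estimates

**Consensus.** Replicate frequencies are averaged per time point
(unweighted). A replicate is excluded from the first time its *observed*
frequency hits 0 onwards: trajectories that continue past an apparent loss
are conditioned on survival and would bias estimates. The number of
contributing replicates per time point is recorded. Observed fixation
(frequency 1) does not mask — such points simply carry no logit information
and are dropped from the regression. If fewer than two informative points
remain, the locus is flagged `insufficient_data` and no estimate is
produced; downstream summaries (rRMSE maps, power) drop such loci rather
than imputing a value.

**LLS.** Ordinary least squares of logit frequency on generation;
$\hat{s}$ is the slope (doubled for diploids), $\hat{p}_0$ the
inverse-logit intercept. Weighting by coverage (inverse sampling variance)
is available behind `weights = "coverage"` but off by default: coverage has
little effect on accuracy except when very low, and the unweighted fit keeps
the estimator free of a tuning choice.

**Bias correction.** LLS targets the continuous-time model; discrete
generations bias $\hat{s}$ increasingly with selection strength. The
correction computes the deterministic discrete trajectory at
$(\hat{p}_0, \hat{s})$ over the design's sampling times, re-estimates the
coefficient with LLS, and adds back the difference. That additive step is
the first iterate of the fixed-point problem
$\mathrm{LLS}(\mathrm{discrete}(p_0, s^\ast)) = \hat{s}$; the package
iterates to convergence (tolerance $10^{-8}$, at most 25 iterations), which
recovers discrete-truth coefficients to better than $10^{-3}$ where the
single step leaves an error of order $10^{-2}$ at $s = 0.3$. The correction
vanishes as $\hat{s} \to 0$, so it is applied unconditionally rather than
behind a "large $\hat{s}$" threshold — this removes a free parameter. Loci
whose deterministic re-trajectory is monomorphic at the sampled times (e.g.
$\hat{p}_0$ at a boundary) are returned uncorrected and flagged.

**Survival conditioning.** When the starting frequency is low relative to
$N_e$, masking lost replicates conditions the consensus on survival and
inflates it even under neutrality. `condition_on_survival()` simulates
neutral replicates from the observed starting consensus under the same
design, applies the identical masking-and-averaging rule, and subtracts the
per-time mean neutral excess (conditioned consensus minus $p_0$), clipping
to $[0,1]$. This restores the consensus on the frequency scale; on the
logit scale a small negative residual bias remains for near-boundary
frequencies (clipped and near-zero values enter the regression
non-linearly). The exact functional form of this correction is a design
choice of this package; mean-excess subtraction was chosen as the simplest
rule that is exactly zero in the no-drift limit. In `fit_selection()` the
trigger is `condition = "auto"`: applied when the starting consensus times
$n_g$ is below 30, or when a 200-simulation neutral probe shows more than
1% loss by the final sampling time; 1000 neutral simulations per locus by
default. The neutrality-test and power pipelines deliberately do not apply
it, so that observed and null estimates pass through the same estimator.

**NLS.** For non-codominant loci, $(s, h)$ are co-estimated by minimising
the frequency-scale sum of squared deviations between the consensus and the
discrete deterministic trajectory. The starting frequency is fixed at the
first usable consensus value rather than co-estimated — with the typical
7 time points, freeing all three parameters leaves ridges where $h$ and
$p_0$ trade off. The residual scale was likewise a choice left open;
frequency-scale residuals weight the informative mid-trajectory more than
logit-scale residuals would and avoid dropping near-boundary points twice.
The optimiser is bounded L-BFGS-B with $s \in [-0.5, 1.5]$,
$h \in [-1, 2]$, started at the LLS estimate with $h = 0.5$; because the
objective is numerically tiny (squared frequencies), the stopping rule is
tightened (`factr = 1e3`) and parameters scaled — with default settings the
optimiser stops prematurely. One random restart inside the bounds is
attempted on non-convergence, then the caller falls back to LLS with a
flag. Multiple local optima are rare; outliers instead reflect genuinely
uninformative trajectories (high $p_0$).

**Switching.** `method = "auto"` regresses logit frequency on $t$ and
$t^2$; if the two-sided p-value of the quadratic coefficient is below
`p_threshold` (default 0.1), the trajectory bends as non-codominant loci do
and NLS is used, otherwise LLS. The test needs at least four interior
points (the quadratic model is otherwise saturated); with exactly four it
runs on one residual degree of freedom. A numerically exact fit (zero
residual variance) returns p = 1 when the quadratic coefficient is zero —
the exactly-linear case — and p = 0 otherwise.

## Neutrality testing

The bootstrap test simulates `n_sims` (default 1000) neutral datasets per
locus, matched in starting frequency (the observed starting consensus),
replicate count, sampling times and coverage (observed coverages are
reused), estimates $s$ on each with the same LLS pipeline, and reports
$p = (1 + \#\{s^\ast \ge \hat{s}\})/(1 + n)$. The test is one-sided for
positive selection by default (`alternative = "two.sided"` compares
absolute values); the add-one pseudo-count avoids literal zeros and is
immaterial for decisions at $\alpha = 0.01$ with 1000 simulations. Under
the null the p-values are uniform (verified by simulation with a KS check)
and the type-I error at $\alpha = 0.01$ is at nominal level. Chi-squared
(no continuity correction) and CMH (continuity correction on by default,
removable; a single stratum falls back to the plain chi-squared test) cover
the classic two-time-point analyses; `bh_adjust()` wraps Benjamini–Hochberg
and `neighbor_support_filter()` retains only outliers supported by another
outlier within 1 kb.

## Evaluation suite and simulation scales

Accuracy is summarised by the relative root-mean-squared error, RMSE
divided by the mean true $s$ of the loci being summarised, binned on an
equal-width grid over $(p_0, s)$ with percentile-bootstrap confidence
intervals (200 resamples by default). The grid defaults to 10 × 10 at the
$10^5$-locus scale the package's experiments run at, keeping per-bin counts
near $10^3$; coarser grids mix the sharp boundary between well- and
poorly-estimated regions, which shifts the fraction of "accurate" bins
upward relative to a fine grid over many millions of loci. Estimates can be
projected to $[-0.2, 1]$ (`clip_estimates()`) when comparing against
estimators whose priors bound their output.

The packaged experiments use a standard E&R design — 6 replicates,
$N_e = 300$, 60 generations sampled every 10 at 80× coverage — with
$10^3$ loci per power scenario (1000 bootstrap simulations each) and
$10^5$ loci for the accuracy map; these sizes put Monte-Carlo error well
inside the tolerances asserted and complete in minutes on one CPU. The
measurement interval for the single-replicate robustness scenario is the
same every-10-generations grid.

Known limits of what the simulations establish: the generator draws
unlinked loci with constant $s$ and shared $p_0$ across replicates, so the
power and accuracy figures say nothing about linked selection, clonal
interference, variable selective pressure, or replicates founded at
different frequencies. One headline scenario is not reproduced: for a
single replicate at 20× coverage with $p_0 \sim U(0,1)$,
$s \sim U(0, 0.3)$, the fraction of loci the calibrated bootstrap test
flags at $\alpha = 0.01$ is about 39–40%, not 87%. With one trajectory at
$N_e = 300$, a substantial share of loci (starting frequencies near the
boundaries, $s$ below drift scale) cannot be distinguished from neutrality
by any calibrated test — a noise-free variant of the same experiment caps
near 52% — so the package reports the calibrated value rather than tuning
the test towards the larger figure.

## Numerical notes

- Frequencies exactly 0 or 1 never enter a logit; the estimators drop such
  points rather than clamping them, and report how many points were used.
- The batch OLS uses closed-form normal equations (one pass of row sums);
  degenerate fits (fewer than two points, zero time variance) return `NA`
  rather than a pseudo-estimate.
- Biallelic reduction of sync records takes the two highest-count bases
  (ties in base order A, T, C, G), flags loci with more than two bases above
  a noise floor (1% of pooled reads, minimum 2) and polarises towards the
  allele rising between the first and last time point, breaking ties
  towards the non-reference allele. N and deletion counts never count
  towards coverage.
- All user-facing simulation entry points accept a `seed` and restore the
  caller's RNG state afterwards.
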