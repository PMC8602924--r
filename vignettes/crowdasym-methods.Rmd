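---
title: "Methods: simulating and modelling the in-out asymmetry in crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modelling the in-out asymmetry in crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Visual crowding limits peripheral letter recognition: a target that is easy
to identify in isolation becomes unrecognisable when a flanking letter sits
nearby. A classic signature of crowding is the *in-out asymmetry* (IOA): a
single flanker placed peripheral ("outward") to the target crowds far more
than one placed foveal ("inward") to it, even at the same centre-to-centre
distance. crowdasym implements a complete simulation-and-analysis pipeline
for experiments that quantify the IOA as the ratio of outward-flanked to
inward-flanked size thresholds, measured by an adaptive staircase in a
3 (design: blocked / pre-cued / random location) x 4 (location: up / down /
left / right, all at 7.5 degrees eccentricity) x 3 (flanker: none / inward /
outward) factorial.

The package has two jobs:

1. **Forward simulation.** Synthetic observers with known, configurable
   ground truth generate trial-level 9AFC responses; a QUEST staircase
   estimates their thresholds exactly as an experiment would.
2. **Inference.** A multilevel Bayesian lognormal regression recovers cell
   thresholds, crowding factors and IOA ratios with full posterior
   uncertainty, including what the model implies about unseen individuals.

Because the generator's truth is known, the pipeline's end-to-end behaviour
(bias, interval coverage, false-positive control) is testable — the
`recovery_harness` functions automate exactly that.

## The observer model

A response is correct with probability given by the Watson–Pelli Weibull
form, in log10 stimulus units:

$$\Psi(x) = \delta\gamma + (1-\delta)\left[1 - (1-\gamma)\,
  e^{-10^{\beta (x - t) + \epsilon}}\right]$$

with $\gamma = 1/9$ the 9AFC guess rate (commonly quoted as 0.11),
$\delta = 0.05$ the lapse rate, $\beta = 3.5$ the slope, $x$ the letter size
and $t$ the threshold (both log10 degrees). Lapses succeed at chance, hence
the $\delta\gamma$ term and the ceiling $1 - \delta(1-\gamma) \approx
0.956$. The offset $\epsilon$ is solved in closed form so that
$\Psi(t) = 0.5$ exactly — the experiment's threshold criterion. Performance
depends on size and threshold only through $x - t$, so all threshold ratios
are scale-free.

The population generator parameterises truth multiplicatively, mirroring the
quantities the analysis reports: a median unflanked threshold per location
(default 0.6 degrees, a typical letter acuity at 7.5 degrees eccentricity),
an inward crowding factor (default 2), and an IOA ratio (default 2.5, the
middle of the 1.5–4.5 range reported for human cohorts). Observer-level
variation enters as centred normal offsets in log10 units on an intercept
and on each location/flanker/design dummy — the same random-effect structure
the regression model assumes — with defaults of 0.1 (intercept) and 0.05
(each effect). The outward threshold is therefore
`unflanked x cf_inward x ioa`, and the generative IOA is an explicit,
recoverable quantity. These observer-variation defaults are a modelling
choice, not an estimate from any particular dataset: they produce cohort
threshold spreads of roughly a factor of two, which is what crowding
experiments typically show.

What the generator deliberately does **not** emulate: letter-confusion
structure (responses are Bernoulli, not 9-way), attentional mechanics
(design effects exist only as condition-dependent true thresholds),
eye movements, or any stimulus rendering. Passing recovery tests therefore
demonstrate the statistical machinery, not fidelity to every property of
human data.

## The QUEST staircase

`quest_*()` functions maintain a discrete posterior over log10 threshold:

* **Prior**: Gaussian, mean log10(1.1 degrees), SD 3 log10 units. The SD is
  deliberately diffuse — the prior contributes almost nothing after a few
  trials.
* **Grid**: the prior mean ± 3 SDs in steps of 0.005 log10 units (3601
  points). The grid must span the prior: clipping it to the physical
  stimulus range (0.1–3 degrees) would truncate the tails so severely that
  a fresh staircase's estimate would sit near 0.55 degrees instead of the
  initial guess, and its reported SD near 1 instead of 3. The step is 40x
  finer than the 0.2 log10-unit exclusion cutoff, so discretisation never
  matters at the scales analysed.
* **Placement**: each trial shows the posterior mean of log10 threshold
  (exponentiated), clamped to 0.1–3 degrees — mean placement is the
  standard recommendation for this staircase family; the likelihood is
  always evaluated at the clamped size actually shown. Mode placement would
  change individual trial sequences but, by the calibration tests, not the
  pooled estimates.
* **Estimate**: threshold = 10^(posterior mean of log10 t); the reported
  reliability is the posterior SD of log10 t ("log units" are log10
  throughout, the staircase's native convention).
* **Two-run pooling**: each cell is measured by two independent 40-trial
  adaptive runs from the fresh prior; the 80 pooled (size, correct) pairs
  are then re-evaluated in a third pass that also starts from the fresh
  prior — pure Bayesian re-evaluation, no adaptation — so the two runs
  contribute only their data, and the result is invariant to trial order.

Thresholds whose pooled posterior SD exceeds 0.2 log10 units are flagged
(never deleted) by `apply_exclusion()`; the model stage drops flagged rows,
and `cohort_counts()` reports the bookkeeping, with the percentage rounded
to the nearest integer.

## The threshold model

`fit_ioa()` fits, by MCMC,

$$\text{threshold}_{i} \sim \text{LogNormal}(\eta_i, \sigma), \qquad
  \eta_i = \mathbf{x}_i^\top\beta + \mathbf{z}_i^\top b_{j[i]}$$

on the natural-log scale. The fixed effects are a full three-way factorial
in dummy coding: four location intercepts (no global intercept), inward and
outward flanker dummies, pre-cued and random design dummies, and all two-
and three-way interactions — 36 columns of full rank, so every cell mean is
reachable. The random effects $b_j$ are a by-participant intercept plus each
main-effect dummy (8 terms), modelled as independent normals. A full
correlation matrix among the 8 terms would be the other defensible choice;
we model them as independent because the scientific quantities reported here
(fixed-effect ratios, and population proportions driven by the flanker-offset
SDs) are insensitive to those correlations at these cohort sizes, and the
independent parameterisation keeps the Gibbs sampler fast and well mixed.

Priors, stated on the log-threshold scale:

| term | prior | rationale |
|---|---|---|
| location intercepts | Normal(1, 2) | weakly centres unflanked thresholds near e^1 ≈ 2.7 deg with a very wide spread |
| flanker main effects | Normal(1, 0.5) | flankers raise thresholds; deliberately identical for inward and outward, so the asymmetry under study is not assumed |
| design effects, all interactions | Normal(0, 1) | agnostic |
| random-effect SDs | half-Cauchy(0, 10) | weak, positive, heavy-tailed |
| residual SD | half-Cauchy(0, 1) | weak, positive |

The lognormal likelihood is implemented as a normal model on
log(threshold); the Jacobian of that transform is constant in the
parameters, so the posterior is identical, and it lets the sampler's
conjugate block updates handle the linear part. Chains are seeded
individually, so a fit is bit-for-bit reproducible given its seed.
Convergence is summarised by split-chain R-hat and effective sample size per
parameter; any R-hat above 1.01 triggers a warning, never a silent pass.
Presets: `smoke` (2 chains x 500 kept draws after 500 adaptation + 500
warmup) for pipeline checks, `full` (4 x 2000) for reported summaries.

`prior_predictive()` pushes the priors through the likelihood (fixed effects
plus residual; random effects excluded by default, since their
half-Cauchy(0, 10) scales make the unconditional predictive extremely
heavy-tailed) and reports the 75% highest-density interval of the implied
thresholds. Under this natural-log convention the interval is on the order
of [0, 50] degrees with a median near 5 degrees — wide but physically
sensible for a prior check. Note that descriptions of this prior family
sometimes quote tighter predictive summaries; those depend on conventions
(log base, which terms are included) that the function's arguments expose,
and we report what the stated priors actually imply rather than forcing
agreement.

## Posterior quantities

All derived quantities are computed per posterior draw and summarised last:

* **Cell threshold** (average observer): exp of the sum of the cell's
  active fixed effects.
* **Crowding factor**: flanked / unflanked threshold, per design x location
  x flanker side.
* **IOA**: outward / inward threshold — identically the ratio of the two
  crowding factors, since the unflanked cell cancels draw by draw.
* **HPDI** (`hdi()`): shortest contiguous window of the sorted draws
  containing ⌈mass·n⌉ points; ties break toward the lower window. Masses
  0.53 and 0.97 are the reporting convention (53% ≈ ±0.75 posterior SD for
  a normal; 97% avoids the false precision of 95%).
* **Exceedance** (`exceedance()`): strict fraction of draws above a
  criterion; criteria 1 (any asymmetry) and 1.5 (conservative asymmetry).
* **Contrasts** (`contrast_ratio()`): ratios of IOA between cells or pooled
  cell sets (e.g. horizontal vs vertical meridian). Pooling uses the
  geometric mean of the per-draw IOA values because IOA is a ratio —
  multiplicative by nature; an arithmetic-mean switch is provided.
* **Simulated population** (`simulate_population()`): each simulated
  participant takes one posterior draw (integrating over posterior
  uncertainty rather than fixing point estimates) and draws observer
  offsets from that draw's random-effect SDs; only the inward and outward
  flanker offsets survive in the IOA ratio. Reported: the proportion of the
  simulated sample with IOA above each criterion, per cell.

## Recovery harness and problem sizes

`run_scenario()` chains generator → staircases → exclusion → model →
analysis under one seed and reports, per design x location: the true IOA,
the posterior median, the 97% HPDI, a coverage flag, and exceedance
probabilities, plus staircase bias/precision and the exclusion counts. The
default scenario uses 12 participants and the smoke preset and runs in a
few minutes on one core; the packaged tests run three such seeds for the
asymmetry-recovery check and one for the zero-asymmetry null (true IOA = 1
everywhere, where the median across cells of p(IOA > 1.5) should stay
small). Unit tests use even smaller cohorts (6–8 participants) with a
measurement-noise shortcut in place of full staircase simulation where the
staircase itself is not under test. Full cohort scale (38 participants,
1368 thresholds) is exercised by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* The staircase's posterior is held as unnormalised log densities;
  normalisation happens on demand, so 80-trial products cannot underflow.
* `psychometric_params()` solves its offset in closed form; the threshold
  criterion holds to machine precision.
* `hdi()` on constant samples returns the degenerate interval; on masses
  whose window equals the sample it returns the range.
* Exclusion uses a strict inequality (SD exactly 0.2 is retained).
* `study_design()` refuses configurations whose block arithmetic does not
  close (blocks x trials x designs must equal runs x trials x cells), and
  schedules require block sizes divisible by the location x flanker grid.
* Degenerate fits: a single-row dataset is accepted by the sampler but
  prior-dominated; fewer than 2 chains is an error since R-hat would be
  undefined.

## Known limitations

* Bernoulli responses ignore letter-confusion structure; real 9AFC data
  have inhomogeneous error probabilities across letter pairs.
* Random-effect correlations are not modelled (see above).
* The staircase clamps placements at 3 degrees, so thresholds well above
  the stimulus ceiling are estimated from the psychometric function's lower
  flank only; their posterior SDs grow accordingly and the exclusion rule
  then removes the least reliable of them — visible in the synthetic
  cohort's excluded fraction.
* Bayesian R² is a property of whatever dataset is fitted; on strongly
  structured synthetic cohorts it is naturally higher than on noisier human
  data.
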