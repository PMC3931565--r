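---
title: "Models and methods behind the heterosis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the heterosis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterogrow)
```

This vignette explains the statistical models, the tunable parameters,
and the design choices behind `heterogrow`, in the spirit of a methods
section: what each stage assumes, where the defaults come from, and what
the synthetic-data validation does and does not demonstrate about real
data.

## 1. Growth-rate estimation from OD trajectories

A microplate culture in exponential phase satisfies
$\mathrm{OD}(t) \propto e^{rt}$, so $\log \mathrm{OD}$ is linear in time
with slope $r$, the maximum growth rate (MGR, per hour). The practical
problem is deciding *which part* of a trajectory is exponential: early
readings sit near the background of medium and plate, late readings
decelerate towards saturation. `fit_mgr_experiment()` resolves this per
environment, not per culture:

1. **Background correction** (`correct_background()`): subtract a
   per-culture background estimate and clip at $\varepsilon$ (default
   0.005 OD) so the log stays defined. Methods: median of blank wells
   (when blanks exist), the first reading, or `min_minus_eps`
   (default): $b = \min(\mathrm{OD}) - \varepsilon$. None of these can
   recover the true medium background exactly — `min_minus_eps`
   over-subtracts by roughly the inoculum OD — so the *window* selection
   below must avoid the distorted low range, and does.
2. **Window selection** (`select_window()`): candidate bounds are the
   `grid_size` (default 25) quantiles of the pooled corrected OD values
   of all the environment's cultures. A candidate pair $(lo, hi)$ is
   feasible iff it lies inside every culture's observed OD span — the
   window must be a range that *every* culture traverses — and every
   culture retains at least `min_points` (default 5) readings inside it
   with a defined correlation. The objective is the mean over cultures
   of Pearson $r(\log \mathrm{OD}, t)$ on the retained readings; the
   feasible candidate pair maximising it wins. Ties (within $10^{-12}$)
   go to the wider window, then the smaller lower bound, favouring use
   of more of the trajectory. The span constraint is what makes
   environments whose cultures occupy disjoint OD ranges fail loudly
   instead of returning a meaningless union window.
3. **Regression** (`fit_mgr()`): OLS of natural-log corrected OD on time
   over the in-window readings. Natural log means the slope is the
   instantaneous exponential rate; any other base only rescales it by a
   constant. A fit passes QC when it uses $\ge$ `min_points` readings
   and reaches $r \ge$ `qc_r_threshold` (default 0.99, flagging the
   rare poorly linear fits). Degenerate inputs are flagged rather than
   fabricated: fewer than two in-window points give `NA`, constant OD
   gives slope 0 with undefined $r$, and both fail QC.

One window per environment (rather than per culture) is deliberate: the
exponential OD range is a property of the medium and instrument shared
by all cultures, and per-culture windows would let noise pick
flattering sub-ranges. The implementation evaluates all candidate pairs
with prefix sums over od-sorted readings ($O(1)$ per pair per culture);
`exhaustive = TRUE` uses every observed value as a candidate bound and
serves as the slow reference mode, and the test suite checks the fast
path against an independently coded brute-force search.

**Known limitation.** The max-mean-$r$ objective tolerates mild
curvature: on a logistic trajectory the selected window extends into the
early deceleration phase (roughly up to 0.2 of the carrying capacity),
biasing the slope a few percent low. When runs continue to full
saturation the effect grows; the synthetic assay design therefore stops
each environment's run after a fixed log-fold growth (below), the regime
in which the test suite and acceptance script measure recovery errors of
a few percent.

## 2. Heterosis statistics

With $F$ the mean MGR over QC-passing replicates
(`fitness_matrix()`), per hybrid and environment:

$$\mathrm{MPH} = F_h - \tfrac{1}{2}(F_{p1} + F_{p2}), \qquad
  \mathrm{BPH} = F_h - \max(F_{p1}, F_{p2}).$$

Both are symmetric in the parents and $\mathrm{BPH} \le \mathrm{MPH}$
always. The BPH sign convention is chosen so that *positive = hybrid
beats its best parent*, the conventional reading of best-parent
heterosis. Hybrid×environment cells where the hybrid or either parent
lacks a usable value are excluded (with a count), so a QC-failing parent
never silently contributes. Proportions of positive scores use strict
$> 0$; exact zeros are counted as non-positive and reported separately
(a measure-zero event in real data, but the convention is pinned down).

Supporting tests are wrappers around the standard machinery:
heterozygote-versus-homozygote contrasts use a classic one-way ANOVA on
*strain-level means* (each strain's MGR averaged over all environments
and replicates — so 22 homozygotes plus 231 heterozygotes give
denominator df 251), Welch's unequal-variance $t$ with
Welch–Satterthwaite df, and Pearson correlations between a hybrid
fitness metric (MGR, MPH or BPH) and the parents' sequence divergence,
within one environment and cross-class subset, with the usual
$t$-transform p-value and 0.05/0.01/0.001 star coding.
`correlation_grid()` assembles the full metric × subset × environment
grid and adds a Benjamini–Hochberg column; raw p-values remain the
primary display. Note that hybrids sharing a parent share that parent's
estimation error, so the nominal p-values in the grid are mildly
anti-conservative; the package reports them as such.

## 3. Variance decomposition and repeatability

`varcomp_two_way()` uses the method-of-moments (expected mean squares)
estimators for the balanced two-way random model with interaction,
with $g$ genotypes, $e$ environments, $n$ replicates per cell:

$$\hat\sigma^2_{err} = MS_{w},\quad
  \hat\sigma^2_{G\times E} = \frac{MS_{GE} - MS_w}{n},\quad
  \hat\sigma^2_{G} = \frac{MS_G - MS_{GE}}{en},\quad
  \hat\sigma^2_{E} = \frac{MS_E - MS_{GE}}{gn}.$$

EMS was preferred over REML because it is closed-form, exactly
testable, and agrees with REML on balanced data for this model. Raw
estimates may be negative by sampling; both the raw and the
absolute-value ("reported") scales are kept. Unbalanced input is an
error pointing to `balance_replicates()` (seeded subsampling to the
minimum cell count) rather than a silent approximation. Components are
invariant under adding a constant and scale as $c^2$ — both are tested.

Repeatability uses ICC(1) from the one-way random model of replicates
within strains, per environment, with Searle's adjusted mean group size
$k_0 = (N - \sum k_i^2/N)/(s-1)$ for unbalanced counts; reported values
are truncated below at zero with the raw value retained, and
`icc_average()` averages environments arithmetically. Because the ICC
operates on *estimated* MGRs, estimation noise inflates the
within-strain component; the synthetic pipeline's average ICC (reported
by the acceptance script) is accordingly lower than what error-free
fitness values would give.

## 4. Agar stress assays

Patch image intensities are converted to cell numbers through an OLS
calibration line (`calibrate_intensity()`, $\ge 3$ pairs, warning if
the line predicts non-positive counts over the observed range). Fitness
on agar is the mean growth rate over the whole incubation,
$\ln(N_{final}/N_{initial})/t$ per hour, with doublings counted in log
base 2 — the "three doublings" rule is a base-2 statement, the growth
rate a natural-log one, and both are reported.

The two-stage grower rule is order-sensitive and the order is pinned
down: first, a strain×condition whose trials average $\le 3$ doublings
is classified non-growing and *all* its fitness values are zeroed
(initial residual growth is attributed to carry-over from benign
pre-growth); second, the strain counts as a grower iff at least one
trial retains positive fitness. Consequently a condition with trials
(3.5, 0, 0) is a non-grower despite one good trial. The alternative
order is available (`zero_first = FALSE`) for sensitivity analysis.

For the cross-stress analysis, each stress condition's rates are
divided by the median rate of that condition's growers
(`normalize_fitness()`; non-growers keep 0), the empirical statistic is
each strain's mean normalized fitness over the three stresses, and the
null (`resample_null()`) draws one value per stress uniformly with
replacement — zeros included, which is what produces the four-modal
null matching strains that grow in 0–3 stresses — 10,000 times. The
two distributions are compared with a two-sample Kolmogorov–Smirnov
test whose $D$ is evaluated at every pooled data point (exact under the
heavy ties that the zeros create) and whose p-value uses the asymptotic
Kolmogorov distribution at $\sqrt{n_a n_b/(n_a+n_b)}\,D$, appropriate
at these sample sizes.

## 5. The synthetic-data generator

`simulate_crosses()` generates data with exactly the statistical
structure the analysis assumes, so that every stage can be checked by
parameter recovery. What it emulates, per stage:

* **Phylogeny** (`simulate_tree()`): a coalescent tree per clade
  (domesticated, wild), rescaled to `clade_height` (default 2.6) and
  joined through stems (`stem_length` 0.3). Internal node depths are
  raised to the power `radiation` (default 6), concentrating splits
  near the clade root. This radiation shape is load-bearing: with a
  plain coalescent most pairs coalesce deep, shared mutations dominate,
  and within-clade crosses could not out-gain mixed crosses — the
  empirically observed ordering (largest heterosis among
  domesticated×domesticated crosses) requires most within-clade
  divergence to trace to early splits, which is also the shape of real
  domesticated yeast lineages. Pairwise divergence is Poisson-sampled
  at `subst_per_unit` (2000) substitutions per unit patristic distance,
  drawn once per pair (symmetric, zero diagonal).
* **Mutation accumulation** (`assign_mutations()`): per branch, a
  Poisson number of deleterious mutations at the clade's rate
  (`lambda_dom` 3.5, `lambda_wild` 0 per unit branch length), each with
  homozygous effect $s \sim \mathrm{Exp}(\bar s)$, $\bar s = 0.008$,
  resampled if $s \ge 1$. Strains inherit all mutations on their
  root-to-tip path, so shared ancestry means shared mutation
  identities. The defaults give about ten small-effect mutations per
  domesticated strain — many weak mutations rather than few strong
  ones, consistent with the dozens of candidate loss-of-function
  variants that sequenced strain panels carry — and an expected
  domesticated×domesticated mid-parent gain of roughly 5% of the
  environment baseline. Setting `lambda_wild = lambda_dom` removes the
  clade asymmetry (negative control, tested).
* **Fitness** (`homozygote_fitness()`, `hybrid_fitness()`):
  multiplicative across loci — a homozygote's deterministic fitness is
  $\mu_e \prod_i (1 - s_i)$; in a hybrid, mutations shared by both
  parents stay homozygous ($1 - s$) and private ones become
  heterozygous ($1 - hs$), fully masked at the default $h = 0$.
  Environment baselines `env_means` span 0.25–0.55/h across 11
  environments; a lognormal genotype×environment effect
  (`sigma_gxe` 0.04, one draw per strain×environment) and lognormal
  replicate noise (`sigma_rep` 0.02) complete the model. With
  `lambda_wild = 0` the model is a stylisation that isolates the
  complementation mechanism; it cannot simultaneously hold domesticated
  and wild homozygote means nearly equal (as real panels show) while
  domesticated crosses gain from complementation — synthetic
  domesticated homozygotes sit several percent below wild ones. The
  qualitative contrasts, not the homozygote means, are the validation
  surface.
* **OD trajectories** (`generate_od_curves()`): logistic
  $\mathrm{OD}(t) = K\,\mathrm{od}_0 e^{rt}/(K + \mathrm{od}_0(e^{rt}-1))$
  with $K = 2.5$, $\mathrm{od}_0 = 0.02$, times a lognormal
  measurement factor (`sigma_od_rel` 0.02), plus additive background
  (0.08 OD) and read noise (`sigma_od` 0.002 OD), sampled every 20
  minutes. Both noise components matter: with additive noise alone the
  smooth deceleration phase would out-correlate the genuinely
  exponential but relatively noisier low-OD phase and systematically
  mislead the window selector — a property of the method worth knowing
  about, not a bug in it. Each environment runs until a baseline strain
  has grown `od_log_growth` = 3.6 natural-log units (slow environments
  incubate longer, as an experimenter would arrange), keeping every
  environment's trajectories in the near-exponential regime where the
  window method is accurate.
* **Agar assays** (`generate_agar_assays()`): a strain grows under
  agent $a$ at dose $k$ iff
  $\mathrm{load} + z_a < \mathrm{threshold}_k$, with
  $z_a \sim N(0, \sigma_{robust})$, $\sigma_{robust} = 0.5$, drawn once
  per strain×agent — shared across that agent's doses (so survival is
  monotone along each gradient) but independent across agents, which
  makes cross-stress performance uncorrelated *by construction*: the
  resampling null holds in this world, and the pipeline should not
  reject it. Because $\sigma_{robust}$ dwarfs the load spread, the
  generator does not produce a heterozygote survival advantage under
  stress; it reproduces the null structure of the cross-stress
  comparison, not every stress-related contrast. Growing patches make
  $3 + 1.5 \times \mathrm{margin}$ doublings on average (bounded far
  from the calibration's breakdown regime), non-growing patches a
  sub-3-doubling carry-over residue; three trials per condition;
  calibration pairs follow the true linear cells–intensity law with 5%
  relative noise, drawn log-uniformly over the observed patch-size
  range so small patches anchor the intercept.

Everything is deterministic under a fixed seed, and all stochastic
entry points require one.

### What the synthetic validation shows — and what it does not

The test suite and `scripts/acceptance.R` verify, among other things:
exact agreement of the window search with brute force; MGR recovery
within a few percent through the full OD pipeline; unbiased recovery of
known variance components at the study's dimensions; correct type-I
error of the F and Welch tests; exact KS distances against a
brute-force ECDF; the headline pattern (mid-parent heterosis ordered
DxD > mixed > WxW ≈ 0, with a positive MPH–divergence correlation only
within the domesticated clade) in the large majority of seeded runs;
and non-rejection of the cross-stress resampling null in ≥90% of runs.

These checks validate the *estimators and their wiring* under the
generator's assumptions: multiplicative fitness, fully recessive
mutations, lognormal noise, logistic growth, linear calibration,
threshold survival. Real data can violate any of these — overdominant
loci, epistasis, plate spatial effects, non-logistic growth, intensity
saturation — and passing the synthetic suite says nothing about those
violations. The problem sizes used throughout (the full 253-strain ×
11-environment design for single runs; fitness-level simulation for the
200-run property checks) were chosen to mirror the study design while
keeping a complete validation run in the minutes range.

## 6. Conventions and edge cases, collected

* Time is in hours, MGR in $h^{-1}$, everywhere.
* Natural log for growth regressions; log base 2 only for doublings.
* Symmetry of a divergence matrix is enforced to $10^{-9}$; asymmetric
  input is an error, never averaged away.
* Proportion-positive counts exact zeros as non-positive, reported
  separately.
* Negative variance components are reported as absolute values only in
  the display scale; raw values are always retained.
* ICC is truncated below at 0 (raw kept); all-identical data give ICC 1
  with a flag.
* Welch's test on two zero-variance samples with equal means returns
  $t = 0, p = 1$ by convention.
* Window-objective ties break to the wider window, then the smaller
  lower bound; the tolerance for "tie" is $10^{-12}$.
* Unusably short cultures (fewer than 3 readings) are flagged and kept,
  never silently dropped.
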