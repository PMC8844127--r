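---
title: "Methods: demography-linked metabolomic aging clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demography-linked metabolomic aging clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Inbred genetic reference panels (such as the Drosophila Genetic
Reference Panel) make it possible to measure, on genetically identical
individuals, both a genotype's full mortality trajectory and its
molecular state at several ages.  `metaboclock` implements the analysis
chain that links the two: demographic parameter estimation from
interval-censored death records, age-specific functional phenotypes,
per-metabolite linear models, and a penalized-regression "metabolome
clock" whose residual — age acceleration — is tested as a predictor of
lifespan and mortality parameters.

## Mortality model and estimation

Mortality follows the Gompertz–Makeham hazard

$$\mu(x) = \alpha e^{\beta x} + M,$$

with baseline mortality $\alpha$ (day$^{-1}$), rate of aging $\beta$
(day$^{-1}$), and age-independent extrinsic mortality $M$.  Deaths in a
vial-transfer design are only known to intervals between censuses, so
`fit_gm()` maximizes the exact interval-censored likelihood

$$\ell = \sum_k n_k \log\{S(t_{k-1}) - S(t_k)\} + \sum_c \log S(t_c),$$

with $S(x) = \exp\{-Mx - (\alpha/\beta)(e^{\beta x} - 1)\}$, rather than
imputing midpoint death times.  Optimization runs over
$(\ln\alpha, \ln\beta, \ln M)$ — which enforces positivity and removes
scale pathologies — from multiple starts: the primary start seeds
$(\ln\alpha, \beta)$ by least squares on the log empirical interval
hazard against age and $M$ at half the earliest-interval hazard, with
fixed fallbacks, each polished by Nelder–Mead and then BFGS (relative
objective tolerance $10^{-12}$).  Non-convergence is reported, not
silently accepted; the returned log-likelihood is the achieved maximum,
and tests verify it dominates both the generating truth and a coarse
parameter lattice.

`include_makeham = TRUE` is the default (flies show extra early-age
mortality); the pure Gompertz fit is used for analyses phrased only in
$\alpha$ and $\beta$, such as the Strehler–Mildvan correlation
(Spearman's $\rho$ between $\ln\alpha$ and $\beta$ across genotypes)
and the linear model of mean lifespan on $(\ln\alpha, \beta)$.

Restricted mean lifespan is the area under the Kaplan–Meier curve
(survival package), with events placed at interval *ends* — the census
at which a death is recorded — for compatibility with transfer-day
recording; its standard error is the Greenwood-based area formula.  The
choice of the KM/Greenwood SE (rather than a simple SEM across flies)
is deliberate and documented here because either convention is
defensible.  Mid-life hazards (days 45 and 60) are computed from the
fitted model, not from empirical bins, because binned hazards at those
ages are noisy while model-based ones are stable.

## Per-metabolite models

Raw intensities are log-transformed, QC-screened, and each *sample* is
centred and scaled to mean 0, SD 1 across the panel.  The QC rule drops
a sample when more than a threshold fraction (default 1/3) of its
metabolites have robust z-scores (median/MAD per metabolite) beyond 4 —
the situation where a third of a replicate's panel is visibly abnormal.

`fit_age_genotype_model()` fits, per metabolite,
`level ~ Age + Genotype + Age:Genotype` with age categorical, and
adjusts p-values by Benjamini–Hochberg within each term family.  Age is
categorical here because the screen asks whether level differs among
sampled ages at all; the increase/decrease *direction* label instead
comes from the OLS slope on numeric age, since a direction needs a
monotone summary.  By default the model uses only the first four
sampling ages, where nearly all genotypes are present; later ages are
unbalanced by cohort die-off and would conflate age with genotype
composition.  Block and batch columns are carried in the metadata but
not modelled: the module's scope is the fixed-effects screen, and
nuisance variance-component estimation is deliberately out of scope.

Associations with demography (`level_demography_assoc()`,
`trajectory_demography_assoc()`) regress a *genotype-level* summary
(mean level at one age, or the per-genotype age-trajectory slope over
the first four ages) on each demographic parameter.  Replicates are
averaged first because the demographic parameters are genotype-level
quantities — using replicate rows would pseudo-replicate.  BH
adjustment is applied within each (parameter, age) family of
panel-width tests, the structure in which such tables are reported.
Both the linear-model p-value and Spearman's $\rho$ are emitted; the
q-values follow the linear-model p.

## The clock

The clock minimizes

$$\frac{1}{2N}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
  \lambda_2\left\{(1-\lambda_1)\tfrac{\|\beta\|_2^2}{2} +
  \lambda_1\|\beta\|_1\right\},$$

with the penalty exactly in this parameterization (no rescaling to
other conventions): $\lambda_1 = 0$ is ridge, $\lambda_1 = 1$ is lasso,
$\lambda_1 = \lambda_2 = 0$ is OLS.  The solver is covariance-update
coordinate descent in compiled code, warm-started along a descending
$\lambda_2$ path.  Because row-standardized samples place the all-ones
vector in the null space of the design, the unpenalized corner is flat
along that direction; convergence is therefore declared either on the
maximum coordinate change or on a monotone-objective plateau, which is
exact in function value.  Features enter as-is — samples are already
row-standardized — and no per-feature standardization happens inside
the fit (a documented choice; the intercept is never penalized).

Tuning follows the repeated-split protocol: random 80/20 train/test
splits, $(\lambda_1, \lambda_2)$ selected by 5-fold CV inside the
training set over the grid ($\lambda_1 \in \{0, 0.1, \ldots, 1\}$;
$\lambda_2$ over 100 values evenly spaced in $[10^{-6}, 1]$ plus 1000
in $[1, 1000]$ — linear spacing, as is conventional for this protocol),
test-set $R^2$ reported per repeat, 100 repeats by default.  The
"optimal" pair used for leave-one-out prediction is the grid point
minimizing mean CV error across all repeats; the per-repeat modal pair
is also returned, since no single rule is canonical.  CV folds are
unstratified and every split is governed by one seed.  LOOCV refits the
model $N$ times with cross-moment matrices downdated per left-out
sample, so no sample influences its own prediction; selection and
LOOCV both operate on the post-QC sample set.

Age acceleration is `predicted − chronological` age per sample;
genotype means at a chosen age (day 45 by default) are regressed
against each demographic parameter, with Spearman correlations
alongside.

## What the generator emulates — and what it does not

The synthetic module reproduces the statistical structure the analysis
assumes, so that every stage is testable without external data:

* **Cohorts**: 20 genotypes, 5 vials of 25 females, censused every 2
  days.  Death times are drawn exactly: the Gompertz component by
  closed-form CDF inversion, $T = \beta^{-1}\log\{1 -
  (\beta/\alpha)\log U\}$, the Makeham component as a competing
  exponential — the minimum has exactly the Gompertz–Makeham hazard.
  $(\ln\alpha, \beta)$ pairs come from a Gaussian copula over uniform
  margins with the copula correlation set to $2\sin(\rho_s\pi/6)$ so
  the *Spearman* correlation matches the requested Strehler–Mildvan
  coupling (default $-0.8$).  The default ranges, $\ln\alpha \in
  [-16.5, -7]$ and $\beta \in [0.075, 0.25]$, were fixed once by
  numerical integration of the survival curve so that 20 genotypes span
  mean lifespans of roughly 37–82 days — the breadth such panels are
  chosen to cover.
* **Metabolome**: an 87-metabolite panel at days 4/10/24/45/69/80, with
  a replicate design of a quarter of genotypes at 4 replicates, a
  quarter at 2, the rest at 1, and survival-based dropout (a genotype
  is absent from ages its cohort would reach with under 10% survival),
  yielding ~180 samples.  Effect classes follow the composition of a
  real targeted panel (≈33% age-increasing, ≈36% age-decreasing, ≈93%
  genotype, ≈43% interaction).  Real studies report which effects
  exist, not their sizes, so effect sizes are configuration defaults
  calibrated once by pilot simulation to roughly 80–95% power at BH-FDR
  0.01 under this design (age slopes 0.02–0.05 log-units/day, genotype
  SD 0.7, interaction slope SD 0.05/day, residual SD 1, baseline
  abundance SD 2).
* **The planted clock phenomenon**: the age-trend metabolites define
  the clock direction; at days 24 and 45 each genotype's samples are
  shifted along it by `aa_coupling` × (reference − genotype lifespan),
  with the median lifespan as reference.  Early ages carry no lifespan
  signal, matching the observation that young-age profiles do not
  predict lifespan.  The default coupling (0.75 days of acceleration
  per day of lifespan deficit) makes a genotype ~30 days short-lived
  read ~22 days old at day 45 — the magnitude needed for mid-life
  short-lived profiles to resemble late-life long-lived ones.  Two
  generator choices keep this phenomenon identifiable: interaction
  deviations are orthogonalized against the clock axis (they are trend
  noise, not lifespan signal), and age trends are centred at the mean
  sampling age with a wide baseline-abundance spread, so per-sample
  standardization is nearly age-invariant.  Without the latter, row
  scaling compresses the clock axis at extreme ages — a real
  phenomenon worth remembering when normalizing real data.
* **Phenotypes**: activity declines linearly over weeks 3–6 with
  genotype-specific slopes and a level positively coupled to lifespan;
  weeks 1–2 vary idiosyncratically.  Fecundity at days 8 and 12 shares
  a genotype effect (correlating the two days) but is independent of
  lifespan.

The generator does *not* emulate: raw chromatograms or peak
integration (intensities start at the peak-area-table level),
block/batch variance (the columns exist but carry no signal),
non-linear or non-monotone metabolite trajectories, or heavy-tailed
measurement noise.  Passing tests therefore demonstrate that the
estimators recover the structure they assume — not that real data meet
those assumptions.

## Numerical choices

* GM likelihood: interval probabilities below machine precision return
  $-\infty$ and the start is discarded; fits with fewer than 10 deaths
  warn as unreliable; a single-interval table is not identifiable and
  errors.
* Coordinate descent: tolerance $10^{-9}$ on the maximum coordinate
  change (fits) or $10^{-7}$ (grid search), objective-plateau stop after
  3 flat sweeps at relative $10^{-13}$, $10^5$ sweep cap; grid search
  warm-starts along descending $\lambda_2$; CV ties resolve to the
  first grid point in iteration order (smaller $\lambda_1$, larger
  $\lambda_2$), deterministically.
* Spearman p-values: exact permutation distribution for $n < 10$
  without ties, t-approximation otherwise; ties get average ranks.
* Restricted mean defaults its truncation to the last observed time;
  `tau` earlier than the first event is an error.
* Fecundity is stored as raw offspring per female-day; the square-root
  transform used for variance stabilization in genotype ANOVAs is
  applied at analysis time, not storage time.

## Problem sizes used by the test suite

The packaged checks run the full 20-genotype, 87-metabolite design for
clock recovery (20 tuning repeats over a reduced 3 × 50 grid) and
age-acceleration recovery (20 planted and 20 null simulations), a
reduced 8-genotype, 30-metabolite design for the 200-replicate FDR
calibration, and 50 cohorts of 1000 flies per parameter set for GM
recovery — sizes chosen so each property is measured with adequate
replication while the whole suite stays comfortably runnable on a
laptop.

## Known limitations

* The interval-censored likelihood assumes the census grid is exact;
  deaths at transfer time are assigned to the preceding interval.
* Late-age analyses inherit the survivorship structure of the design:
  day-69/80 samples exist only for long-lived genotypes, which is why
  the age-by-genotype screen restricts to early ages by default.
* The clock is linear; saturating trajectories would need basis
  expansion before the same machinery applied.
* With ~20 genotypes, genotype-level correlations have wide sampling
  error; the planted-effect recovery rates quoted in the tests are
  properties of this design size.
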