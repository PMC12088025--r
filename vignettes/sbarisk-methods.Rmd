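---
title: "Methods: the skilled-birth-attendance risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the skilled-birth-attendance risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbarisk)
```

## The model and its assumptions

`sbarisk` models the probability that a skilled birth attendant (SBA) is
present when a woman's active phase of labour begins as

$$P(\mathrm{SBA}) = 1 - G_k(t)\,F(d),$$

with $F$ the CDF of the labour-onset offset ADD − EDD in days, $G_k$ the
parity-specific CDF of the latent-phase duration in hours, $t \ge 0$ the
woman's time to reach an SBA from the first signs of labour, and
$d \le 0$ the planned maternity-waiting-home (MWH) move day relative to
the expected due date (EDD). $d = +\infty$ encodes "no MWH stay", for
which $F \equiv 1$ and the risk reduces to the latent phase being shorter
than the journey. The model's structural assumptions are:

* labour onset and latent-phase duration are independent;
* $t$ is known (uncertainty in $t$ is handled only through the
  interval-grid convention below, not as a random quantity);
* moving to the MWH on day EDD + d removes all travel-time risk for
  labour onsets after that day.

Both inputs are one-dimensional CDFs, so every quantity in the package
reduces to evaluations of $F$ and $G_k$; everything downstream (tables,
recommendation rule, bootstrap) is deterministic given those inputs.

## Input distributions

Two estimation routes produce interchangeable `sba_dist` objects.

**Gaussian KDE on truncated supports.** Given an empirical sample, the
density estimate is the equal-weight sum of Gaussian kernels at the
sample points, clipped to the stated value range ([−30, 30] days for
onset; [0, 30] h nulliparous and [0, 16] h multiparous latent phases) and
renormalised so the CDF runs from 0 to 1 across the range — the estimated
curves reach 1 at the range boundary. Internally a KDE is just a
truncated normal mixture with one component per sample point, so the same
closed-form CDF/quantile/moment code serves both routes, and a
10,000-kernel KDE evaluates in microseconds.

The bandwidth parameter (default 0.3) is interpreted as the kernel SD
itself, in days or hours (`bandwidth_type = "absolute"`). The alternative
reading — a multiplicative factor on the sample SD — is available as
`bandwidth_type = "relative"`. We chose the absolute reading as the
default for two reasons. First, it keeps the estimator's smoothing bias
well below the sampling error of the source cohorts: a relative factor of
0.3 on onset data with SD 9.21 d means a kernel SD of 2.8 d, which
inflates the estimated spread by ~4% systematically; with cohorts of
500–10,000 points that bias dominates the sampling error, and percentile
bootstrap intervals (which cannot absorb estimator bias) then fail to
cover the generating value. With an absolute 0.3 d/h kernel the full-grid
bootstrap coverage in our Monte-Carlo study is ~0.91 at the 95% nominal
level, against ~0.78 under the relative reading. Second, the absolute
reading leaves end-to-end parameter recovery (surrogate → synthetic
cohort → KDE → risk table) essentially unbiased as cohorts grow.

**Calibrated truncated-normal-mixture surrogates.** The source cohorts
for both inputs are published only as summary statistics, so the package
ships surrogate distributions calibrated to those printed values:

| preset | kind | constraints | support |
|---|---|---|---|
| `khambalia` | onset | mean −1.48 d, SD 9.21 d, mass 0.66 on [−7, 7] d | [−30, 30] d |
| `mongelli` | onset | mean −1.79 d, SD 11.3 d (single component) | [−30, 30] d |
| `friedman_nulliparous` | latent | mean 7.1 h, SD 4.0 h, P95 = 20 h | [0, 30] h |
| `friedman_multiparous` | latent | mean 5.3 h, SD 4.1 h, P95 = 14 h | [0, 16] h |

A two-component truncated normal mixture is the smallest family that can
satisfy three constraints; notably, the printed latent-phase means/SDs
and 95th percentiles are mutually inconsistent under *any* two-parameter
unimodal family (a normal with mean 7.1 and SD 4.0 has its 95th
percentile at 13.7 h, not 20 h), so a heavier-tailed mixture is forced.

**Calibration.** Constraints are matched on the truncated, renormalised
mixture using closed-form truncated-normal moment identities, verified
independently by adaptive quadrature. With five free parameters and three
constraints the solution set is a manifold; the fit is identified by
**maximum differential entropy** — among all mixtures reproducing the
printed statistics we return the least-informative one. The solve is a
deterministic penalised Nelder-Mead (entropy objective with increasing
constraint penalty, then a pure-constraint projection) from a fixed
initialisation schedule, so identical calls give identical mixtures with
no random seed. Component scales are floored at 5% of the target SD so no
component degenerates towards a point mass. Infeasible constraint sets
(e.g. a quantile violating Cantelli's inequality for the requested
mean/SD) are reported as errors naming the violated constraint.

## Synthetic cohorts

`sample_cohort()` draws i.i.d. values from a preset's calibrated mixture
by component choice (truncation-adjusted weights) followed by an
inverse-CDF truncated-normal draw — exact, so latent draws are never
negative and onset draws never leave [−30, 30] d. Default sizes are the
published cohort sizes (10,243 onset; 500 per parity). The generator
emulates the *published statistics* of the real cohorts, not their full
empirical shape: passing recovery tests shows the pipeline recovers the
surrogate truth from finite samples, not that the surrogates equal the
unpublished data (see "Known limitations").

## Risk tables and the conservative convention

The device grid has 22 access-time rows ([0,1], [1,2], [2,3] h, then
half-hour steps to 12.5 h) and six scenarios (no MWH, move on the EDD,
1–4 weeks early). Because $P(\mathrm{SBA})$ is non-increasing in $t$,
each interval reports its value at the **upper** bound — the interval
minimum — so advice never overstates safety within a row. Intervals are
treated as half-open $(\ell, u]$; since only upper bounds are evaluated,
endpoint ownership does not affect any output. Cells are banded salmon
($p < 0.90$), light green ($0.90 \le p < 0.95$) and dark green
($p \ge 0.95$); the half-open convention partitions $[0,1]$ without
overlap. Displayed values are rounded to two decimals; CSV/JSON exports
carry full precision (17 significant digits) and round-trip exactly. The
JSON export additionally groups the six scenario columns as concentric
rings keyed by interval label — the data layout of the physical
wheel-style device the tables feed.

## Recommendation rule

`recommend_move_date()` walks candidates from least burdensome (no MWH
stay) to most (earliest move) and returns the first whose
$P(\mathrm{SBA})$ meets the threshold. The worked example — a multiparous
woman 10 h 15 min from an SBA at threshold 0.90 — selects the move two
weeks before the EDD. When no candidate meets the threshold the best
candidate is returned flagged `met = FALSE` rather than erroring, since
the device always displays all six scenarios.

## Bootstrap confidence intervals

Cell CIs account for sampling error in the estimated inputs: each
iteration resamples the onset and latent datasets with replacement
(independently, at their original sizes), re-estimates both CDFs with the
same KDE settings as the point estimate, and recomputes every cell. The
95% interval is the 2.5th/97.5th percentile (type-7 interpolation) of the
replicates. Defaults: at most 2000 iterations, convergence checked every
100 on the running SDs of all cells jointly — the loop stops once every
cell's running SD has moved less than 10⁻³ over the last 100 iterations
(measured as the range of the running-SD sequence, so drift and
oscillation both count). Non-convergence is reported via a flag, not an
error. Identical seeds and inputs give bit-identical intervals.

In a 200-replication Monte-Carlo study (cohorts of 500 drawn from the
calibrated surrogates, every cell of the multiparous table tracked), mean
coverage of the true cell values at the 95% nominal level is ~0.91.
Coverage is lowest (~0.75–0.85) in the first row (0–1 h), where the
truncated KDE's boundary bias is largest relative to the tiny
latent-phase mass below 1 h.

## Numerical choices

* Quantiles invert the monotone CDF by bisection (`uniroot`, tolerance
  10⁻⁹; the round-trip $|F(F^{-1}(p)) - p|$ is well under 10⁻⁶).
* Quadrature cross-checks split the support at component locations so an
  adaptive rule cannot step over a narrow component.
* Calibration tolerance is 10⁻³ relative on every constraint.
* Zero-variance samples are rejected by the KDE rather than producing a
  point mass; samples outside the support are errors, not clipped.
* Units are fixed by type: onset offsets are always days (negative =
  before the EDD), latent durations always hours. Nothing is inferred.

## Known limitations

* **Surrogate-vs-empirical gap.** The calibrated surrogates reproduce the
  printed summary statistics exactly, but not the unpublished empirical
  curves. The printed multiparous statistics (SD 4.1 h, P95 = 14 h) are in
  fact inconsistent with the multiparous risk table they accompany, whose
  no-MWH column implies SD ≈ 3.4 h and P95 ≈ 11.5 h. Consequently
  surrogate-built tables agree with the printed ones to within ±0.02 in
  the early-move columns (d ≤ −14) but deviate by up to ~0.07 in the
  no-MWH column; we verified by direct search that no mixture in the
  family can satisfy the printed constraints and stay within ±0.05 of
  that column everywhere.
* **Parity ordering.** The multiparous-riskier-than-nulliparous ordering
  holds for $t \in [1, 9]$ h under the surrogates but crosses above
  ~9.5 h: the nulliparous P95 = 20 h constraint defers 5% of its mass
  beyond 20 h, flattening its upper tail while its core rises faster. The
  real empirical curves do not cross; this is a surrogate artefact.
* The model treats $t$ as exact, ignores EDD-prediction uncertainty, and
  assumes onset/latent independence; none of these are estimated here.
* Bootstrap intervals quantify sampling error only, not the
  surrogate-vs-empirical gap above, and percentile intervals cannot
  correct estimator bias.

## Problem sizes used in the test suite

Unit tests run KDE/bootstrap experiments at cohort sizes 100–5,000 and
100–400 bootstrap replicates; the coverage study uses 200 replications ×
200 replicates at cohort size 500; generator-recovery checks draw 10⁵
points; the end-to-end recovery experiment uses up to 20,000 onset /
5,000 latent points. These sizes were chosen so the whole suite exercises
every code path at Monte-Carlo error levels well below the tolerances
asserted.
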