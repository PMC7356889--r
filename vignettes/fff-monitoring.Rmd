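---
title: "Robust multivariate monitoring of formulation, fill and finish campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multivariate monitoring of formulation, fill and finish campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fffmon)
```

## The monitoring problem

Formulation, fill and finish (FFF) is the last set of unit operations that
turns a purified drug substance into the final product: thawing,
formulation, sterile filtration, filling and (often) lyophilization.
Monitoring data for these steps is heterogeneous: a quality database (QDB)
holds one row of single-point features per lot together with step
timestamps, the lyophilizer logs per-lot time series (inlet/outlet
temperatures, chamber vacuums, condenser signals — LP1–LP7), and the
filtration skid records a single continuous stream (product temperature,
applied pressure, weight — SF1–SF3) with nothing in the data marking where
one lot ends and the next begins. Routine practice evaluates each feature
univariately, which misses abnormalities that only show up as a change in
the *correlation* between features. `fffmon` implements a five-step
multivariate workflow: align, clean, set phases, extract features, and fit
a robust PCA outlier model.

## Alignment

The lot identifier joins the QDB and lyophilization sources. The filtration
stream has no lot labels; it is contextualized by the QDB's
sterile-filtration start/end timestamps. Intervals are half-open
`[start, end)`, so adjacent lots are non-overlapping by construction, and a
boundary sample belongs to the later lot; the attribution of boundary
samples is a convention of this package, chosen for its conservation
property (every stream sample is assigned at most once, and assigned plus
unassigned counts equal the stream length — an invariant the tests assert).
Analysis uses per-series seconds-from-start; absolute datetimes survive
only inside the QDB record. No resampling happens at ingest: the phase
algorithms receive the native grid, and a warning is emitted when the
max/median inter-sample gap exceeds 10 (a gappy series is usually a export
artifact). A batch may lack a source; downstream stages skip absent signals
and log the omission rather than failing the campaign.

## Cleaning

Two artifact classes are removed because they are process-typical but
monitoring-irrelevant, and would otherwise dominate extracted features:

* the terminal pressure peak of SF2 (pressure rises sharply when filtration
  ends) — a backward scan truncates the last contiguous suffix whose local
  slope magnitude exceeds a threshold; interior ramps are never touched;
* operator-induced spikes on the SF3 weight signal (personnel stepping on
  the scale) — excursions whose local slope magnitude exceeds a threshold
  are deleted from the sample that leaves a `3σ` band around the
  pre-excursion level until the signal re-enters that band (or a maximum
  duration elapses).

Samples are deleted, never interpolated: deletion cannot fabricate data,
and all downstream features tolerate non-uniform grids. Slopes are measured
over a 3-sample window so a single noisy sample cannot trigger removal.
Both cleaners are idempotent and their output is a subsequence of the
input. The noise scale `σ` is estimated from first differences:
`1.4826 · median|Δy − median Δy| / √2` by default, which is immune to the
small fraction of samples lying on ramps or spikes. The default slope
threshold is `10σ / median(Δt)`, appropriate for signals whose process
slope is far below any artifact slope (the slow drain of a filtration
weight); both thresholds are configurable per signal. General smoothing
filters (median, Savitzky–Golay) are deliberately out of scope: they trade
artifact suppression for information loss and still fail on strong
interference.

## Step-signal phase setting

Most FFF time series are step-shaped — plateaus joined by sharp ramps
caused by setpoint changes. A slope starts at the first sample where
`|y_t − y_{t+i}| > threshold` and ends at the first subsequent sample where
the difference falls back to the threshold or below; the intervals between
slopes are plateaus. Three design choices matter in noise:

* **Lookahead `i`.** The detector compares values `i` samples apart, so a
  ramp contributes `i` increments per comparison while noise does not
  accumulate. The constructor default is `i = 1` (the bare form of the
  detection equations); the campaign-matched configuration
  (`default_step_config()`) uses `i = 3`, sized so template ramps clear the
  noise threshold with a wide margin. Boundary accuracy degrades gracefully
  with `i` (all recovery tolerances scale as `i + 2` samples).
* **Threshold.** Default `3 × σ` from the noise estimator above. When
  expert duration bounds are supplied, the threshold adapts: a phase
  shorter than its minimum raises the threshold (the detector was too
  jumpy), one longer than its maximum lowers it, and the scan restarts
  globally — up to `max_iterations` (default 20). The adjustment is
  multiplicative (factor 1.5) until one raise and one reduce event bracket
  the viable window, after which it bisects geometrically; a pure
  multiplicative step can hop over a narrow window indefinitely. If the
  bracket collapses, no viable threshold exists and the best iteration
  (fewest duration violations) is returned flagged as non-converged.
* **Local end-discarding.** Inside a ramp, noise can momentarily pull the
  lookahead difference under the threshold. A slope-end proposal arriving
  before the minimum slope duration is therefore discarded and the scan
  searches for the next best end guess. The complementary failure —
  a noise excursion on a plateau promoted to a forced-minimum-length
  slope — is absorbed by re-classifying every slope segment by the
  *median* of its lookahead differences and merging re-classified segments
  into their plateau neighbours.

With these three mechanisms, boundary recovery on synthetic campaigns is
exact without noise and ≥ 95% (within `i + 2` samples) at a
signal-to-noise ratio of 20, degrading at SNR 10 — the regime the
`generate_noise_study()` sweep quantifies. Determinism, coverage,
alternation of kinds and scale equivariance are property-tested.

A signal that begins mid-slope yields a leading slope phase and a flag,
rather than an error.

## Intertwined (rule-based) phases

Some process phases are only defined by conditions across several signals.
Rules are declarative: each has a run order, a start predicate and an end
predicate, and may reference boundaries of phases with smaller run order
only. The bundled lyophilization rule set monitors LP4 in four phases with
run order (2, 1, 3, 4): LP-Phase 2 starts at the first time the relative
difference between the chamber-vacuum signals LP3 and LP4 drops below 20%
and ends at the increasing slope of LP1; Phase 1 runs from the start of LP4
to the start of Phase 2; Phase 3 ends when LP4 returns to the value it had
at the beginning of Phase 2; Phase 4 closes the signal. The four phases
partition LP4's support exactly — an invariant of the rule semantics
(each phase ends where the next starts).

Two under-specified points were resolved as follows:

* *Relative difference.* "Below 20%" is computed as
  `|LP3 − LP4| / max(|LP3|, |LP4|)` on the union grid with linear
  interpolation of the coarser signal. The symmetric maximum denominator
  avoids division by near-zero on vacuum signals and is monotone in the
  gap; the percentage is interpreted against the larger reading.
* *Value return "within a certain time range".* A bare
  earliest-within-tolerance rule would fire immediately, because the signal
  is still inside the tolerance band right at the reference boundary. The
  predicate therefore requires a *departure* (the signal leaves the band)
  followed by a *re-entry*, with the crossing time interpolated so a steep
  ramp that jumps across the band between samples still yields its
  crossing. The re-entry is debounced over a window (default 10% of the
  signal span): it counts only if the signal stays in the band or crosses
  the reference within the window, which rejects transient noise blips.
* *Slope onset.* A one-shot first-crossing detector is much more exposed
  to noise than the repeated scan of the segmentation algorithm (a single
  false comparison anywhere before the true onset is fatal), so its
  default threshold is `6σ` with a 3-sample lookahead.

## Feature extraction

Per phase: mean, minimum, maximum on any phase; the sample standard
deviation on plateaus (a direct noise monitor); the RMSE of an ordinary
least-squares line of value on time within slopes ("residuals of the
slope" — RMSE is the scalar a monitoring chart needs); and phase durations.
Feature names are canonical `signal|phase|statistic`. The default roster
(4 step signals × 28, the four LP-Phases × 4, plus 2 cleaned-SF2 summaries)
yields 130 extracted features; joined with 122 QDB features this gives the
252-column lot × feature matrix whose bookkeeping the tests assert.
Zero-variance columns (setpoint-like constants) are removed first; columns
with more than 20% missing entries are dropped with a warning and remaining
missing entries are imputed by the column median, because the robust fit
requires complete data; then every column is scaled to equal weight. The
default scaling is median/MAD so that the scaling itself cannot be skewed
by the very lots one hopes to find (classical mean/SD scaling is available
for comparison). Pipeline order is filter, then model.

## Robust PCA, distances and diagnostics

The model is the pinned three-stage ROBPCA variant:

1. **Rank reduction.** An SVD restricts the data to the affine subspace
   they span — mandatory when features outnumber lots.
2. **Stahel–Donoho trimming.** Outlyingness is the maximum over projection
   directions of the robustly standardized projection
   (`|x − median| / MAD`); directions pass through pairs of observations —
   all pairs when `N ≤ 25`, plus 250 seeded random pair directions. The
   `h = max(⌊αN⌋, ⌊(N+k+1)/2⌋)` least outlying lots (α defaults to 0.75,
   trading efficiency against a 25% breakdown reserve) define a trimmed
   covariance whose spectrum selects `k` (smallest reaching 80% cumulative
   variance, unless pinned) — mirroring variance-driven component selection
   in monitoring practice.
3. **Refinement.** Lots whose orthogonal distance to the preliminary
   subspace is below its Wilson–Hilferty cutoff re-estimate the subspace
   (this reweighting restores efficiency on clean data without readmitting
   leverage points: without it the robust-vs-classical subspace angle on
   clean Gaussian data roughly doubles); then a reweighted minimum
   covariance determinant in the k-dimensional score space — exhaustive
   over all `C(N, h)` subsets when that is feasible, otherwise a seeded
   C-step search — supplies the robust center and component variances, with
   the usual chi-squared consistency factors.

Distances are `SD_i = sqrt(Σ_k t_ik²/λ_k)` and
`OD_i = ‖x_i − μ − P t_i‖`. Cutoffs (both at the 97.5% quantile): SD uses
`sqrt(χ²_{k,0.975})`; OD uses the Wilson–Hilferty route, treating
`OD^{2/3}` as Gaussian with median/MAD location and scale. Classification
is strict (`>` flags; boundary equality is regular); when the model spans
the full data rank, OD is identically zero and OD classification is
suppressed. The contribution decomposition
`c_ij = (x_ij − μ_j) Σ_k P_jk t_ik / λ_k` satisfies `Σ_j c_ij = SD_i²`
exactly (an algebraic identity the tests check to 1e-6 relative), which is
why this particular decomposition was adopted — the bar plot provably
accounts for the whole squared score distance.

All stochastic steps derive from a required seed; identical input and
configuration reproduce the model bit for bit.

The classical comparison (`fit_cpca_diagnostics()`) fits mean-centered PCA
and computes Hotelling `T²` with its `k(N−1)(N+1)/(N(N−k)) · F_{0.95;k,N−k}`
limit and normalized DModX with its F-based 95% limit. Because a gross lot
inflates exactly the classical eigenvalues it is judged against, classical
T² systematically masks planted score outliers that the robust fit flags —
the qualitative direction the acceptance suite reproduces (robust detection
≈ 100%, classical ≈ 0–3% on 10%-contaminated campaigns).

## The synthetic campaign generator

The generator emulates the *statistical shape* of an industrial 58-lot
campaign, not lyophilization physics: step templates for LP2/LP5/LP6/LP7
(levels, plateau and ramp durations bracketed by the default duration
bounds — unsolvable templates are rejected), rule signals LP1/LP3/LP4
constructed so every bundled rule condition has a unique closed-form
crossing, filtration segments with a terminal SF2 ramp and rectangular SF3
spikes, inter-lot gap samples in the continuous stream, and a QDB block
from a latent-factor model with decaying factor strengths (process
campaigns have a dominant covariance direction) plus constant setpoint
columns. Lot-to-lot variability enters as jitter on levels (1% of range)
and durations (±3%). Everything is deterministic from one master seed, with
per-lot sub-seeds.

Planted abnormalities: `noise_inflation` multiplies one signal's sensor
noise by 1.3 — the magnitude seen on real excursion lots — and reliably
lifts that signal's plateau-standard-deviation features by ≥ 25%;
`plateau_shift` offsets a signal's levels; `qdb_shift` moves a lot along
the dominant direction of the true QDB covariance by 10 standard deviations
of that component. The 10-SD magnitude makes the plant an unambiguous
*score* outlier: with far more features than lots the estimated subspace
deviates from the population one by a non-trivial angle, and a smaller
shift leaks enough of its norm into the orthogonal complement to sit on
the classification boundary, which would test subspace estimation error
rather than outlier detection.

What passing tests do and do not show: the generator's noise is i.i.d.
Gaussian per sample, sensors share a common clock, and abnormalities are
single-mechanism. Real campaigns have drifting sensors, autocorrelated
noise, and compound root causes; results here validate the machinery, not
any specific facility. One negative finding is documented deliberately: a
1.3× noise excess on a *single* signal spreads its evidence over ~10
statistically independent spread-features, and with 58 lots and ~250
features whether that deviation loads on the score or the orthogonal
distance depends on which noise-shaped directions the 80%-variance subspace
happens to retain — the planted lot then lands beyond the 97.5% line in
only about half of the campaigns (top contributors still point at the
right features, as the README example shows). Reliable quadrant-level
detection claims therefore use the in-model `qdb_shift` mechanism.

## Numerical choices and limitations

* Noise-free signals yield `σ = 0`; thresholds then fall back to machine
  epsilon, so exact step profiles still segment.
* The MCD covariance is regularized by a scaled identity when a candidate
  subset is numerically singular; ties in the left-to-right scan resolve to
  the earliest sample.
* The SD flag rate on clean Gaussian lots sits near its nominal 2.5%
  (measured 2.5–3.1% at N = 200), but on heavy-tailed *feature* matrices
  (durations, extrema) the asymptotic chi-squared cutoffs are liberal:
  on a realistic campaign a material fraction of lots lands outside the
  regular quadrant. The map is a screening and root-causing tool; adaptive
  cutoff estimation is a known refinement and out of scope here, as are
  machine-learning phase setting, kernel/sparse PCA variants and online
  model updating.
* Problem sizes in the test and acceptance suites (4–20 lot campaigns for
  fixtures, the 58-lot default shape for pipeline-level checks, 50-seed
  Monte-Carlo panels) were chosen as the smallest sizes at which the
  studied properties are stable.
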