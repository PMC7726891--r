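---
title: "Methods: balance-board array fusion, step intentions, and functional screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balance-board array fusion, step intentions, and functional screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebbmetrics)
```

This vignette is the package's account of its own modelling choices: the
sensor-fusion model and its assumptions, every tunable parameter that
matters, what the synthetic cohort generator does and does not emulate,
and the numerical conventions adopted where the design was genuinely
open.

## 1. Sensor fusion model

An extended balance board is an array of six force platforms, each with
four corner load sensors, sampled at 20 Hz (24 channels). Each sensor
*(i, j)* is assigned a fixed coordinate $c_{ij} \in [-1,1]^2$ in the
board-plane frame. The centre of mass of the standing player is the
weight-normalised projection

$$\mathrm{com}(t) = \frac{1}{w}\sum_{i=1}^{6}\sum_{j=1}^{4}
  s_{ij}(t)\, c_{ij},$$

where $w$ is the player's weight in the same load units. The model
assumes (a) quasi-static loading — the projection is a centre of
*pressure* treated as a centre-of-mass proxy, valid at the slow movement
speeds of the target population; (b) mass conservation — the 24 loads sum
to $w$; when they do not (sensor dropout, dynamic loading), components
may leave $[-1,1]$. We deliberately do **not** clip out-of-range values:
clipping would silently distort the max/min/SD features, so the values
are kept and counted in the playthrough's QC summary.

**Board geometry.** The physical arrangement of the six boards is not
canonical, so the layout is a validated configuration object
(`ebb_layout()`, YAML/JSON round-trip via `read_layout()`), not a
constant. The default is a plus/cross: two central boards jointly
covering $[-0.33, 0.33]^2$ and four outer boards (up/down/left/right)
whose far edges reach $\pm 1$. This is the geometry implied by the
intention thresholds: a full step onto an outer board must push the main
axis well past 0.5 while the off-axis stays near 0. Within a board,
sensors sit at the rectangle corners — the four-sensor rectangle is a
validated invariant.

**Weight calibration.** The normalising weight is nominally "the
player's weight", but a live total fluctuates with movement and dropout.
`estimate_weight()` therefore uses the median per-frame total over
frames where the player stands centred (both provisional com components
within 0.1), after discarding frames whose total falls below 20% of a
running median (k = 21 samples, about one second) — the sensor-dropout
floor. The centred-frame restriction needs a provisional com, which is
computed with the post-dropout global median; if no centred frame
exists, that global median is the answer. This two-pass scheme is robust
to transient dips without assuming any particular stance schedule.

## 2. Intentions and the step state machine

A com sample is classified Up/Down/Left/Right when its main axis is
$\ge 0.5$ in magnitude and the other axis $\le 0.1$; Center when both are
$\le 0.1$; otherwise Undetermined. Thresholds are **inclusive** — the
rule is stated with "equal to or greater/lesser than" — and the six
labels partition the plane, so each sample gets exactly one label. Both
constants are arguments (`main`, `off`) everywhere they appear.

Step detection is an explicitly armed state machine: starting armed, the
first direction-labelled sample while armed emits a step and disarms;
only a Center sample re-arms; Undetermined samples are inert (they
neither emit nor re-arm — they are the transition samples between centre
and pose). Two open conventions were fixed as follows:

* **Registration time** is the *first* sample of the qualifying run, not
  its midpoint — deterministic, and what an online game controller would
  do.
* **Dwell**: whether the original game required a pose to persist before
  registering is unknown; `dwell` defaults to 1 sample (immediate
  registration) and is configurable. With dwell > 1 the event is still
  stamped at the run's first sample.

Directional sample masks (`direction_masks()`) use the same inclusive
conditions but ignore the state machine: the mask size $n_{COM,Dir}$ is
the count of samples *satisfying the direction condition*, which is the
only reading consistent with the per-sample summation bounds of the
directional feature definitions (a per-step reading would make those
sums ill-defined).

## 3. Instability factor

$$if(t) = \sqrt{\tfrac12\,(\Delta \mathrm{com}_x)^2 +
                \tfrac12\,(\Delta \mathrm{com}_y)^2}, \qquad if(0) = 0,$$

a per-sample displacement (an RMS of the component deltas), with rolling
sum $if_{sum}(t) = \sum_{u=t-24}^{t} if(u)$ over the last 25 samples
(1.25 s), **truncated** — not NaN-padded — at the series start, so early
samples carry partial sums. $if$ is not rescaled by the 20 Hz interval:
the conventional exceedance thresholds (0.5, 1, 1.5, 2) are in
per-sample units, and rescaling would silently move them.

## 4. The 42-feature vector

Per playthrough (one level, no windowing): 8 directional com means + 8
SDs, 4 balance asymmetries, 8 global com statistics, 12 instability
summaries, 2 step-timing summaries (`feature_names()` fixes the order).
Conventions where the printed feature table is ambiguous or degenerate:

* **Denominators.** Directional and balance averages divide by the count
  of *qualifying* samples — the only reading that matches their stated
  semantics ("average value … for all values where …"). `step_avg`
  divides the interval sum by the number of intervals
  ($n_{steps} - 1$): the telescoped alternative reduces to
  $(t_{last} - t_{first}) / n_{steps}$, which is not an average interval.
  A `table1_literal` switch restores the literal total-count
  denominators for comparability experiments.
* **Min/max.** The y-axis minimum is a minimum (the printed table
  repeats the max formula in its min row; an evident typographical slip).
* **`if_sum_over` normalisation** divides by the sample count $n_{COM}$
  (the printed formula) rather than playthrough seconds (the prose);
  at 20 Hz the two differ by a factor of 20. A separate `ifsum_time_norm`
  flag selects time normalisation; `table1_literal` deliberately does not
  touch it.
* **Missingness.** Empty direction masks and playthroughs with fewer
  than two steps produce explicit `NA`s (not zeros), counted in QC.
  Classification mean-imputes them per cross-validation training fold.
  With exactly one interval, `step_std` is 0 with a QC flag.
* Sample standard deviations use the $n-1$ denominator throughout; a
  single qualifying sample yields SD 0.

All standard deviations, means and extrema are deterministic; permuting
frames leaves the global and balance features unchanged but alters the
instability and step features (tested as a property, since it documents
which features are order-sensitive).

## 5. Log format

Each level's recording is one XML file: player block (id, weight,
optional age/sex), level block, a `samples` block with `t`, `x`, `y`,
`if` per 20 Hz sample, and optional `raw` (24 loads per frame) and
`steps` blocks. The original exergame's file layout is unpublished; this
schema (bundled XSD) is a reconstruction of the stated content, and is
flagged as such. Numbers are serialised at six decimals — enough that a
read-write-read cycle is byte-stable. Ingestion distinguishes malformed
XML, schema violations and *data failures* (gapped or truncated sample
blocks, raw frames that no longer reproduce the stored com within
$10^{-6}$) by condition class, so batch ingestion can count discards the
way a field deployment must. Stored `if` values are trusted on read;
`recompute = TRUE` re-derives them and warns above $10^{-4}$ deviation.

## 6. The synthetic cohort generator

`simulate_com_trajectory()` emulates the movement grammar the game
enforces: centre dwell with Gaussian sway → smoothstep ramp onto a
directional pose (main axis 0.8, off-axis jitter sd capped at 0.03 —
comfortably past the 0.5 threshold and inside the 0.1 tolerance, matching
the worked poses (0.1, 0.9) and (−0.8, 0.05)) → hold → ramp back.
Inter-step intervals are Normal, truncated below at feasibility; a step
cycle is ramp-out + hold + ramp-in + dwell, so the mean interval must
exceed $2\,T_{ramp} + T_{hold} + 0.25$ s (the 0.25 s floor keeps at
least a few genuine centre samples between steps, which the state
machine needs to re-arm). `decompose_to_sensors()` inverts the fusion:
the containing board gets the full weight with exact bilinear corner
weights (zero-noise round-trip through `compute_com()` is exact to
machine precision), then truncated-at-zero Gaussian noise is added
per channel *without* renormalising — the resulting total-load bias and
jitter are precisely the realism the weight estimator has to absorb.

The two stock archetypes encode the behavioural contrast the screening
rule exploits — mean inter-step interval 4 s (fit) vs 8 s (not fit),
straddling the 6.17 s decision threshold, with the not-fit archetype
also given slower ramps (0.8 s vs 0.5 s), doubled sway (0.06 vs 0.03 com
units) and doubled sensor noise (4 vs 2 load units on a 700-unit
weight). Interval SDs (0.75 s / 1.5 s) keep the groups separable but
overlapping in individual intervals. Default playthrough lengths
(20 / 15 steps ≈ 1.5–2 minutes) match typical level durations. These
values were chosen once, as a realistic encoding of the stated
conditions, and are not tuned.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: biomechanically realistic force
waveforms within a step (weight transfer between feet, heel-strike
transients), fatigue and learning across levels, repeated measures per
participant (each simulated playthrough is independent), genuinely
abrupt balance-loss events, or age/sex structure. Synthetic archetypes
separate far more cleanly than real participants: cross-validated
accuracies near 100% and very large effect sizes on simulated cohorts
are properties of the generator's contrast, not predictions of clinical
performance. The published 91.4% accuracy arose on 81 real instances
from 16 participants; this package reproduces that result's *arithmetic*
(from its confusion matrix) and the pipeline's behaviour, not the
participant data.

## 7. Labelling and evaluation

The 30CST label rule is `fit` iff score > cutoff (default 12). A score
exactly at the cutoff cannot be resolved from the published description
(groups of 8/8 participants but 34/47 instances); we label it `not_fit`
and expose `boundary_fit` to flip the convention. Age/sex-adjusted
cutoffs are supported via a user-supplied lookup table.

The positive class is `not_fit` — screening convention: the group the
screen exists to find. Weighted metric rows weight each class's metric
by its true-class count (the only weighting that reproduces the
published weighted row), which also makes the weighted TP rate equal the
accuracy identically (a tested invariant). Zero denominators yield 0
with a QC flag rather than NaN. ROC/PRC areas are only meaningful for
scoring classifiers; threshold rules produce degenerate one-point curves,
so no area is fabricated for them.

Information gain uses a supervised binary split (exhaustive midpoint
search minimising conditional entropy, base-2), with missing values in
their own bin so informative missingness is credited; whether the
original attribute ranking used multi-way MDL discretisation is unknown,
so the single split is the default and the discretiser is pluggable in
principle. Hedges' g uses the pooled SD weighted by $n-1$ and the
small-sample correction $J = 1 - 3/(4\,df - 1)$, signed not-fit minus
fit; significance is a two-sided Welch t-test (Satterthwaite df), chosen
for the groups' unequal variances. Raw p-values are reported without
multiplicity adjustment, matching the original analysis.

**Classifiers.** Bit-exact replication of the original Logistic Model
Tree induction is out of scope; the published best model reduced to a
single `step_avg` threshold anyway. The suite brackets that behaviour with: an
information-gain decision stump, a CART tree (rpart), plain logistic
regression, and an LMT-like model (info-gain root split with a logistic
model per branch, falling back to branch majority when a branch is pure
or smaller than 8). Cross-validation is stratified k-fold (default 10)
with per-fold mean imputation fitted on training data only; the pooled
held-out confusion matrix is reported, and fold-wise stump
features/thresholds are exposed so threshold recovery can be inspected.

## 8. Problem sizes and numerical tolerances

The test suite and acceptance script run entirely on synthetic data:
1 000 random frames for the fusion oracle, 20 random playthroughs for
the feature-extraction oracle, a 40 + 40 cohort (20/15 steps per
playthrough) for parameter-recovery and cross-validation checks, and 87
short logs (2 steps each) for ingestion accounting — sizes chosen to
exercise every code path at desk scale. Agreement tolerances: $10^{-12}$
relative for linear-algebra oracles (fusion, rolling sums, metric
arithmetic), $10^{-9}$ for the bilinear round-trip, $10^{-10}$ for the
42-feature brute-force oracle, $5\times10^{-7}$ for six-decimal log
serialisation. Stochastic recovery checks use two standard errors of the
estimated quantity under a fixed seed.

## 9. Known limitations

* The default board geometry is an informed reconstruction; analyses of
  real recordings must supply the actual layout file.
* The com projection is a centre-of-pressure proxy; fast movements
  violate the quasi-static assumption (mild at this population's speeds).
* The LMT-like classifier is a structural analogue, not a re-derivation
  of the original induction algorithm.
* Effect sizes and attribute rankings on synthetic cohorts reflect the
  generator's assumptions; only their *machinery* (not their values)
  transfers to real data.
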