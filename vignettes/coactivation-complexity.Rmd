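---
title: "Multi-scale complexity of muscle coactivation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale complexity of muscle coactivation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During walking, groups of lower-limb muscles activate together in
phase-locked patterns. Neurological conditions such as cerebral palsy alter
not only *how much* individual muscles activate but *how they coordinate*:
spasticity and over-activation can abnormally synchronize a muscle group,
while paresis can silence a muscle's contribution and break couplings. This
package quantifies that coordination as the *dynamical complexity of joint
muscle activity across time scales*: multichannel surface EMG is decomposed
into scale-aligned oscillatory modes, and a multivariate entropy is tracked
as fine scales are successively removed.

The pipeline has five stages, each usable on its own:

1. **Gait segmentation** (`detect_acc_peaks()`, `build_gait_cycles()`):
   heel strikes are located as peaks in the gravity-axis accelerometer of
   each leg; one gait cycle of a leg spans two consecutive ipsilateral
   strikes, with the stance phase ending at the intervening contralateral
   strike and the swing phase covering the remainder.
2. **MEMD** (`memd()`): multivariate empirical mode decomposition of all EMG
   channels jointly, with white-noise assistance (`add_noise_channels()`),
   producing the same number of intrinsic mode functions (IMFs) per channel.
3. **Cumulative scales** (`cumulative_scales()`): scale *n* is the sum of
   modes *n* through the last, residual included — the signal with its
   finest *n − 1* modes removed.
4. **MSampEn / MMSE** (`msampen()`, `mmse_curve()`): multivariate sample
   entropy of each cumulative scale, giving one complexity value per scale —
   the MMSE curve.
5. **Schemes, aggregation and statistics** (`enumerate_schemes()`,
   `run_analysis()`, `rm_anova()`, `posthoc_bonferroni()`): 14 muscle/side/
   phase configurations, cycle → subject → group curve aggregation, and a
   two-way repeated-measures ANOVA (scale within subjects, group between)
   with Bonferroni post-hoc comparisons.

## MEMD: model and numerical choices

A multichannel signal $\mathbf v(t)$ is decomposed as
$\mathbf v(t) = \sum_{i=1}^{N} \mathbf c_i(t) + \mathbf r(t)$, where each IMF
$\mathbf c_i$ is extracted by *sifting*: subtract the local mean of the
current detail until a stoppage criterion declares it an IMF. For
multivariate data the local mean cannot come from upper/lower envelopes, so
it is estimated by projecting the signal along $K$ directions on the unit
hypersphere, interpolating the multichannel samples at each projection's
maxima with a cubic spline, and averaging the $K$ directional envelopes.

Design choices (all configurable):

* **Direction count** $K = 64$. Standard MEMD practice: enough directions
  for a stable envelope mean at 16–22 channels without prohibitive cost.
* **Direction placement**: a Hammersley low-discrepancy point set mapped
  area-uniformly onto the hypersphere via the recursive marginal
  inverse-CDF (Beta quantile) angular parameterization. Deterministic for a
  fixed `(n_dim, count)` and measurably more even than random directions
  (the test suite compares nearest-neighbour spacing CVs against a
  Monte-Carlo random baseline).
* **Stoppage criterion**: normalized sift difference
  $\sum_t \lVert \mathbf m(t)\rVert^2 / \sum_t \lVert \mathbf d(t)\rVert^2 < 0.2$
  with a hard cap of 15 sifting iterations per mode. The cap guarantees
  termination; for broadband EMG the criterion typically stops sifting
  earlier.
* **Extrema**: strict local maxima of each projection; plateaus contribute
  their midpoint. Before spline fitting, two extrema are mirror-reflected at
  each end of the record to suppress end swings. Natural cubic splines are
  used (second derivative zero at the extended ends).
* **Monotonic residual**: when no projection has at least 3 maxima the
  remainder is declared the residual and decomposition stops.
* **Mode truncation**: `max_modes = 6`, with the residual kept as the 7th,
  coarsest analysis scale. In broadband EMG virtually all signal energy sits
  in the first handful of modes, so analysis beyond scale 7 adds computation
  without information; all group analyses here use 7 scales.
* **Noise assistance**: 6 independent Gaussian white-noise channels are
  appended before decomposition (16 EMG channels → a 22-channel composite)
  and stripped afterwards. Broadband noise populates every mode and
  stabilizes mode alignment against mode mixing. The noise amplitude equals
  the mean SD of the EMG channels so the noise carries comparable energy —
  a deliberate choice where unit-variance noise would under- or over-weight
  the assistance depending on EMG units.
* **Decomposition granularity**: by default (`mode = "concat"`) the
  contiguous analysis span of every subject (first retained cycle start to
  last retained cycle end) is concatenated and decomposed in a single MEMD
  run, which guarantees scale alignment across cycles, muscles *and*
  subjects; per-cycle segments are sliced from the aligned scales
  afterwards. `mode = "per_subject"` decomposes each subject separately,
  which is cheaper and keeps subjects independent, at the cost of
  between-subject alignment. Concatenating full spans (rather than glueing
  per-cycle snippets) keeps both legs' interleaved cycles sliceable from one
  decomposition.

The only randomness in the decomposition stage is the noise augmentation,
which is seeded; everything else is deterministic.

## MSampEn and the MMSE curve

For an $N \times n$ segment with per-channel embedding dimensions
$M = [m_1,\dots,m_n]$ and lags $\tau$, composite delay vectors concatenate
the lagged samples channel by channel, giving $N - \delta$ vectors of total
dimension $m = \sum_k m_k$, where $\delta = \max M \cdot \max\tau$. With
Chebyshev distance and tolerance $r$, $B^m(r)$ is the average fraction of
vector pairs within $r$ (self-matches excluded, ties count as matches:
$d \le r$). The embedding is then extended by one element in each channel in
turn — $n(N-\delta)$ candidate vectors of dimension $m+1$; every extension
index $i + m_k\tau_k$ is within the record because
$m_k \tau_k \le \delta$, so no boundary cases arise — and $B^{m+1}(r)$ is
computed over that candidate set. Then

$$\mathrm{MSampEn}(M, \tau, r, N) = -\ln\frac{B^{m+1}(r)}{B^m(r)}.$$

Defaults are $m_k = 2$, $\tau_k = 1$ and $r = 0.2 \times \sum_k
\mathrm{SD}_k$, the sum running over the **raw** (pre-decomposition) channels
entering the computation. Channels are deliberately *not* normalized before
embedding — the tolerance convention sums raw SDs, which presumes
unnormalized amplitudes. The tolerance is computed once per analyzed raw
segment (the cycle or phase slice) and reused for every cumulative scale of
that segment, so scales are compared under one yardstick.

Degenerate segments where $B^m$ or $B^{m+1}$ is zero yield a *flagged
undefined* value, not a number; curve aggregation averages pairwise over the
defined values and records how many cycles contributed per scale.

One subtlety of the multivariate formulation is worth stating: unlike the
univariate case, $B^{m+1} \le B^m$ is **not** guaranteed. The extended
candidate set contains same-origin pairs (the same origin index extended in
two different channels) whose shared base distance is zero, so when base
matches are extremely rare those pairs can push $B^{m+1}$ above $B^m$ and
MSampEn below zero. This is a property of the published counting procedure
itself — an exhaustive enumeration oracle reproduces it bit for bit — and it
only occurs far outside the analysis regime (it needs $B^m$ of order
$1/(nN)$; the summed-SD tolerance on cycle-length segments keeps $B^m$
orders of magnitude larger). The package reports whatever the formula
yields rather than clamping.

The match counting is exact: an $(m+1)$-dimensional pair matches iff its
shared $m$-dimensional base pair matches and the two extension elements
differ by at most $r$. The implementation exploits that identity to switch
between direct accumulation (rare base matches) and a sorted two-pointer
count with subtraction (dominant base matches), and short-circuits scales
where every embedded column's global range is within $r$. All routes count
exactly the same pairs as the naive double loop, which the test suite
verifies to the last integer on random segments.

## The 14 analysis schemes and aggregation

`enumerate_schemes()` builds the 14 configurations: 2 full-cycle all-8
schemes (strategy 1), then 4 schemes each for all-8, lower-leg-3
(TA, SO, LG) and thigh-5 (VL, RF, SE, BF, TF) muscle sets over
stance/swing × left/right (strategies 2–4), ordered deterministically by
(strategy, side, segment). Full-cycle schemes use the ipsilateral leg's
cycle definition. Per scheme, each cycle's raw slice and scale slices feed
`mmse_curve()`; cycle curves average into a subject curve, and group curves
report the per-scale mean and SD over subjects.

## Group statistics

`rm_anova()` fits the standard two-way mixed design — scale (7 levels)
within subjects, group between — via a multivariate linear model with a
repeated-measures design (delegated to `car::Anova`), reporting F, df and p
for group, scale and their interaction. Because sphericity rarely holds for
7 ordered scales, the Greenhouse–Geisser epsilon and adjusted p are reported
alongside the uncorrected within-subject tests; readers can use either.
Subjects with any flagged scale are excluded listwise (classic
repeated-measures requirement), and the exclusion count is kept in the
result. When an effect's sum of squares is exactly zero (e.g. literally
identical curves in every group) its F is reported as 0 with p = 1 rather
than 0/0. Post-hoc pairwise group comparisons use Welch t tests with the
Bonferroni multiplier capped at 1.

## The synthetic generator: what it emulates, and what it does not

No public recordings accompany this analysis problem, so the package ships a
fully seeded generator (`generate_subject()`, `make_cohort()`) that emulates
the *statistical structure the analysis assumes*:

* 16 EMG channels at 1 kHz (8 muscles per leg) and two single-axis
  accelerometer traces at 100 Hz;
* per muscle, a smooth activation envelope — tonic baseline 0.25 plus a
  Hann burst over a textbook activation window (e.g. TA around swing and
  heel strike, SO/LG in late stance, quadriceps in early stance) —
  multiplying a 20–450 Hz band-limited Gaussian carrier (the canonical
  surface-EMG bandwidth at 1 kHz sampling);
* cross-muscle coupling: carriers of a named muscle subset mix a per-leg
  shared drive with weight $\sqrt\rho$, making their pairwise correlation
  equal $\rho$;
* carriers are soft-limited at 3.5 carrier SDs (tanh), emulating the finite
  dynamic range of a recording front-end; this also bounds the peak-to-SD
  ratio of clean cycles below the amplitude-artifact screen's default
  threshold of 8, as clean recordings should be;
* legs alternate half a cycle out of phase; cycle durations are
  1.1 s ± 0.05 s (self-selected child cadence), 12 cycles by default;
* accelerometers carry a Gaussian bump (SD 30 ms) at each heel strike plus
  noise, so strikes are recoverable to ±1–2 samples.

Group presets mirror two impairment mechanisms: `"spastic"` raises the
shared-drive weight across the thigh muscles ($\rho = 0.85$) and widens
their stance-phase windows (over-activation/synchronization); `"paretic"`
attenuates lower-leg amplitudes (× 0.3) and decouples those muscles (reduced
motor output, loss of couplings). Whether these knobs reproduce the
*direction* of group differences seen in clinical cohorts is an empirical
calibration question and is deliberately not asserted by any test; the
generator's contract is structural (phase locking, coupling monotonicity,
strike recoverability).

What the generator does **not** model: motor-unit physiology, amplitude
non-stationarity across cycles beyond cadence jitter, electrode artifacts,
crosstalk between adjacent channels, or kinematics. Passing tests therefore
demonstrate that the pipeline measures what it claims on signals with known
structure — not that any clinical effect size is reproduced.

All randomness flows from one master seed: `make_cohort()` draws per-subject
seeds once from the master-seeded stream, and each subject's signals are
generated under `withr`-style local RNG state, so cohorts are
bit-reproducible and independent of call order.

## Problem sizes and degenerate inputs

The shipped checks run at desk scale, chosen once as the package's own
study conditions: the end-to-end pipeline check uses 2 subjects × 6 gait
cycles (about 25 k concatenated samples through a 22-channel MEMD);
stochastic properties use 50 seeds (MMSE decreasing trend on 4-channel
broadband noise, N = 2500; gait-cycle recovery over 50 simulated subjects);
ANOVA calibration uses 200 null and 100 offset replicates at n = 8 per
group. Larger cohorts scale linearly in samples for MEMD and quadratically
in segment length for MSampEn.

Degenerate inputs are handled explicitly rather than silently: constant
signals have no projection maxima (monotonic residual), constant channels
give $r = 0$ with a warning, zero-match segments flag the scale as
undefined, singleton groups flag the SD, and subjects with flagged scales
are excluded listwise from the ANOVA with a recorded count.

## Known limitations

* The IMF count of a decomposition is data-length dependent; analyses fix
  the scale count by truncation (6 modes + residual), not by asserting any
  particular total count.
* The automated amplitude screen is a stand-in for visual artifact
  inspection; it cannot reproduce human judgments on clinical data.
* `"concat"` mode couples subjects through one decomposition — that is its
  purpose (shared scales) — so adding a subject changes everyone's scales
  slightly; use `"per_subject"` when independence matters more than
  alignment.
* MSampEn values depend strongly on the channel count through the summed-SD
  tolerance; curves are comparable within a scheme, not across muscle sets
  of different sizes.
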