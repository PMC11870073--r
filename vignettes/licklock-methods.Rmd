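---
title: "Models and methods behind licklock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind licklock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`licklock` analyses paired spike/behaviour event tables from Purkinje-cell
recordings in rhythmically licking mice. This vignette documents the models
the package implements, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic-data
validation does and does not demonstrate about real recordings.

## Event model and conventions

All times are seconds from session start; coordinates are millimetres, with
x positive toward the animal's right (ipsiversive for right-hemisphere
recordings; `flip_x` flags flip the convention for left-hemisphere data) and
y positive in the protrusion direction. A *bout* is a maximal run of licks
whose inter-lick intervals are all strictly below 0.5 s; a gap of exactly
0.5 s splits bouts (the inclusion rule is "intervals < 500 ms", read
literally). Bouts of a single lick are permitted and participate in
bout-transition analyses; nothing in the data model forbids them, and
excluding them would silently change bout counts. When maximal-protrusion
times are not recorded they are derived as detection + 16 ms, the average
optical-sensor-to-apex delay measured with video tracking.

A recording qualifies as a single Purkinje cell only if every complex spike
is followed by at least 8 ms without simple spikes and at least 20
analysable trials are available; `validate_cell()` reports violations
rather than raising, so inclusion decisions stay visible.

## PSTHs and Z-scores

PSTHs use 10 ms bins, pooled over alignment events; alignment events whose
window would cross the session edge are dropped whole rather than corrected
per bin, which keeps every bin an average over the same number of events.
`Z = (value − baseline mean)/baseline SD` with three baseline conventions,
each tied to an alignment type: −1000..−500 ms before bout starts,
+500..+1000 ms after bout ends, and −1000..−250 ms before licks of
interest. No floor is applied to the baseline SD: a zero-SD baseline marks
the Z undefined and the cell is excluded from significance counts, because
a floor would silently deflate Z values exactly where the data are too
sparse to support them.

For per-lick rhythmic modulation the baselines above leave one open choice:
none of them is anchored to ordinary mid-bout licks. `lick_modulation()`
aligns on bout-start licks, the only licks whose −1000..−250 ms baseline
window is guaranteed bout-free, and `all_licks = TRUE` exposes the
alternative.

### Significance of sparse complex-spike responses

The detection rule for bout-transition and movement-locked complex-spike
responses deserves its own paragraph. Complex spikes fire at ~1 Hz, so a
10 ms PSTH bin holds a count with mean well below one even after a hundred
alignments. The maximum of thirty such skewed Poisson bins, divided by a
baseline SD estimated from fifty equally sparse bins, exceeds 3 in 15–30%
of *unmodulated* cells — a peak-bin `Z > 3` rule is not a 3-sigma test at
these rates, and no realistic session length fixes it (the skew shrinks
only as counts approach normality). The package therefore tests the firing
increase *over the interval*: `window_mean_z()` compares the mean window
rate with the baseline mean on the scale of the standard error of a mean of
n bins. Under the null this statistic is close to standard normal and the
false-positive rate stays well below 5%, while a transition bump of a few
times the base rate is detected essentially always. The peak-bin Z is still
computed and reported (`peak_z`) as the response *amplitude* — peaks are
what one plots and correlates across conditions — but significance comes
from the interval statistic. The 300 ms analysis interval is taken as
±150 ms around the detection of the first (or last) lick of the bout.

## Phase transform and coherence

Each lick cycle maps linearly onto phase with three anchors: protrusion
start (0), maximal protrusion (π), end of retraction (2π). Sensor-only
sessions record only the detection (and derived apex) times, so protrusion
start and retraction end are placed at the temporal midpoints between
neighbouring apices within a bout, with bout-edge cycles extended by the
bout's mean half-cycle. This construction is symmetric, parameter-free and
honours the anchors exactly: the apex always maps to π regardless of lick
jitter (a property the tests check on random inputs). Licks in single-lick
bouts define no cycle and are masked.

Coherence between spiking and licking is computed on the warped axis
(units of lick cycles), where every lick event sits exactly one cycle
apart — warping is what "annihilates" inter-lick timing differences.
On that axis the package builds the spike–lick cross-correlogram and the
lick autocorrelogram (±2 cycles, 0.02-cycle bins, pairs restricted to the
same bout). Two estimation details matter:

- **Envelope normalization.** A finite correlogram window over
  finite-length bouts yields a triangular pair-availability envelope; raw
  counts would carry that envelope's spectral leakage into the fundamental
  and bias the null. Each correlogram is divided by its availability
  envelope (computed by counting, per lick, which lags stay inside the
  bout), so an unmodulated train gives a flat normalized correlogram.
- **Block averaging.** The magnitude-squared coherence of two single
  whole-length spectra is identically 1, so some averaging is unavoidable.
  Rather than Welch-segmenting an axis only four cycles long, bouts are
  assigned round-robin to 8 blocks; each block contributes one correlogram
  pair, and cross- and auto-spectra are averaged over blocks before msc and
  the cross-spectrum phase are read at 1 cycle⁻¹. Under the null the
  expected msc is ≈ 1/8 and `msc > 0.5` occurs in well under 10% of cells;
  a strongly locked cell reaches msc ≈ 1. Cells with fewer than 100
  in-bout spikes, or sessions with fewer bouts than blocks, are flagged
  low-power and not classified.

The preferred phase is recovered from the cross-spectrum phase at the
fundamental, translated into the anchor convention (a spike comb at the
apex has lag 0 relative to lick events and preferred phase π). The
threshold is strict: msc exactly 0.5 is not coherent.

Autocorrelogram power inside versus outside bouts uses real-time (±2 s,
10 ms bins) autocorrelograms of epoch-restricted spikes, normalized to
conditional rate, mean-removed, Hann-tapered. Power is read at the
preferred lick frequency (spectral peak of the lick autocorrelogram in
3–12 Hz) and reported *relative to the mean power in 0.5–25 Hz*, making
epochs of different lengths and rates comparable; only orderings and ratios
of these relative powers are meaningful, and the package asserts nothing
about their absolute scale.

## Endpoint kinematics

The rosette divides each session's endpoint distribution into tertiles per
axis using that session's empirical 1/3 and 2/3 quantiles (type-7
interpolation), which adapts the analysis to each animal's idiosyncratic
bias; values equal to an edge go to the upper tertile so that assignment is
deterministic and order-independent. Per lick, SS rates in the early
(−150..−75 ms) and late (−75..0 ms) pre-apex windows are Z-scored against
the across-lick distribution of per-lick baseline rates (−1000..−250 ms
before detection) and then averaged per zone — per-lick-then-average, the
variant that keeps per-lick values available for paired population tests;
baseline windows overlapping earlier licks of the bout are allowed, as
excluding them would empty mid-bout zones.

## Decoder

Sessions are tiled from t = 0 into 200 ms windows sharing 10 ms
(stride 190 ms). A window is labelled *lick* iff at least one detection
falls inside it. Features: SS rate, CS rate, and mean CV2, where each CV2
value (one per adjacent ISI pair) belongs to the window containing the
middle spike of its pair. Windows with fewer than three simple spikes have
undefined CV2; it is imputed with the cell's median CV2 within the same
label class and flagged (`impute = FALSE` drops them instead). Imputation
keeps the class balance intact; the flag makes sensitivity analyses easy.

Training sets are balanced by drawing ⌊2/3 · min(n₁, n₀)⌋ windows from
each class; everything else is test data, keeping the natural imbalance
where accuracy is measured per class. The classifier is XGBoost
(`binary:logistic`, histogram split finding, depth 8, 4096 trees by
default, no early stopping, single thread for reproducibility); attribution
is the mean absolute TreeSHAP contribution per feature over test windows.
Predictivity is a pure threshold function of the two per-class accuracies
(> 55% both: predictive; > 65% both: strongly predictive; boundary values
do not qualify). One seed governs split and fit and is recorded in the
report. Validation uses 256 trees — the behaviour class of the ensemble is
unchanged and the suite asserts classification outcomes, never accuracy
values tied to the ensemble size.

## Perturbation and optogenetic trials

The closed-loop protocol: a randomly selected lick (p = 0.5) triggers a
3 mm rightward port movement starting 40 ms after detection (travel 50 ms);
the port returns after 750 ms and stays centred for at least another
750 ms. Returns are analysed as centreward movements with the same
machinery. Lick k (k = 1..3) after an event is the k-th detection before
the next event; trials truncated earlier keep only the available indices.
Baseline licks stay at least 300 ms clear of every trial's 1.5 s span.

Coordinates are normalized per trial to the mean endpoint of pre-movement
reference licks. References are the licks in the 750 ms before the event —
the span during which the port provably held its previous position — with
one refinement: references still settling from an *earlier* movement
(within 750 ms after any previous event) are excluded when settled ones
exist. Without this filter, licks adapting back from the preceding return
occasionally leak into the reference set and bias recovered displacements
by ~0.1 mm, which the ground-truth recovery tests expose. Normalization is
idempotent: coordinates already expressed relative to the pre-movement
position are unchanged.

CS movement responses use the 500 ms pre-bout-start baseline and the
interval statistic described above over 0..300 ms after the event (the
window in which responses precede the next apex); selectivity is
`peak_z(rightward) − peak_z(centreward)`. SS adaptation peaks reuse the
late kinematic window (−75..0 ms before the apex) with the 750 ms per-lick
baseline; population comparisons across lick indices go through standard
paired Wilcoxon tests with Benjamini–Hochberg correction
(`compare_direction_peaks()` merely assembles the table).

Optogenetic effects are estimated as group-mean differences (stimulated
minus control) of endpoint coordinates per lick index, pulse timing and
fibre; controls are licks whose following three licks are unstimulated.

## The synthetic-data generator

`generate_session()` is first-class, tested code, not a fixture. Its
defaults define the simulated study conditions:

- Licking: intra-bout intervals Gamma with mean 160 ms (6.25 Hz) and CV
  0.1; bout sizes geometric with mean 8; inter-bout gaps 0.5 s plus an
  exponential with mean 1.5 s; endpoints Gaussian with SD 0.5 mm (x) and
  0.7 mm (y) around a 4.2 mm protrusion; apex at detection + 16 ms.
- Simple spikes: inhomogeneous Poisson by thinning under an exact constant
  envelope, rate `r(t) = base · exp(κ cos(φ(t) − φ*))/I₀(κ)` inside lick
  cycles and `base` outside bouts (no rhythm without licking, matching the
  in/out-of-bout power contrast the analysis is meant to detect);
  optional in-bout gain and endpoint coupling (`1 + g·x` per cycle).
  κ is capped at 20 as a rate-overflow guard.
- Complex spikes: sparse Poisson (1 Hz) with multiplicative bumps
  (duration 0.3 s) at bout transitions and after port movements, and
  optional von Mises phase locking. After each CS, simple spikes within
  `cs_pause` (≥ 8 ms) are deleted post hoc — deletion, not rate
  modulation, makes the pause guarantee exact.
- Adaptation: after each port position change the k-th following lick aims
  at `old + gain_k · (new − old)` with gains (0.5, 1, 1), and any lick more
  than 750 ms after the change aims at the new position — partial
  adaptation does not persist across pauses. Optogenetic pulses bend the
  next lick by ±0.5 mm toward the stimulated side and shorten it by
  0.3 mm.

No quantitative coupling strengths are published for these cells, so the
reference effect sizes (κ = 4 for strong locking, gain 5 — a six-fold rate
bump — for CS responses, in-bout gain 1 for decodable cells) were chosen
once to produce effects comparable in magnitude to real recordings and are
exposed as configuration, never asserted as facts about the biology.

One session seed is split into independent substreams (behaviour, port
schedule, opto schedule, one per cell) drawn as a sequential sample, so the
first k substreams are invariant to how many are requested: adding a cell
never perturbs the behaviour stream. Candidate event times are
de-duplicated because R's RNG has ~2⁻³² granularity, which produces exact
ties at realistic spike counts.

### What the validation shows — and what it does not

Every analysis stage is validated two ways: exact equivalence with naive
brute-force reimplementations on random inputs (bout scan, per-alignment
histograms, window features, trial-lick indexing, 2×2 grid means), and
parameter recovery against the generator's ground truth (phase and
coherence, bout-start detection with a zero-gain false-positive control,
decoder calibration with permutation nulls, follow-gain and opto-effect
recovery within sampling CIs). Typical validation problem sizes are 300–700
s sessions, 20–40 seeds per calibration, and 10³ random instances per
oracle, which keeps the whole suite within a few minutes.

The generator emulates the statistical structure of the recordings, not
their biophysics: no electrode drift, no sorting errors, no slow rate
nonstationarities, no correlated noise across simultaneously recorded
cells, no tongue-trajectory dynamics beyond the endpoint, and conditionally
independent SS/CS streams given the behaviour (except for the enforced
pause). Passing recovery tests therefore demonstrates that the estimators
are correct and calibrated under the stated model — not that real data
satisfy that model. On real sessions the flags that matter are the ones the
package reports: validity failures, zero-SD baselines, low-power coherence,
degenerate decoder features and excluded trials.

## Numerical choices and limitations

- Window membership is half-open (`[lo, hi)`) everywhere; ties at tertile
  edges go to the upper zone; a gap of exactly 0.5 s splits bouts; msc of
  exactly 0.5 and accuracies of exactly 55/65% do not qualify.
- Session files store times at 1 µs and coordinates at 1 µm; within-stream
  ties created by quantisation are nudged by 1 µs so the strictly
  increasing invariant survives a round trip.
- Coherence defaults (±2-cycle window, 0.02-cycle bins, 8 blocks) and the
  correlogram parameters are configuration, not science; the estimator's
  calibration under the null is what the tests pin down.
- `run_pipeline()` is deterministic given its configuration, including the
  seed; summaries contain no timestamps.
- Population-level hypothesis testing beyond assembling per-cell values is
  out of scope; standard routines (`wilcox.test`, `p.adjust`, `ks.test`)
  are called where needed, never re-derived.
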