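---
title: "Models and methods behind contraplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind contraplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contraplast)
```

`contraplast` quantifies how contralesional cortical neurons adapt after a
unilateral traumatic brain injury: turnover and persistence of their
dendritic spines, changes in their spontaneous calcium activity, and the
reorganisation of their monosynaptic input maps. This vignette describes the
models and conventions the package commits to, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the package's
known limitations.

## Spine dynamics

### Data model

The unit of observation is a *spine-session*: a long-format table with one
row per (dendrite, spine, session) holding a binary presence flag and an
optional morphology label (mushroom / thin / stubby). Sessions are opaque
ordered labels supplied by configuration — never sorted lexically — so both
regular 3-day schedules (B1, B2, 3d, 6d, …) and irregular ones are
representable. Rows start at a spine's first observed session; earlier
sessions are treated as absent.

### Transition statistics

For each consecutive session pair t−1 → t, per dendrite:

- *stable*: present at both sessions;
- *eliminated*: present at t−1, absent at t;
- *formed*: absent at t−1, present at t.

Two conservation identities hold by construction and are asserted on every
simulated table: `stable + eliminated = N(t−1)` and
`stable + formed = N(t)`. Elimination and formation **rates** divide the
respective counts by the *previous* session's total and multiply by 100.
Pairs with `N(t−1) = 0` yield explicit `NA` markers — degenerate dendrites
are excluded from aggregation with a reported exclusion count, never
silently zeroed. Spine **density** is presence count over dendrite length
(spines/µm); lengths are measured once at baseline and carried per dendrite.

A spine whose identifier disappears and later reappears is counted as an
elimination followed by a new formation. Identity reuse of a `spine_id` is
how a table encodes same-location reappearance; the package cannot (and does
not try to) verify spatial location.

### Persistence index

Each spine's presence history is a binary code over the ordered sessions.
Spines present at **every** baseline session are *pre-existing*; spines
absent at all baselines whose first presence follows the last baseline are
*newly formed*. Spines present at some but not all baselines fit neither
class and are reported as `ambiguous_baseline` with an `NA` index, so they
are visible rather than silently absorbed.

Two denominator conventions are implemented because the choice is genuinely
open:

- `post_baseline` (default): a pre-existing spine's index averages its code
  over the post-baseline sessions; a newly formed spine's over sessions
  strictly after its birth. Rationale: the baselines *define*
  pre-existence, they cannot also test persistence, and a newly formed
  spine is trivially present at its own birth session. This makes the two
  classes comparable survival fractions on [0, 1]. A spine born at the
  final session has an empty follow-up window and gets an `NA` marker.
- `all_sessions`: the code summed over all sessions divided by the total
  number of imaging time points, for both classes — the literal reading of
  "sum of binary code / number of all time points".

Both conventions are verified against exhaustive brute-force enumeration of
every binary code up to length 6.

One consequence of the default convention worth knowing: spines born late
in a schedule are scored over very few follow-up sessions, so their index
distribution is coarse (a spine born at the penultimate session can only
score 0 or 1). When comparing persistence across classes or populations,
restricting to spines born within a fixed early window gives better-matched
denominators.

### Synthetic spine cohorts

`simulate_spine_tracks()` is a discrete-time birth–death process: each
spine present at t−1 is eliminated at t with the session hazard `e_t`, and
`Poisson(f_t × N(t−1))` new spines are born. Formation is multiplicative on
the previous total precisely so that the formation-rate estimator (count
over previous total × 100) is unbiased for `100·f_t` — the generator and
the estimator share a denominator by design. Defaults (81 dendrites,
~126 spines on a 63 µm stretch, i.e. ~2 spines/µm on apical tufts imaged at
two baselines plus 3-day follow-ups) mirror the scale of a chronic
cranial-window experiment of this kind. Spines are exchangeable: no spatial
structure along the dendrite, no distance-dependent hazards, no clustering
of turnover — so passing parameter-recovery tests says the estimators are
correct, not that real dendrites lack spatial structure. Reappearance is
off by default (presence codes contain no 1→0→1 pattern); the analysis side
nevertheless handles arbitrary codes.

## Calcium activity

### Processing chain

Traces enter as per-frame ROI and neuropil-mask pixel means (extracted from
movies by `extract_roi_traces()`, or supplied directly as CSV). The chain
is: zero-phase low-pass at 10 Hz → neuropil compensation → robust transient
detection. Neuron identity across sessions comes from the input ID mapping;
no registration is attempted.

**Low-pass.** A second-order Butterworth applied forward and backward
(`signal::filtfilt`), so it is zero-phase: event onsets and peaks do not
shift, which matters because activity is compared across sessions at frame
resolution. The trace is extended by odd reflection at both ends and
trimmed after filtering; this confines startup transients to the discarded
padding and makes constant traces pass through unchanged. The effective
two-pass magnitude response is `1/(1 + (f/10 Hz)^4)`, verified in the tests
at 0.5 Hz (passband, <1% loss) and 14 Hz (stopband).

**Neuropil compensation.** `F_comp = F_ROI − α·(F_neuropil − median(F_neuropil))`
with α = 0.7. The median is taken over the whole session's trace (a rolling
variant can be configured); recentring on the median removes the shared
slow background without changing the trace's level, and adding any constant
to the neuropil trace leaves the output bitwise unchanged. The expression
is grouped exactly as written above so the constant-neuropil identity is
exact in floating point.

**Transient detection.** "Prominent transient" needs an operational
definition; the package uses: baseline = trace median, noise scale
σ = 1.4826 × median absolute deviation (the robust Gaussian-consistent
estimate), and an event is a maximal run of at least `min_duration_frames`
(default 20 frames ≈ 0.7 s at 30 Hz) consecutive frames above
baseline + `k_sigma`·σ (default k = 3). This rule is parameter-light,
scale-invariant (no ΔF/F normalisation is needed), and degrades safely: a
constant trace has σ = 0 and yields zero events rather than a division
error. Event intervals are half-open `[start, end)` with 0-based frames.
A neuron is *active* with ≥ 1 event; frequency is events per minute;
*high* activity means ≥ 1 transient/min, *low* below that, *inactive* none.
The alternative reading of the duration rule — a sliding-window prominence
criterion rather than a minimum run length — would admit shorter, sharper
events; with the default GCaMP6m-like kinetics the run-length reading is
the stricter and simpler of the two, and it is the one implemented.

### Fate taxonomies

Across three sessions (baseline, an early post-injury session, a late
session), two complementary taxonomies are computed from per-neuron active
flags. For neurons active at baseline: persistently active (1,1,1),
regained (1,0,1), silent at mid (1,0,0), silent at late only (1,1,0). For
neurons active at the late session: persistently active, regained
(baseline-active but mid-silent), newly active (baseline-inactive). Each
taxonomy partitions its denominator; neurons outside it (e.g.
baseline-silent neurons in the baseline-fate taxonomy) get `NA`, and the
8-row truth table is asserted exhaustively in the tests.

### Synthetic recordings

`simulate_calcium_recording()` builds each true trace as a Poisson event
train convolved with a unit-peak difference-of-exponentials kernel
(rise 0.08 s, decay 0.6 s — GCaMP6m-like; the field's indicator kinetics
vary, so both constants are configuration) plus a flat baseline. The
observed ROI trace adds Gaussian noise and neuropil contamination
`α·(neuropil − median(neuropil))` — deliberately centred on the neuropil
median so the compensation formula above is its *exact algebraic inverse*,
which turns "the compensation equation is implemented correctly" into a
machine-checkable identity (max abs error ≤ 1e−9 on noise-free traces).
Defaults are a 10-minute, 30 Hz, 18,000-frame recording; event amplitude
1.0 against noise SD 0.1 gives a peak SNR of 10, typical of somatic
GCaMP6m transients in superficial cortex. The movie renderer paints disk
ROIs and annulus neuropil masks on a small frame (64×64 by default;
512×512 supported) — it models no optics, PSF, motion, or overlapping
neuropil, so movie-based tests exercise bookkeeping (mask averaging,
round-trips), not image restoration.

What the generator does *not* emulate: correlated network events, baseline
drift and bleaching, indicator saturation and nonlinearity, neuropil
signals correlated with the soma, and motion artifacts. Detection results
on real recordings therefore depend on upstream correction quality in ways
these tests cannot certify.

## Circuit connectivity

Starter cells counted on a subset of sections are interpolated to the whole
series by inverse sampling fraction
(`counted × sections_total / sections_imaged`, kept real-valued); the
connectivity ratio of a region is its presynaptic count divided by the
whole-brain starter estimate. Brains with zero observed starters are
excluded from ratio summaries and listed in the run report — never coerced
to infinity. Group tables report mean ± SEM per (group, hemisphere,
region); comparisons against matching controls (7d vs 7d control, 42d vs
42d control by default, overridable) use two-tailed t-tests through the
standard-test facade. The simulator draws per-region Poisson counts and
binomially thins the true starter count, under which interpolation is
exactly unbiased — checked over 500 replicate brains — and the ratio
estimator converges to `mean presynaptic / true starters` (relative error
< 5% at 50 brains). Atlas registration and region assignment are upstream
of this module: it consumes already-regionized counts.

## Morphometry

Four closed forms, with units explicit in every signature: lesion volume as
the Cavalieri sum `Σ areaᵢ × spacing` (spacing is a required input — 0.05 mm
for consecutive 50 µm sections, larger if the series is subsampled);
cortical thickness as the mean of exactly three medio-lateral measurements;
cell density as count/area; synaptic-pair density as pairs per µm of
outlined dendritic perimeter. `convert_units()` converts between mm- and
µm-based quantities and refuses dimension-mixing conversions outright.

## Bootstrap inference

Fractions of neurons (active, of a given fate) get percentile bootstrap
CIs: resample units with replacement, recompute the fraction, take the
(α/2, 1−α/2) quantiles of 10,000 replicates. The percentile interval is the
simplest method consistent with "nonparametric bootstrapping"; BCa or other
flavours were deliberately not layered on top, and the point estimate is
always the plug-in fraction. The resampling unit defaults to the neuron —
the natural unit for per-neuron fractions — but is explicit in the result
object because per-FOV or per-animal resampling is a defensible alternative
the data sometimes warrants. Two-population differences use independent
within-group resampling with two-sided
p = 2·min(P(diff* ≤ 0), P(diff* ≥ 0)), floored at 2/iterations so p = 0 is
never reported. Calibration at study scale (n = 139 units, true fraction
0.3) puts 95% CI coverage near 0.94 and the difference test's type-I error
near 0.05; the discrete undercoverage of a couple of percent is the
percentile interval's known small-sample behaviour on binomial fractions,
not an implementation artifact.

Standard hypothesis tests (t, Mann–Whitney, KS, Friedman, repeated-measures
and one-way ANOVA, Dunnett, Tukey) delegate to `stats` and `multcomp`
routines behind one facade that records which routine produced each result.
One consequence of faithful delegation: `friedman.test` on fully tied data
returns NaN (0/0 after tie correction) and the facade propagates it rather
than substituting a value.

## Determinism and numerical conventions

Every generator and bootstrap call takes an explicit integer seed; one
global seed expands to per-module streams via
`child_seed(seed, index) = (seed + 104729·index) mod (2³¹ − 1)`. The
pipeline driver writes results to a staging directory and renames it into
place only on success (no partial outputs), writes no timestamps, and is
bit-deterministic: two runs with the same configuration and seed produce
identical files, asserted by checksum in the tests. Undefined quantities
(zero-denominator rates, empty cells, zero-starter brains) are `NA` markers
carried through aggregation with exclusion counts, never zeros.

Problem sizes used by the test suite and the acceptance script — 100
dendrites × ~100 spines for hazard recovery, 100 neurons × 18,000 frames
for detection, 1,000 replicate datasets × 10,000 iterations for bootstrap
calibration, 50–500 replicate brains for connectivity — were chosen so each
check's sampling error is small against the property being asserted while
the whole suite runs on a laptop in minutes.

## Known limitations

- Morphology labels are inputs; the package classifies nothing from images
  (no spine detection, no mushroom/thin/stubby criteria, no 0.4 µm
  protrusion rule — those live upstream in annotation tools).
- The transient criterion is a declared convention for an under-specified
  notion of "prominent"; results at low SNR are sensitive to `k_sigma` and
  the minimum duration.
- The calcium simulator's contamination model is intentionally the exact
  inverse of the compensation formula; it validates the implementation, not
  the biological adequacy of a global α = 0.7.
- Bootstrap CIs treat units as exchangeable; hierarchical structure
  (neurons within FOVs within animals) is acknowledged only through the
  choice of resampling unit.
- The axon-branch arbitrarily-unitised branching metric sometimes reported
  alongside these analyses has no stated procedure and is not implemented.
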