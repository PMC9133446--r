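---
title: "EEG vigilance staging and arousal stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG vigilance staging and arousal stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigileeg)
```

## The scientific problem

Brain arousal during quiet rest is not constant: over a 20-minute
eyes-closed recording the EEG drifts through a sequence of vigilance
stages, from desynchronized active wakefulness (stage 0) through
alpha-dominant relaxed wakefulness (A1, A2, A3, distinguished by the
posterior-to-anterior migration of the alpha rhythm), into low-voltage
drowsiness (B1), delta/theta-dominant drowsiness (B2/3), and finally
sleep onset (C, marked by sleep spindles and K-complexes). How fast and
how deep this decline runs is a stable individual trait that is altered
in affective disorders: depressed patients tend to show *higher* and
*more rigid* arousal than controls. Chronotherapeutic interventions such
as morning bright light therapy (BLT) plausibly shift this regulation,
which makes second-by-second vigilance staging of resting EEG an
attractive objective treatment marker.

`vigileeg` re-implements such an analysis end to end as a tested,
reusable pipeline: a synthetic resting-EEG generator with a *known*
latent vigilance trajectory, the standard preprocessing chain, a
sensor-space stage classifier, the three per-recording outcome
measures (relative stage occurrence, mean vigilance level, the 1--8
arousal stability index), and the statistical battery of a two-group
pre/post design (9 vs 10 analyzed patients), including its power and
equivalence machinery.

## The generator: a Markov model of arousal with stage-conditional spectra

Real resting recordings for this design are not publicly available, so
every downstream component is exercised against simulated recordings
whose ground truth is known by construction.

The latent trajectory is a first-order Markov chain over the seven
stages, sampled once per second (`sample_stage_trajectory()`). The
default transition matrix is persistent (stage runs of roughly 5--15 s)
and its stationary distribution spends about 30% of the time in A1,
34% in B2/3 and 45% in all A-stages together -- an occurrence profile
of the same shape as the study population the package emulates. Stage C
receives no mass by default: sleep onset is not reached in 20 min of
quiet rest, matching the empirical observation the analysis plan
assumes. Two modelling choices deserve a note:

* The matrix was constructed in two steps: a persistent base matrix with
  the desired stationary law, then the mixing acceleration
  `P' = c P + (1 - c) I` with `c = 1.8`, which shortens run lengths
  while leaving the stationary distribution untouched. Faster mixing
  keeps the realized stage mix of a single 20-min recording closer to
  its expectation.
* Stage C's row escapes deterministically to B2/3, so the chain has a
  unique stationary law even though C is unreachable by default.

Signals are rendered per channel as a sum of three band-limited Gaussian
noise carriers (delta-theta 2--7 Hz, alpha 8--12 Hz, beta 13--30 Hz)
whose per-second RMS follows a stage x band x region gain table
(`default_stage_spectra()`), cross-faded at second boundaries with a
50 ms raised-cosine ramp so stage transitions do not inject clicks into
the segment spectra. Carriers are synthesized in the frequency domain
(white-noise FFT masked to the band), giving *exact* band support: no
filter-skirt energy leaks from the alpha band into the 12--16 Hz
spindle range, which matters for graphoelement screening. The default
gains encode the staging signatures -- posterior alpha at least 3x
frontal in A1, frontal roughly equal to posterior in A2, frontal at
least 1.5x posterior in A3, a low-voltage floor in B1, delta-theta at
least twice alpha in B2/3, and low-amplitude beta-dominant activity in
stage 0 -- on top of a common broadband noise floor that keeps the
classes from being trivially separable.

The EOG channel carries slow-eye-movement (SEM) oscillations
(0.25--0.6 Hz, 140--200 uV peak-to-peak, events of 4--7 s at 12 per
minute of B-stage time) only inside B-stage runs, and blink transients
(~200 uV, 0.2--0.4 s) only during wake seconds; this generator contract
is what entitles the classifier tests to treat SEM presence as a
drowsiness marker. The ECG channel carries a 70 bpm QRS-like impulse
train. Gross artifact bursts (>500 uV, confined to single seconds) are
injected at 1 per minute and their seconds recorded in the ground
truth. An optional `eog_leakage` coefficient mixes the ocular signal
into the frontal channels to exercise the ICA cleanup.

What the generator does *not* emulate: volume conduction and channel
covariance (channels are independent given the stage), 1/f background
structure, topographic detail beyond three coarse regions, and real
artifact morphology. Passing tests therefore demonstrate that the
pipeline recovers the stage structure it assumes, not that it would
reproduce a specific patient's VIGALL output.

## Preprocessing

`bandpass_notch()` applies the standard analysis filter: a zero-phase
(forward-backward) Butterworth band-pass of 0.5--70 Hz, order 4, plus a
50 Hz notch (quality factor 30). One deliberate deviation: EOG channels
are filtered with a 0.1 Hz lower edge instead of 0.5 Hz, because slow
eye movements live at 0.1--1 Hz and a 0.5 Hz high-pass would erase the
signal on which the 0-versus-B1 decision rests. EEG and ECG use the
0.5 Hz edge.

`segment_recording()` cuts consecutive non-overlapping 1-s segments
(trailing partial second dropped; segments are reported 1-based).
`detect_artifacts()` replaces visual screening with deterministic,
configurable rules -- absolute amplitude above 100 uV, sample-to-sample
jumps above 50 uV, or a flatline (range below 0.5 uV) on any EEG
channel -- each flag carrying a machine-readable reason. The rules are
monotone in their thresholds by construction.

`remove_stereotyped_artifacts()` decomposes the EEG channels with
FastICA (symmetric orthogonalization, logcosh contrast, deterministic
identity initialization in whitened space) and excludes every component
whose time course correlates above |r| = 0.8 with the EOG or ECG
channel. References are band-matched (0.5--70 Hz) before correlating,
since the EOG channel deliberately retains sub-0.5 Hz content that
cannot appear in any EEG-derived component.

`screen_graphoelements()` flags candidate stage-C segments: sleep
spindles as a 12--16 Hz RMS envelope above twice its recording-wide
median sustained for at least 0.5 s, required *concurrently on at least
two central channels*; and K-complexes as biphasic 0.5--4 Hz
deflections above 100 uV peak-to-peak within 0.15--1.5 s. Two
robustness choices: the two-channel concurrence requirement (genuine
spindles are synchronous across the vertex, sustained single-channel
noise exceedances of a 2x-median threshold are not rare in band-limited
noise), and a 2-s exclusion zone around artifact-flagged segments
(high-amplitude bursts bleed into band-filtered envelopes).

## The classifier

Where the original toolchain scores source-localized band activity,
`vigileeg` works in sensor space with region-of-interest band powers:
posterior alpha (P3, P4, Pz, O1, O2), frontal alpha (Fp1, Fp2, F3, F4,
Fz), and whole-head delta-theta. Power is a Hann-tapered periodogram of
each 1-s segment integrated over the band (1 Hz resolution); the
normalization recovers signal variance (Parseval), which the tests
check against closed forms for tones and white noise.

Thresholds adapt per recording (`fit_thresholds()`): the alpha and
delta-theta thresholds default to twice the median of the respective
feature over all artifact-free segments. This makes staging invariant
under rescaling of all channels and independent of absolute gain. The
rule presumes that alpha-dominant segments are a minority of the
recording, so that the median sits at the non-alpha floor -- true for
the drowsiness-rich population profile emulated here, stated as an
explicit assumption. The SEM detector, in contrast, is an absolute
physical calibration (100 uV peak-to-peak on the 0.1--1 Hz EOG in a
3-s window) and deliberately does not scale with the recording.

`classify_segment()` is a first-match decision list: graphoelement ->
C; delta-theta above threshold and above posterior alpha -> B2/3;
posterior alpha above threshold -> A-substage by the frontal/posterior
alpha power ratio (<= 1: A1, <= 1.5: A2, else A3); otherwise SEM
present -> B1, else 0. Without an EOG channel the classifier degrades
gracefully: B1 collapses into 0 with a logged warning.

On default 20-min material the staging recovers ~89% of latent
seconds (A2/A3 confusions counted at half weight; the acceptance suite
requires at least 80%). The main residual error is B1 seconds without
a detectable SEM in their 3-s window, which are indistinguishable from
stage 0 by design of the decision list.

## Metrics

`relative_occurrence()` and `mean_vigilance()` operate on artifact-free
segments only. The numeric stage mapping (0 -> 7, A1 -> 6, A2 -> 5,
A3 -> 4, B1 -> 3, B2/3 -> 2, C -> 1) is not stated in the source
analysis; it was chosen because it respects the
wakefulness-to-drowsiness ordering and reproduces the magnitude of the
published mean-vigilance descriptives (an A1-heavy profile with 44%
B2/3 lands near 4.0 on this scale, bracketing the printed 4.039). It is
a consistency-checked assumption, not an established constant.

`interval_labels()` implements the sliding 1-min convention (interval 1
= segments 1--60, interval 2 = segments 2--61, ...), labelling each
interval with its modal stage among artifact-free segments, ties broken
toward the drowsier stage (conservative for a drowsiness index);
intervals with fewer than 30 artifact-free segments are `UNSCORABLE`.

`arousal_stability_index()` scores the scoring table on these interval
labels. Three points were genuinely open and are resolved as package
options with documented defaults:

* **Windowing.** "First/second/last 10 min" is contradictory for a
  20-min recording; the default splits the timeline into equal thirds
  (`windowing = "thirds"`), with a literal `"minutes"` mode available.
* **Evaluation order.** The table is checked in ascending score order
  (deepest decline first), so a globally alpha-rich recording cannot
  mask an early decline -- consistent with "lower = earlier decline".
  The descending reading is available (`order = "descending"`); the two
  differ for recordings matching several rows (an all-A1 recording
  scores 7 ascending, 8 descending).
* **Counting unit.** Criteria are evaluated on 1-min interval labels by
  default (`unit = "intervals"`, the unit the index is defined on) or
  on raw segment fractions (`unit = "segments"`). When no row matches,
  rules 4--6 are retried with B1 and B2/3 pooled; if still nothing
  matches the score is 7.

The index is monotone under moving a drowsiness block earlier: exactly
so in segment-fraction mode; in interval mode the modal-window
conversion quantizes fractions, so monotonicity can be violated by one
window's worth of mass for blocks sitting exactly at the 1/3 criterion
boundary. The property suite checks the exact property in segment mode
and the interval mode away from that knife edge.

## The statistical battery

Classical machinery is delegated to base R (`t.test`, `aov`,
`chisq.test`, `cor.test`, the signed-rank distribution); the package
adds the design-specific layer:

* `mde_t()` solves for the minimal detectable effect size by
  root-finding on the *exact* noncentral-t power function (tolerance
  1e-6 in d). The three design values -- d = 1.366 for the two-sample
  9 vs 10 baseline test, dz = 0.70 for 18 pairs, dz = 0.66 for 20
  pairs, all at two-tailed alpha = 0.05 and power 0.8 -- are what
  `scripts/acceptance.R` recomputes.
* `equivalence_check()` builds the 95% CI of pooled Cohen's d from the
  noncentral-t pivot and declares equivalence only when both bounds lie
  strictly inside (-SESOI, +SESOI). The pivot agrees with a
  100,000-replicate bootstrap within 0.05 on the test fixture. The
  published CIs themselves could not be reproduced under either the
  pooled or unpooled convention, so they are not used as references.
* `mixed_anova_2x2()` fits the 2x2 split-plot ANOVA via the classical
  univariate error strata and reports effect sizes through the d = 2f
  convention (f^2 = F df1/df2) -- the conversion is logged in the
  output because the original report prints "Cohen's d" for F-tests
  without stating one.
* `wilcoxon_signed_rank()` reports the continuity-corrected normal
  approximation Z with r = |Z|/sqrt(n), or the exact signed-rank
  distribution for small samples (validated against full 2^n
  enumeration).
* Paired tests use the actual pair count; the published table prints
  t(16) for groups of 9, but the printed statistics are only consistent
  with n = 9 pairs (df = 8), and the recomputation tests treat the
  printed difference mean/SD at n = 9 as the ground truth.
* No multiple-testing correction is applied, matching the analysis
  plan; the report notes the number of tests run.

## The end-to-end pipeline

`run_study()` simulates a full cohort (default 9 BLT + 10 TAU, 20-min
pre and post recordings each), summarizes every recording and runs the
battery into a three-block report (paired tests, ANOVA, descriptives,
all at 3 decimals) via `report_text()`/`report_csv()`. Participant
heterogeneity and treatment are modelled as *tilts* of the transition
matrix: each participant draws a baseline tilt (SD 0.25) toward an
"aroused" or "drowsy" row profile, and treatment adds an arm-specific
mean tilt plus individual response noise. The default BLT effect
(+0.28 tilt, response SD 0.17) yields a paired effect of dz ~ 1.0 on
mean vigilance -- the order of magnitude the emulated study reports --
and the TAU arm a small same-direction drift. BDI-II scores are drawn
from a truncated normal (mean 31.53, SD 10.98, bounds 0--63) with an
optional coupling to simulated B2/3 occurrence for exercising the
correlation analyses.

Two fidelity levels exist. `level = "eeg"` runs the full synthesis ->
filter -> artifact screening -> staging chain per recording.
`level = "stages"` (default) scores the latent trajectories directly,
which is exact with respect to the metrics and statistics and makes
repeated-study experiments cheap; the calibration experiments in the
acceptance suite (200 null studies for the type-I error of the paired
t-test, 100 replicates for sign recovery of an injected dz ~ 1.5
effect, obtained with tilt +0.45 and response SD 0.10) run at this
level. ICA is opt-in in the preprocessing chain (`ica = TRUE`),
appropriate when ocular leakage into frontal channels is expected;
under the generator's default (no leakage) it verifiably removes
nothing.

## Numerical choices and degenerate inputs

* Filters are applied forward-backward; zero phase is verified by
  cross-correlation on tones. Filtering is idempotent to <1% in
  passband RMS.
* EDF output quantizes to 16 bits over +/-3276.8 uV (0.1 uV per step);
  round-trips are exact to one step. Recordings shorter than 3x the
  high-pass impulse-response scale are rejected rather than filtered.
* Segment counts floor to whole seconds; sub-second recordings yield
  zero segments with a warning.
* Zero-variance differences, empty artifact-free sets, missing ANOVA
  cells, and all-unscorable interval sets raise errors naming the
  offending unit rather than propagating NaN.
* All simulations are seeded; a fixed seed reproduces trajectories,
  signals, summaries and reports byte for byte.

## Known limitations

* Fidelity to the original VIGALL 2.1 implementation is unknowable from
  the published description alone (its band edges, thresholds and
  source-space ROIs are not reproduced there); the package's
  acceptance standard is recovery of its own generator's ground truth
  plus the recomputable published statistics, not VIGALL-equivalence.
* The adaptive median-based thresholds assume a non-alpha-dominant
  majority of segments; recordings dominated by A-stages (or by B2/3
  beyond ~65%) push the median onto the wrong plateau and degrade
  staging. This is a property of the published-style adaptive rule, not
  a bug; the multipliers and cut points are exposed for recalibration.
* B1 seconds without a slow eye movement in their 3-s window are
  classified 0 by construction; B1 recall is bounded by SEM coverage.
* The generator's spectra are calibration knobs chosen to exercise the
  decision boundaries, not estimates of any patient population.
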