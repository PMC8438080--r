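---
title: "Methods: multimodal analysis of action observation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal analysis of action observation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(observa)
```

# The experimental setting

`observa` analyzes experiments in which observers watch short videos of an
actor grasping a hammer and pounding a peg, in two conditions: an
*efficient* initial grip (an underhand grasp that ends in a comfortable
hammering posture) and an *inefficient* one (a habitual overhand grasp that
ends awkwardly). Gaze position and pupil size are recorded with a remote
eye tracker (120 Hz) on a 1920 x 1200 display; scalp EEG is recorded from a
32-channel cap (extended 10-20 montage plus two mastoids) at 500 Hz. Videos
run 5.4 s with the actor starting to move at 2.5 s, so a long pre-movement
period provides pupil and EEG baselines.

The scientific question is whether an observer *registers* the efficiency
of the initial grip, not merely whether they watch. The package therefore
measures, per participant: where gaze goes (AOI metrics, probability maps),
whether the visual information actually sampled suffices to separate the
two conditions (gaze-masked "looking video" classification), and whether
physiology differentiates the conditions (pupil dilation, mu-rhythm
suppression and its condition dependence).

# Dynamic AOI analysis

Five rectangular, per-frame AOIs cover the hammer, the peg(board), the
actor's dominant and non-dominant hand, and the face. When rectangles
overlap (the hand grasping the hammer, the hammer reaching the peg), a
gaze point inside several AOIs is attributed to the *front-most* one,
defined as the AOI that most recently moved into the space of another AOI.
The display specification records these entry events as a depth history; if
no containing AOI ever produced an entry event the canonical AOI order
breaks the tie deterministically.

Fixations are detected with the dispersion algorithm (I-DT): a window of
consecutive valid samples grows while
`(max(x) - min(x)) + (max(y) - min(y))` stays within the dispersion
threshold (default 50 px, appropriate for 120 Hz data on this display);
windows shorter than 100 ms are discarded. The vendor software used for
the original recordings is proprietary; I-DT was chosen because it is
standard, parameter-light, and exactly reproducible. Each fixation is
labeled with the majority AOI of its per-sample assignments, ties broken
by the canonical order.

Measures per trial: **percent dwell** (AOI sample time over total tracked
time; invalid samples are excluded from numerator and denominator),
**percent fixation** (AOI fixation time over total fixation time),
**revisits** (entries into the AOI from outside; the first entry counts, so
any AOI with positive dwell has at least one revisit), and **gaze shifts**
(consecutive fixations on different AOIs separated by at most 100 ms),
pooled over direction into the 10 unordered AOI pairs.

# Temporal probability maps

For each participant, each pixel's value is the fraction of video frames in
the reach interval (movement onset to grasp) on which the pixel lay within
75 px (Euclidean, inclusive) of the gaze point — 75 px absorbs tracker
detection resolution. Frames without valid gaze cover nothing but stay in
the denominator. Group maps average participants; groups are compared with
a pixel-wise Welch (unequal-variance) t-test and a Benjamini-Hochberg mask
at `q = 0.05` over the *full grid* (the FDR family is stated explicitly
because it is a real choice; restricting it to nonzero-variance pixels
would be less conservative). Pixels with zero variance in both groups
carry no evidence and are assigned `p = 1` rather than dropped. An integer
`downsample` factor supports desk-scale runs; the default is the full
display grid.

# Looking videos and gaze-contingent classification

A looking video keeps each display frame identical to the original inside
the 75 px disk around that frame's gaze (nearest valid sample within half a
frame interval) and black elsewhere; frames without gaze are entirely
black. This is precisely the visual information the observer sampled.

Because the package must build and test without network access or
pretrained weights, the display is rendered *schematically*: each AOI is a
filled rectangle in a distinct color on a gray background at a reduced
working resolution (default width 96 px in the desk preset). The schematic
scene carries exactly the information the AOI tracks define, which is the
information the simulator's observers use; a pretrained-network feature
extractor for real video frames can be plugged in through
`register_extractor()` without touching the rest of the pipeline.

The default feature extractor pools each frame's RGB values over an 8 x 8
spatial grid (192 dimensions per frame). Each trial's feature sequence is
then pooled over time as piecewise means across 8 equal video segments.
This preserves *when* information was sampled — the condition signal lives
in the timing of looks at the hammer and hand around the grasp — while
keeping the classifier input of fixed, modest dimension. A recurrent
sequence model was considered and rejected: no suitable dependency-free
implementation exists here, stochastic training would compromise exact
reproducibility, and the scientific claim (the sampled information
separates the conditions) does not hinge on the classifier family.

Classification is per participant: a linear support vector machine with
least-squares cost and regularization constant `C = 1`, solved in closed
form in the dual. On each of 500 repetitions (200 in the desk preset) one
random trial per condition is held out, the classifier is trained on the
remaining trials (46 under the full design of 24 + 24), and the held-out
pair is scored; accuracy is the mean percent correct. Significance comes
from a label-shuffle null: the whole procedure is repeated under permuted
labels (1000 shuffles, 200 at desk scale; 50 repetitions per shuffle by
default — cheaper than the observed statistic, recorded in the result
metadata), with the finite-sample permutation p-value
`(1 + #{null >= observed}) / (1 + n_shuffles)`. Features are z-scored
across a participant's trials before the Gram matrix is formed; the
transform is label-independent, so the permutation test remains valid.

# Pupillometry

Blinks and artifacts are flagged with a vendor-independent rule (pupil
non-positive, or more than 5 MADs from the trial median, widened by 50 ms);
gaps up to 300 ms are bridged linearly, longer gaps stay missing, and
trials over half missing are excluded. Traces are mean-binned to 30 Hz,
aligned to movement onset, and expressed as percent of the trial's baseline
(mean pupil size over the first 1250 ms of the display, before the actor
moves). Between-condition comparison runs a Welch t-test on participant-
mean traces at every timepoint, with BH-FDR across the timepoints from
movement onset onward (the pre-movement baseline is not a hypothesis), and
reports contiguous significant windows. Computing on participant means
(rather than pooling trials) keeps the degrees of freedom at the
participant level, matching how such comparisons are conventionally
reported.

# EEG: spectral analysis, localizer, classification

Preprocessing: zero-phase (forward-backward) 4th-order Butterworth
band-pass 1-45 Hz — a 4th-order filter has a 24 dB/octave asymptotic slope,
and applying it in both directions removes phase distortion — then
re-referencing to the digital average of the two mastoids, then epoching
from -1.5 to +2.9 s around movement onset (the video ends exactly 2.9 s
after movement onset under the default display timing). Epochs exceeding
the recording are dropped with a warning. Ocular-artifact removal (ICA) is
an injectable hook rather than a reimplementation: `eeg_preprocess()`
accepts any `function(epochs) -> epochs`.

ERSP uses complex Morlet wavelets with a fixed 7 cycles at every frequency
(recorded in the map's parameters): per channel and frequency,
`log10(mean power(t, f) / mean baseline power(f))`, baseline -1.5 to 0 s.
Cells within 3 wavelet standard deviations of an epoch edge are flagged and
excluded from baseline means and suppression indices. Power time courses
are decimated (default every 10th sample) — Morlet power at 6-20 Hz is
smooth far beyond 50 Hz resolution.

Single-trial values need care: the log of a noisy power estimate is biased
low (for near-Gaussian background the single-cell Morlet power is
approximately exponential, giving a bias near -0.25 log10 units), so
per-epoch values are computed as `log10 power(f, t)` minus the same
epoch's *mean log* baseline power at that frequency. The bias then cancels
between analysis and baseline cells and the per-epoch value is exactly
zero-mean under stationarity — the property both the sign-flip localizer
and the single-trial classifier require.

The localizer is individualized and data-driven, run on the localizer-video
epochs only: one-sample t against zero at every (frequency, time) cell of
every channel in the search set (bilateral frontocentral, central,
centroparietal, and occipital sites present on the 32-channel cap), within
6-20 Hz and movement onset to hammering time. Cells below the negative
two-sided alpha-level t threshold (suppression only — the localizer targets
suppression) are grouped by 4-connectivity per channel (no cross-channel
clustering, matching per-channel cluster reporting), each cluster scored by
its *mass* (sum of t; mass rather than extent is the recorded choice).
The null records the most negative cluster mass across all channels per
sign-flip permutation (default 1000, seeded) — a max-statistic null, so the
family-wise error over channels is controlled. Test-video epochs never
enter the localizer; selection and inference stay separated.

Per-trial features for the confirmatory classifier are the mean single-
trial log-ratios over each significant cluster's cells; classification then
follows the shared LS-SVM scheme above. Participants whose localizer is
empty are reported *not classifiable* rather than assigned chance accuracy
— under null simulations empty localizers are the correct outcome, and
fabricating an accuracy for them would distort group summaries.

Suppression indices are box means of the ERSP log-ratio over a frequency
band and time window, excluding edge-flagged cells. Group summaries use
the mu band of each group (8-13 Hz for adult-like, 6-9 Hz for child-like
observers) over 0.5-2.0 s after movement onset; the early bound keeps the
wavelet's temporal smearing of the amplitude step at onset out of the
index. In the pipeline the index is averaged over the channels the
localizer marked action-sensitive (falling back to the whole search set
when the localizer is empty): averaging over all searched sites would
dilute the index with channels that carry no rhythm, which is exactly what
the localizer exists to exclude.

# The synthetic cohort

The simulator generates data with the statistical structure the analyses
assume, under two observer profiles.

**Display**: 1920 x 1200, 30 Hz, 5.4 s; movement onset 2.5 s, grasp 3.5 s,
hammering 4.0 s. The grasp and hammering times are not dictated by the
stimulus description and were fixed once at these values; the epoch window
-1.5 to +2.9 s then spans exactly movement onset to video end. AOI
rectangles follow the scripted action (hand to hammer by the grasp,
hammer and hand to the peg by the hammering time, pounding oscillation
afterwards) with sizes close to the stimulus AOI areas.

**Gaze**: piecewise-constant fixation targets with instantaneous saccades.
Both profiles scan the face before movement. Adult-like observers
alternate strictly between the dominant hand and the hammer during the
reach; the condition shifts the dwell split toward the hammer/grip on
inefficient trials and pulls gaze toward the grip point on the handle, both
scaled by `gaze_condition_effect` so that a zero effect makes the
conditions exchangeable (identical traces at equal seeds). Child-like
observers jump to the peg `anticipation_latency` (0.3 s) after movement
onset regardless of condition. Noise is decomposed into a per-fixation
placement jitter (SD 15 px — where a fixation lands) and per-sample tracker
noise (SD 5 px — what a 120 Hz tracker adds); a single per-sample jitter of
15 px would make dispersion-based fixation detection impossible, which is a
property of real data the decomposition respects. Blinks arrive as
contiguous invalid runs totalling ~2% of samples by default. The magnitude
of the adult condition effect is a free parameter (no empirical value
exists for it); the default of 1 marks a clearly condition-sensitive
observer and produces near-ceiling looking-video classification — stronger
separation than the empirical adult mean, which is the intended reading of
"adult-like" rather than a fitted quantity.

**Pupil**: a smooth baseline (per-trial level ~4 a.u. with 5% lognormal
variability, slow sinusoidal drift, 2% measurement noise) plus a dilation
bump on inefficient trials only: amplitude `pupil_effect` percent of
baseline (default 8%), shaped as a raised-cosine-tapered plateau (Tukey
window, 25% taper per edge) spanning 0.7-1.4 s after the grasp. A pure
raised cosine was considered but has a measure-zero plateau, which makes
"the injected window" ill-defined for recovery scoring; the Tukey shape
keeps the raised-cosine edges and makes the window a real object.

**EEG**: 1/f background noise on every channel (band-stopped around the mu
band on oscillation channels), plus band-limited Gaussian mu activity on
FC1/FC2/C3/C4/CP1/CP2 whose amplitude steps at movement onset so the
expected log10 post/pre power ratio equals the profile's target at *every*
in-band frequency: -0.42 in the 8-13 Hz band for adult-like observers,
-0.94 in 6-9 Hz for child-like ones (children's overall suppression is the
stronger of the two; it is the *condition difference* they lack). The
condition effect (default 0.4 log10 units for adult-like, 0 for child-like)
splits symmetrically between conditions, inefficient more suppressed.
Independent lognormal amplitude jitter (SD 0.15) on the baseline and
post-onset segments gives single-trial variability without biasing the
across-epoch ratio.

**What the simulator does not emulate**: real video content (actors,
luminance structure — the schematic rendering carries AOI-level information
only), smooth pursuit and saccade kinematics, pupil foreshortening or
luminance responses, volume conduction and channel covariance, ocular EEG
artifacts, and the partial condition sensitivity real children show.
Passing tests therefore certify the *analysis machinery* — oracle
equivalence, parameter recovery, type-I control, selection-inference
separation — not fidelity of any particular biological parameter.

# Numerical and design choices

- Seeds: every stochastic stage derives its own stream from the global seed
  and a stage tag via a polynomial hash modulo a Mersenne prime
  (`derive_seed()`); reruns of a configuration are bit-identical.
- Disk inclusion and mask radius use `<=` (a pixel at exactly 75 px is
  covered).
- Degenerate pixels/timepoints (zero variance in both groups) get `p = 1`.
- BH-FDR via the step-up rule; rejection sets are monotone in `q` and
  order-invariant (property-tested against brute-force enumeration).
- ANOVA treats trial-level rows as observations (a participant-mean mode is
  a matter of passing aggregated rows); Type II sums of squares for
  unbalanced data, recorded in the output.
- Tie-breaks (front-most fallback, fixation labels) always resolve to the
  canonical AOI order, never at random.
- LS-SVM solved via Cholesky on the regularized Gram block; `C = 1`.
- External formats are plain text: gaze CSV, display-spec JSON, tidy CSV
  measures, JSON results and localizer summaries, long-format CSV for
  small EEG epoch sets.

## Problem sizes of the shipped validation runs

The test suite and `scripts/acceptance.R` run desk-scale cohorts chosen as
the package's own validation design: 8 adult-like participants and 40
child-like participants, 24 trials per condition, 200 hold-out repetitions,
200 shuffles (20 repetitions each), 200 localizer permutations, render
width 96 px, map downsampling 8, ERSP over 6-20 Hz at 25 Hz time
resolution. The `"full"` preset restores 500 repetitions, 1000 shuffles,
1000 permutations, 50 Hz ERSP time resolution, and full-resolution maps.

# Known limitations

- The schematic renderer means the default feature extractor sees AOI-level
  structure only; with real stimulus frames a pretrained extractor should
  be registered instead.
- The localizer controls family-wise error across channels via the max-
  statistic null but shares one cluster-forming threshold; very diffuse,
  weak suppression can be missed (a property of cluster tests generally).
- Child-like observers are *exactly* condition-insensitive; empirical
  children are not, so group contrasts on synthetic data are sharper than
  reality.
- `compare_conditions()` treats the two condition samples as independent
  (unequal-variance t), although participants contribute to both; a paired
  mode would gain power and is deliberately out of scope here.
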