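---
title: "Assessing the type and intensity of repetitive hand movements from skeletal keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the type and intensity of repetitive hand movements from skeletal keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handrep)
```

## The problem

Agitation in people living with dementia frequently surfaces as repetitive
hand movements — picking or scratching at an arm, rubbing an object,
wringing the hands. Carers currently assess agitation from recollected
observations, which is subjective and misses gradual change. A fixed RGB
camera watching a mainly sedentary person, combined with an open-source
pose estimator such as OpenPose, yields a privacy-preserving "stickman"
representation: per frame, 2-D keypoint locations with detector
confidences. `handrep` turns such keypoint sequences into two clinically
meaningful outputs per 12-second window:

* the **type** of repetitive hand movement, out of clapping, picking,
  rubbing, scratching and hand wringing (clapping serving as a benchmark
  movement), and
* its **intensity**, the number of repetitions in the window, scored
  either against global *range* boundaries or against *personalised*
  per-subject boundaries.

The two stages are chained: the predicted type selects the
type-appropriate distance measure and peak-detection settings with which
intensity is assessed.

Because hand-movement datasets of this kind are small and rarely shareable,
everything here is designed around small-data methods (an instance-based
classifier, tuned classical peak detection) and the package ships a
parametric generator of synthetic keypoint recordings so that the whole
pipeline is testable end to end without any external data.

## From pixels to analysis windows

Each frame keeps 50 keypoints: nose, neck, both shoulders, elbows and
wrists, plus 21 keypoints per hand. Processing is a fixed chain:

1. **Imputation.** A keypoint reported missing (confidence 0 at the
   origin) is replaced by the coordinate-wise median of its own
   observations within ±8 frames (a 17-frame window, matching the
   smoothing scale below); the window is doubled once if empty. The
   half-window is a package decision — medians over neighbouring frames
   need a concrete neighbourhood, and a symmetric window at the smoothing
   scale is the natural choice.
2. **Resampling** to 30 frames per second by per-keypoint linear
   interpolation. An interpolated frame's confidence is the minimum of
   its two parents: interpolation cannot make a location more
   trustworthy.
3. **Scale normalisation.** Keypoints are translated so the neck is the
   origin and divided by the inter-shoulder distance, removing camera
   distance, image position and body size. All downstream coordinates
   are in *shoulder-width units*.
4. **Smoothing** with a Savitzky–Golay filter, polynomial order 3,
   window 17 frames (0.57 s). This filter family preserves the shape
   and height of waveform extrema — exactly the features repetition
   counting relies on — while flattening detector jitter.
5. **Windowing.** Classification works on 6-s (180-frame) windows with
   no overlap after discarding 3 s at each end of a 30-s recording (four
   windows). Intensity works on 12-s (360-frame) windows shifted by 5 s
   after discarding 1.5 s at each end — again four windows, consecutive
   windows sharing 7 s. A 12-s window holds at least six repetitions at
   the slowest study rate, enough cycles for peak detection to be
   meaningful.
6. **Per-window orientation and re-centring.** Within each window the
   *dominant hand* is the wrist with the larger cumulative path
   distance; if that is the left, the skeleton is reflected
   (x-coordinates negated, left/right labels swapped) so the dominant
   hand is always on the right. Ties keep the right hand, so output is
   deterministic. The 46 hand, wrist and elbow keypoints are then
   re-centred on the wrist midpoint. Orientation is decided per window,
   not per recording, because windows are the unit of classification;
   a recording in which the subject switches hands mid-way is then
   still handled sensibly.

Two invariances follow by construction and are enforced in the test
suite: outputs are unchanged under uniform scaling plus translation of
the pixel coordinates, and under an exact left–right mirroring of the
subject.

## Discriminative poses and NBNN classification

A 180-frame window is summarised by nine *discriminative poses*: for
each of three 60-frame sub-windows, the **mean pose** (per-keypoint
average), the **maximum pose** (the frame where the confidence-weighted
hand centroids are furthest apart) and the **minimum pose** (closest
together). Hand centroids weight each of the 21 hand keypoints by its
detector confidence, so erroneous low-confidence finger predictions do
not drag the estimate. Sixty frames is the shortest span that reliably
contains movement at the slowest rate. For 12-s windows the same rule
yields 18 poses; a `central_180` option restricts to the central 6 s
when strict 9-pose parity is wanted.

Classification is Naive Bayes Nearest Neighbour (NBNN) on the
92-coordinate flattened poses: for each candidate class, each query pose
is matched to its nearest training pose *of the same kind* (mean with
mean, maximum with maximum, minimum with minimum) and the Euclidean
distances are summed; the class with the smallest total wins. Matching
is by pose kind only, not sub-window index, since only the three kinds
carry distinct meaning. The Euclidean norm is the conventional NBNN
choice; exhaustive search is used because libraries here hold a few
thousand 92-vectors at most. Exact ties go to the lexicographically
smallest label, with a warning.

Three validation protocols are provided: stratified four-fold
cross-validation, four-fold cross-intensity validation (each fold holds
out one metronome rate entirely), and leave-one-subject-out
cross-subject validation — the stringent test of generalisation to new
people.

## Counting repetitions

For intensity, a window is reduced to a single 1-D signal: one of the
Euclidean / vertical / horizontal inter-wrist distances or the Euclidean
inter-centroid distance, min–max normalised to [0, 1] within the window
so subjects with different ranges of motion are comparable.
Normalisation is applied to the raw distance per window, before
negation. The signal is then negated, so the instant of each repetition
(hands closest) becomes a wave peak, and peaks are filtered by three
hyperparameters:

* **minimum prominence** — topographic height of a peak above the
  higher of its surrounding valleys, suppressing spurious wiggles;
* **minimum height** — applied to the negated signal (values in
  [−1, 0]), so realistic thresholds are negative; this is the only
  reading consistent with shipped negative defaults such as clap's
  −0.65;
* **minimum distance** — minimal separation in frames; of two closer
  qualifying peaks the higher survives (the earlier on an exact tie).

Filters are applied in the order height, distance, prominence, the
convention of the standard scientific-Python peak detector; prominence
is a property of a peak in the whole signal and is therefore
pre-computable, which is what makes grid search cheap. Plateau peaks
are represented by their midpoint sample, for determinism.

The count maps to an intensity category: ≤ 8 repetitions per 12-s window
is *slow*, 9–12 *medium*, 13–16 *medfast*, ≥ 17 *fast* — the bins
containing the expected counts 6/10/14/18 at the four metronome rates
30/50/70/90 repetitions per minute. **Range accuracy** is the percentage
of windows whose count lands in the true bin. **Personalised accuracy**
instead compares each count with that subject-and-activity's mean
detected counts at the adjacent slower and faster intensities (strictly
between them; one-sided at the extremes). Personalised boundaries are
reset per activity and participant; they are the measure that matters
for monitoring an individual, and are systematically the more lenient
of the two.

Hyperparameters are tuned per movement class by exhaustive grid search —
prominence 0 to 2 in steps of 0.2, distance 10–20 frames, height −0.5 to
0.5 in steps of 0.1, all endpoints inclusive — with range accuracy as
the objective, separately for each candidate distance measure. Ties are
broken towards smaller prominence, then smaller distance, then larger
height, then the measure order Euclidean wrist, vertical wrist,
horizontal wrist, centroid. The shipped defaults
(`default_intensity_config()`) are the published reference tuning; note
its clap height (−0.65) lies off the default grid and is shipped as
published. On any new data source — including the synthetic generator —
the intended workflow is to retune: tuned hyperparameters encode the
waveform shape of a *particular* data source, and a window's first or
last repetition can never exceed the prominence that the waveform
accumulates between the window edge and that peak, so a high fixed
prominence threshold from one source may drop edge repetitions on
another.

## The end-to-end system and its scenarios

`fit_pipeline()` builds the pose library and tunes the intensity
configuration; `run_pipeline()` applies them window by window. Three
scenarios are supported: **proposed** (classify, then assess intensity
with the predicted class's configuration), **known** (ground-truth
labels select the configuration — an oracle upper bound for the
classification stage) and **generic** (classification skipped; a single
Euclidean-wrist configuration tuned on the whole training set, the
measure that embodies both horizontal and vertical motion). Joint
correctness of a window means type correct *and* personalised intensity
correct, so joint accuracy can never exceed either component.

## The synthetic generator

`generate_recording()` produces parametric 30-fps recordings of the five
movement archetypes: clapping as symmetric horizontal wrist oscillation
with brief contact and a wide dwell (its distance dip is sharpened by a
power of 0.25 on the half-cosine cycle); picking as a small vertical
oscillation of the dominant wrist above the opposite forearm; rubbing as
a vertical stroke low in the image against an object held by the other
hand; scratching as a low-amplitude sweep along the opposite forearm;
wringing as near-coincident wrists with a small counter-phase
oscillation. The 21 hand keypoints ride rigidly on each wrist with
per-digit offsets. Subject profiles vary shoulder width (140–190 px),
image position, seated or standing posture, handedness (left-handed
subjects are exact mirrors), whether both hands move, amplitude
(±15 %) and pacing reliability.

The noise model adds per-keypoint Gaussian noise (default 2 px),
drops keypoints to missing with probability 0.01 per keypoint-frame,
and assigns confidences anticorrelated with the injected noise
(`c = max(0, 1 − |error|/10 px)`), so confidence-weighted centroids are
exercised meaningfully. Pacing error is modelled as per-cycle period
jitter with standard deviation 5 % of the period. These defaults are
the generator's standing study conditions: 2 px is a typical detector
error at the simulated ~160 px shoulder width, and 5 % is a plausible
human deviation from a metronome.

One generator choice deserves emphasis: all subjects start a repetition
cycle at *t* = 0, as metronome-paced participants do, and subject
individuality enters through geometry, amplitude and jitter rather than
through a random phase offset. With the pipeline's half-second-aligned
window boundaries and the four study rates, this keeps every repetition
instant at least a quarter cycle (five frames or more) away from every
window edge, which is what makes noise-free repetition counts exactly
recoverable for any seed. Ground truth (the instants at which hands are
closest, hence per-window true counts) is carried in the recording
metadata.

What the generator does *not* emulate: correlated detector failures
(whole-hand misdetections lasting many frames), perspective
foreshortening, occlusion structure, within-recording drift of posture,
or idiosyncratic movement styles. Passing tests on synthetic corpora
therefore demonstrate the correctness and internal consistency of the
pipeline — not field accuracy on real video, which must be established
per deployment with real labelled recordings.

## Numerical choices and edge cases

* A constant distance signal cannot be min–max normalised; it becomes
  all zeros with a warning (and zero detected repetitions).
* A frame whose shoulders coincide (zero shoulder width) is a hard
  error, as is a keypoint missing in every frame.
* Exact ties — dominance, extremal frames, NBNN totals, equal-height
  peaks — are all broken deterministically (right hand, earliest frame,
  lexicographic label, earlier peak), so repeated runs are bit-identical.
* Nearest-neighbour distances are computed from explicit coordinate
  differences rather than the expanded quadratic form, so a query
  identical to a training pose scores exactly zero.
* The internal tabular format writes 17 significant digits, making
  write-then-read round trips bit-exact.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the full study
design — 20 subjects × 5 movements × 4 rates × 30 s — for structural
counts, and train on 10 subjects / evaluate on 5 held-out subjects for
the end-to-end run, with the full tuning grid. Smaller corpora (1–4
subjects) are used for unit-level properties, and a reduced grid
(5 × 3 × 5 points) wherever a tuning result is re-verified by
independent re-evaluation of every grid point. These sizes were chosen
so the whole suite completes in minutes on a single core while still
covering every study-scale count the design implies.

## Limitations

* The classifier is instance-based: accuracy on new people depends on
  how well the training library spans their movement styles;
  cross-subject accuracy is the number to watch, and personalising the
  library with end-user examples is the intended remedy.
* Intensity hyperparameters transfer poorly across data sources by
  design (they encode waveform shape); retune rather than reuse.
* The pipeline assumes one mainly sedentary subject; multi-person
  scenes are reduced to one person by a selection policy (largest
  shoulder width by default), not tracked.
* Only relative 2-D geometry is used; movements distinguished chiefly
  by depth would confuse both stages.
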