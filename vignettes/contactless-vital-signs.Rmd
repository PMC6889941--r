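---
title: "Motion-based respiratory and heart rate estimation from sleep video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based respiratory and heart rate estimation from sleep video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camvitals)
```

## The problem

A near-infrared camera mounted above a bed sees two kinds of physiological
motion on a sleeping person's torso: the breathing excursion of the chest and
abdomen (order 1 px at typical camera geometry) and the far smaller
ballistocardiographic recoil of each heartbeat (order 0.1-0.3 px, sub-pixel).
Both are periodic, so both can be read off the displacement spectra of
tracked surface points — without any sensor touching the patient. This
package implements that pipeline end to end: feature tracking, per-window
blind source separation, rate extraction, movement handling, reference-rate
extraction from ECG and respiratory inductance plethysmography (RIP), and
the agreement metrics used to compare the two.

Overnight clinical recordings cannot be shipped with a package, so
`camvitals` also contains a first-class synthetic-scene generator with exact
ground truth. Every claim the test suite makes is a claim about recovery of
known ground truth on those scenes.

## The estimation pipeline

**Feature selection.** Each 8-bit monochrome frame is divided into a grid of
40 x 40 px cells and up to 8 minimum-eigenvalue (Shi-Tomasi) corner points
are kept per cell, subject to a quality floor at 1 % of the frame's
strongest response and a 3 px non-maximum-suppression radius. A 640 x 480
frame can therefore contribute at most 16 x 12 x 8 = 1536 points; untextured
cells contribute none.

**Tracking.** Points are tracked with pyramidal Lucas-Kanade optical flow
anchored at the window's first frame: the appearance template and gradient
structure tensor come from the anchor frame, and each later frame is
registered against it starting from the point's displacement in the previous
frame. Anchoring removes frame-to-frame drift accumulation, which matters
because the cardiac signal is an order of magnitude below the pixel grid. A
half-resolution pyramid level engages when the previous step exceeded 0.5 px.
Points are dropped when their patch leaves the frame, their structure tensor
degenerates, or the patch residual exceeds 25 intensity levels.

**Displacement filtering.** Within each window, every point's maximum
frame-to-frame Euclidean step is computed and points strictly below the 25th
or strictly above the 75th percentile (linear-interpolation convention) are
discarded. The lower tail removes points stuck on static background, the
upper tail removes unstable tracks; tied values are all retained, so a
degenerate all-equal window passes through unchanged. With fewer than 4
valid points the filter is skipped with a warning flag.

**Windowing.** Analysis runs on sliding 30 s windows with 29 s overlap (1 s
step), so a rate estimate is emitted once per second, and gold-standard
series are computed on exactly the same grid for index-aligned comparison.

**Respiratory rate.** Each retained point contributes its vertical and its
horizontal displacement series separately — the breathing direction depends
on posture, so the method must not privilege one axis. Principal component
analysis concentrates the coherent breathing motion; among the first 5
components the one with the highest fraction of spectral amplitude inside
the breathing band (0.1-1.0 Hz, i.e. 6-60 br/min) is selected, with ties to
the lower index for determinism. The rate is 60 times the parabolic-refined
dominant in-band peak.

**Heart rate.** The same signals are reduced to 8 dimensions by PCA
whitening and unmixed with a seeded symmetric FastICA (tanh contrast).
Every component's spectrum contributes its in-band local maxima (20-140
bpm); candidates are pooled, ranked by *harmonic periodicity* and truncated
to the top 12. Harmonic periodicity is the spectral amplitude attributed to
a candidate fundamental plus its first two harmonics, divided by the total
spectral amplitude — heartbeat motion is pulse-like and harmonically rich,
while breathing harmonics decay quickly, so this score separates the two.
Because a strong breathing harmonic can still masquerade as a cardiac peak,
each candidate $f$ is scored as

$$S = 2 s_1 + (1 - s_2) + (1 - s_3)$$

where $s_1$ is the candidate's harmonic periodicity normalised over the
candidate set, $s_2$ the absolute distance to the previous window's estimate
and $s_3$ the distance to a prior "reasonable" rate of 80 bpm — the midpoint
of the 20-140 bpm band — both normalised by the 120 bpm band width and
clamped to $[0,1]$. The band-width normalisation keeps the two proximity
terms on a fixed scale independent of the candidate set; the plausible
alternative (normalising by the per-window maximum difference) would make a
candidate's score depend on which competitors happened to survive
truncation. With no previous estimate (first window, or after a movement),
$s_2 := s_3$, which reduces the rule to prior-weighted scoring without
inventing a pseudo-history. Ties in $S$ break toward the candidate closest
to the previous estimate, then toward the lower frequency.

**Movement handling.** Whole-body movements (position changes, limb
movements) overwhelm both the video signal and the reference sensors. A
movement spike is declared when the median across points of the
frame-to-frame step exceeds 2 px — more than ten times the largest
physiological step the scene model produces (a 1.5 px breathing sinusoid at
0.5 Hz peaks at about 0.16 px/frame) — or when more than half the live
points lose their template in a single frame, which is how motion too fast
for the tracker announces itself. After a spike the tracker abandons the
segment and re-selects a fresh feature grid. Windows overlapping a spike,
and windows starting within one window length after it, are labelled
`moving` and excluded; the "following" span is the next non-overlapping
30 s, not every 1 s-shifted window, which would cascade the exclusion far
beyond the event. The previous-estimate chain of the heart-rate scorer also
resets across a movement.

## Gold standards

The reference heart rate comes from the ECG: the signal is band-limited to
5-30 Hz (2nd-order Butterworth, zero-phase), thresholded at half its rolling
2 s maximum, and each surviving local maximum is refined to sub-sample
precision with a 3-point parabolic fit. Instantaneous heart rate at each
beat is 60 over the mean of the five preceding R-R intervals, and the gold
series is the mean of those values inside each 30 s window. The reference
respiratory rate is the parabolic-refined dominant spectral peak of each
RIP window within 1-100 br/min.

Windows are excluded from comparison when the estimator marked them invalid,
when the gold window is invalid, or when the gold rate leaves the validity
range (20-140 bpm, 1-100 br/min — deliberately wider than anything
physiological during sleep, so the filter only removes sensor artefacts).
Agreement is summarised by the percentage of windows within 1 / 0.5 br/min
(5 / 2.5 bpm for heart rate), RMSE and MAE, with "within" a closed bound.
A mean-hold baseline — the first-10-minute gold average held constant for
the rest of the recording — quantifies how much overnight variability an
estimator must beat.

## The synthetic scene generator

`gen_video()` renders a speckle-textured ellipse ("torso") on a dark
background and translates it by a displacement law with four ingredients:

* a breathing sinusoid (default 1.5 px amplitude), phase-continuous in the
  instantaneous rate, with spatial gain increasing toward the abdomen;
* a cardiac pulse train modelled as a truncated harmonic stack — fundamental
  plus `cardiac_harmonics` harmonics with amplitudes halving per order
  (default 2 harmonics, 0.25 px) — with spatial gain increasing toward one
  side, so that breathing and heartbeat are spatially as well as spectrally
  distinct sources;
* white displacement noise (default 0.05 px), common to the rigid torso;
* smoothstep movement ramps of configurable onset, duration and magnitude
  that persist after the event.

The texture is blurred with a 3 x 3 kernel before rendering: a camera's
optics low-pass the scene, and pixel-iid speckle would otherwise change
appearance discontinuously under sub-pixel shifts. Frames are quantised to
8 bits, which is the only noise the noiseless test scenes retain.
`gen_ecg()` places one Gaussian R-wave per beat with optional fractional R-R
jitter; `gen_rip()` is a phase-continuous sinusoid. All generators are
bit-deterministic given the scene seed.

What the generator deliberately does **not** model: photometric pulse
signals (intensity rPPG), realistic ECG morphology (P/T waves), blankets and
occlusion, illumination drift, camera noise beyond quantisation, multiple
people, or non-rigid torso deformation. Passing tests on these scenes
therefore demonstrate that the algorithmic chain is correct and
well-conditioned at realistic amplitudes and noise levels — not that the
pipeline is validated on clinical video.

## Numerical choices

* Window spectra are linearly detrended, Hann-tapered and zero-padded to
  `n_fft = 8192`; at 30 frames/s that is a 0.0037 Hz (0.22 br/min) grid,
  comfortably finer than the 1 br/min agreement threshold, whereas a raw
  30 s window would be 2 br/min coarse. Peak locations are refined by
  3-point parabolic interpolation and clamped to the search band.
* Harmonic amplitudes for the periodicity score are integrated over a band
  of plus/minus 2 natural-resolution bins (2 x fs/n) around each harmonic;
  with a tapered, zero-padded spectrum a single-bin read would capture only
  a sliver of the mainlobe and make the score meaningless (a pure tone
  would score ~0.03). With the band convention a pure tone scores ~0.95 and
  white noise ~0.03. Harmonics above Nyquist contribute zero; an all-zero
  spectrum yields a distinct `NA` score.
* Spectral peak candidates below 5 % of the strongest in-band amplitude are
  discarded; the Hann window's first sidelobe sits near 3 %, so this floor
  removes taper artefacts without suppressing genuine secondary sources.
* Percentile cuts use R's default linear-interpolation quantiles (type 7),
  applied per window, and discard only strict exceedances so that tied
  inputs survive.
* Degenerate inputs are signalled, not guessed at: constant signals give
  all-zero spectra, empty candidate sets give invalid windows with a reason
  code, fewer than 4 points skip the displacement filter with a flag, and a
  zero-periodicity candidate set falls back to a uniform $s_1$.
* All stochastic steps (ICA initialisation, generator noise) sit behind
  explicit seeds; identical seeds give byte-identical outputs, which the
  pipeline tests assert on re-runs.

## Problem sizes used in the tests

The test-suite and acceptance scenes run at 160 x 120 px (the 40 px grid
intact, 12 cells, up to 96 points) and 35-120 s durations, with recovery
sweeps over 8-30 br/min and 10-seed heart-rate batches at 60 s each; the
mean-hold baseline is exercised on 700-900 s gold-only traces. These sizes
were chosen so the full validation cycle completes in minutes on one core
while every window still contains 900 frames, the same as at clinical
resolution — the estimators never see the frame size, only the tracked
trajectories.

## Known limitations

* The spike threshold (2 px/frame median step) is a scene-scale constant;
  real recordings with different camera geometry may need it rescaled.
* Candidate pooling keeps duplicate frequencies found by several ICA
  components; they compete individually in the scorer, which slightly
  favours sources visible in many components. In practice the harmonic
  normalisation makes this harmless.
* The PC-selection rule for breathing (largest in-band amplitude fraction
  among the first five components) is this package's choice; it is
  deterministic and robust on separable scenes but has no claim to
  optimality under heavy non-breathing motion.
* `read_edf_signal()` covers plain continuous 16-bit EDF only — enough to
  pull an ECG or RIP channel out of a polysomnography export, not an EDF+
  parser.
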