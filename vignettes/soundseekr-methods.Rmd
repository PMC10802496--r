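---
title: "Models and methods behind soundseekr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soundseekr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundseekr)
```

This vignette documents the scientific models implemented in soundseekr,
the assumptions behind them, and the numerical and design choices that a
maintainer or reviewer would want spelled out.

## The sound-seeking task and its geometry

The task takes place in a regular octagonal arena (side 15 cm, longest
diagonal 40 cm) whose periphery is divided into eight chambers, each with a
speaker and a nosepoke port on its outer wall and a 5.5 cm entryway facing
the open center. `arena_geometry()` reconstructs this plan in centimetre
coordinates with the origin at the arena center and chambers numbered 0–7
counterclockwise from east. The divider tips are placed at the radius where
the chord between adjacent tips equals the entryway width
(`r = w / (2 sin(pi/8))` ≈ 7.2 cm); the central region is the inner octagon
they bound. This is an idealization: the physical arena's dividers have
thickness and the entryway is an opening in a wall rather than a gap
between radial segments, but the only geometric facts the analyses rely on
are (i) a well-defined chamber membership for a planar point and (ii) the
ring adjacency of chambers, and both are faithful.

On each trial the goal speaker is drawn uniformly at random *excluding the
previous trial's goal* — the task never rewards the same port twice in a
row. This exclusion propagates through everything downstream: it is why
chance-level search has seven, not eight, equally likely outcomes.

## Stimulus model

The acoustic stream is a renewal process: inter-burst intervals are i.i.d.
gamma with mean μ and standard deviation σ. We parameterize by the
*repetition rate* (1/μ, bursts/s) and *irregularity* (σ, ms) because they
are the independently controlled axes of the design; the gamma shape and
scale follow as k = (μ/σ)² and θ = σ²/μ. σ = 0 is taken as the degenerate
limit, a perfectly periodic train. The fixed preset is 4 Hz, σ = 31 ms,
70 dB SPL, 10 kHz; the variable preset draws per-trial values from
5–15 kHz, 65–90 dB SPL, 3–10 Hz, and 1–100 ms.

Three choices here were genuinely open:

* **Sampling law over the variable ranges.** The training protocol does not
  pin down a distribution over these ranges. We draw center frequency,
  rate, and irregularity log-uniformly — these are perceptually and
  analytically logarithmic axes (performance analyses bin them on log
  grids) — and level uniformly in dB. This is a documented guess, not a
  measured fact.
* **Level mapping.** Absolute SPL depends on hardware we do not model. We
  adopt the convention that a digital full-scale sine corresponds to
  94 dB SPL (configurable via `ref_db_spl`), so `level_db = 70` sets the
  burst RMS to `10^((70-94)/20) / sqrt(2)` of full scale.
* **Burst synthesis.** Narrowband tokens are white noise passed through a
  zero-phase 4th-order Butterworth band-pass (center ± bandwidth/2) with
  1 ms raised-cosine ramps to limit spectral splatter. Overlapping bursts
  (possible when an interval falls below the 10 ms burst duration) are
  summed, not truncated, preserving the train statistics; a warning is
  emitted.

Speaker calibration is modelled as in practice: measure the path's power
spectrum with a white-noise probe (`estimate_spectrum()`, a Welch-style
averaged periodogram), take the dB difference to a flat target at each
frequency (`fit_calibration()`), and apply the gains as a zero-phase
FFT-domain filter (`apply_calibration()`). Residual flatness is limited by
the spectral estimate's variance, so calibration measurements should use
heavily averaged, coarse-grained spectra.

## Agent policies

Policies are intentionally stationary — they model *strategies*, not
learning dynamics:

* `random` pokes distinct eligible ports in uniformly random order. Its
  statistics are fully determined by symmetry: the goal's visit rank is
  uniform on 1..7, so E[ports poked] = 4 and P(correct) = 1/7.
* `cycling` visits the ring in order from a start port (random unless
  fixed), the traplining-like strategy mice adopt with training.
* `direct` navigates straight to the goal: the perfect-performance bound.
* `checker` enters chambers in ring order but pokes only when it "detects"
  sound in the current chamber. Detection of the goal chamber's sound is
  Bernoulli with probability given by a logistic psychometric function of
  level whose threshold depends on hearing state (intact/sham ≈ 40 dB,
  unilateral ≈ 50 dB, bilateral ≈ 110 dB — the last places the entire
  training range far below threshold, mimicking conductive hearing loss of
  several tens of dB). A configurable false-alarm rate covers non-goal
  pokes. After `max_laps` (default 2) silent laps the checker falls back to
  poking every port in ring order; this guarantees termination and matches
  the serial-poking behavior seen after bilateral loss.

Trajectories are synthesized as piecewise-linear waypoint legs
center → entryway → port → center at a constant 15 cm/s (configurable);
locomotion speed is not a measured quantity here and nothing downstream
depends on its exact value.

## Scoring rules

Both performance metrics first discard every poke into the previously
rewarded port (animals perseverate there, and it can never be the goal).
`ports_poked` counts **distinct** ports up to and including the first goal
poke. The distinct-port reading is forced by the metric's stated range: with
one port excluded, a count from 1 to 7 over an 8-port arena is only possible
if repeats collapse. Pokes after the first goal poke are ignored (the trial
ends at reward). A session's first trial has no previous goal; nothing is
excluded, the count may reach 8, and such trials are flagged and excluded
from session means by default to preserve the [1, 7] contract.

The learning criterion is *strictly fewer than* 2.5 ports poked per trial
("better than 2.5"); the criterion session and all later sessions are
"late", earlier ones "early". `performance_by_param()` is thin glue around
`stats::cor.test()` (Pearson, on the log parameter) plus log-binned means —
deliberately nothing more, as the heavier significance battery around group
comparisons is out of scope.

## Entry detection and taxonomy

A chamber entry is the frame on which the snout crosses the dividers: the
first frame inside a chamber polygon after center residence. Numerical
choices:

* **Debounce.** A visit only ends after ≥ 3 consecutive center frames
  (100 ms at 30 frames/s); a quicker return to the same chamber merges with
  the prior visit. Without this, tracking jitter at a divider
  double-counts entries.
* **Gaps.** Missing snout samples are linearly interpolated up to 5 frames;
  longer gaps leave frames unclassified.
* **Coordinates.** Analyses run in arena cm; pixel tracks are converted
  through an affine `px = scale * cm + offset` supplied alongside the data
  (the synthetic generator writes it out).
* **Trial windows.** Reward events bound each trial; entries during the
  inter-trial delay are dropped rather than attributed to either trial.

Classification follows the taxonomy exactly: duplicates are re-entries of a
chamber already visited that trial; cycling entries are ring-adjacent to
the chamber *just exited* (so a trial's first entry is never cycling);
duplicates and previous-goal entries are discarded; kept entries divide
into entries-with-poke and checks. One ambiguity required a decision: if a
poke occurs on a *duplicate* (discarded) visit, which entry is
"with poke"? By default the kept first entry of that chamber inherits the
poke (`attribution = "first_entry"`), keeping the additivity identity
`n_with_poke + n_without_poke = n_entries_kept` exact while honoring the
reading that the chamber's entry eventually culminated in a poke. The
alternative (`"own_visit"`) is implemented behind the switch.

## Startle quantification

Movement speed is the mean over body parts of per-frame Euclidean
displacement (px/frame), with missing keypoints dropped from that frame's
mean. The startle magnitude is the mean speed over the first five frames
from stimulus onset — 167 ms at 30 frames/s — *including* the onset frame
(either convention for the onset frame is defensible; including it is the
default and the window is configurable). 80 and 90 dB stimuli are
pooled. Magnitudes stay in px/frame: no px-to-mm calibration of the startle
chamber is modelled, and only within-animal contrasts are meaningful.

## ABR preprocessing

The pipeline order is cross-talk removal → 100 Hz high-pass → epoching →
outlier rejection → polarity-corrected averaging.

* **Cross-talk.** The speaker drive leaks into the neural channel; the leak
  is modelled as a causal FIR (default 32 taps = 2 ms at 16 kHz) fit by
  least squares on the continuous record and subtracted. As a projection
  this cannot increase residual power. There is no canonical filter order
  for this step; 32 taps comfortably covers electrical cross-talk memory.
* **High-pass.** "Filtering above 100 Hz" is read as a zero-phase
  Butterworth high-pass (order 2 per pass, applied forward and backward).
  Odd-reflection padding suppresses the forward–backward edge transients.
* **Outliers.** The union of the top 5% of epochs by peak-to-peak excursion
  and the top 5% by SD is discarded (the two rules could also be applied
  sequentially; the union is the default and is order-independent). Counts
  use the
  ceiling, and ties break by epoch index with earlier epochs kept.
* **Averaging.** Epochs span −2 to +10 ms around the trigger
  (configurable). Left-side responses are inverted so Wave 1 is positive
  for both sides. Wave picking/thresholding is deliberately not
  implemented; the averaged waveform is the terminal output.

## What the synthetic generators do and do not emulate

The generators exist so that every pipeline stage has a ground-truth test
path; they emulate the *structure* of the real data, not its biology.

* **Pose sessions** render simulator waypoints at 30 frames/s into a
  640×480 px frame (8 keypoints: snout, head, trunk, four limbs, tail
  base) with Gaussian tracking jitter (default SD 2 px). Body parts trail
  the snout at fixed offsets — body orientation, gait, grooming, rearing
  and identity errors are not modelled. Passing round-trip tests therefore
  shows the detector is exact on clean, jittered trajectories; it does not
  certify performance on real SLEAP output with occlusions.
* **Startle sessions** superimpose a five-frame movement burst (default
  12 px/frame for responsive hearing states, 0 for bilateral) on a
  reflected Brownian wander (step SD 1 px/frame), with onsets 5–30 s apart.
  Habituation and prepulse effects are absent by design.
* **ABR recordings** place a stereotyped three-wave template (Wave 1
  largest, ~1.5 ms latency, ~900 Hz carrier so the 100 Hz high-pass leaves
  it essentially intact) at ~750 click triggers 40 ms apart, add the
  speaker signal through a known FIR and white noise (SD 0.3 of template
  peak), and contaminate 5% of epochs with 10×-amplitude artifacts. Clicks
  alternate polarity (condensation/rarefaction) — the standard trick that
  decorrelates the stimulus artifact from the evoked response; without it,
  the least-squares cross-talk fit would absorb any response energy inside
  the FIR horizon, an identifiability limit of regression-based artifact
  removal worth knowing about when applying it to real recordings.

All generators are bit-deterministic under a seed.

## Problem sizes and tolerances

The test suite and the reproduction script use sizes chosen to make
sampling error small relative to the quantities checked: 2,000 trials for
chance-level scoring (binomial SE ≈ 0.008 on the fraction correct), 250–500
pose-tracked trials for the entry pipeline (SE ≈ 0.1 entries), ≥ 10⁵ gamma
intervals for the stimulus moments (SE of the SD estimator ≈ 0.07 ms via
the delta method with the gamma's excess kurtosis 6/k), and full 750-click
ABR recordings. Stochastic checks use 3–4 standard-error bands around the
analytic expectations; exact derivations (enumeration, degenerate limits,
identities) are asserted exactly.

## Known limitations

* Policies have no learning dynamics; learning-curve shapes can only be
  emulated by switching policies across sessions.
* The arena model ignores wall thickness and treats the snout as a point;
  entry frames can differ by ±1 frame from a human-scored crossing.
* `ports_poked` semantics depend on the distinct-port reading argued above;
  raw-poke counts are recoverable from the event log if ever needed.
* The ABR path stops at the averaged waveform — no threshold estimation or
  wave latency/amplitude scoring.
* HDF5 pose I/O needs `rhdf5`; without it only the CSV dialect is
  available.
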