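# soundseekr

Simulation and analysis tools for **sound-seeking**: a freely-moving
behavioral paradigm in which a mouse explores an eight-chambered octagonal
arena to track down an ongoing sound source. One of eight wall-mounted
speakers (the *goal*) plays a stream of narrowband noise bursts until the
mouse pokes the nosepoke beneath it and earns a water reward. The paradigm
probes active hearing — how body movement supports sound localization — and
how behavior reorganizes after unilateral or bilateral conductive hearing
loss.

The package is written for behavioral neuroscientists who run (or model)
this kind of task: it covers the full computational stack from stimulus
generation to physiology preprocessing, and every stage can be exercised on
synthetic data with known ground truth.

## What it computes

**Stimulus streams.** Inter-burst intervals are i.i.d. draws from a gamma
distribution parameterized by its mean μ and standard deviation σ, so the
*repetition rate* (1/μ, bursts/s) and *irregularity* (σ, ms) are controlled
independently: shape k = (μ/σ)², scale θ = σ²/μ. Bursts are 10 ms tokens of
narrowband (3 kHz) white noise; a per-frequency calibration curve flattens
the playback path. The fixed training preset is 10 kHz, 70 dB SPL, 4 Hz,
σ = 31 ms; the variable preset draws per-trial parameters from 5–15 kHz,
65–90 dB SPL, 3–10 Hz, 1–100 ms.

**Task simulation.** The goal port is drawn uniformly with the previous goal
excluded (never the same goal twice in a row). Pluggable agent policies —
`random`, `cycling` (traplining around the ring), `direct`, and `checker`
(enter a chamber, poke only if sound is detected there, with a
hearing-state-dependent psychometric function) — generate poke logs,
chamber-visit sequences, and waypoint trajectories.

**Scoring.** Two metrics, computed after disregarding all pokes into the
previously rewarded port: the fraction of correct trials (first poke is the
goal) and the mean number of *distinct* ports poked per trial (1 = perfect,
range 1–7). Chance-level random search gives E[ports poked] = 4 and
P(correct) = 1/7 ≈ 0.143. The learning criterion is the first session with
fewer than 2.5 ports poked per trial; earlier sessions are "early", that
session onward "late".

**Trajectory analysis.** A *chamber entry* is the video frame on which the
snout keypoint crosses the internal dividers. Entries are classified as
*duplicate* (chamber already visited this trial), *cycling* (ring-adjacent
to the chamber just exited), and — after discarding duplicates and
previous-goal entries — *entry with poke* versus *entry without poke* (a
"check"). Chance level for kept entries per trial is 4.

**Startle.** The acoustic startle response is quantified from pose tracks as
the mean per-frame keypoint displacement (px/frame, averaged over body
parts), aligned to stimulus onset and averaged over the first five frames
(167 ms at 30 frames/s); 80 and 90 dB stimuli are pooled.

**ABR preprocessing.** Auditory brainstem response epochs (16 kHz sampling)
are cleaned by least-squares FIR removal of speaker cross-talk, high-passed
above 100 Hz (zero-phase), stripped of outlier epochs (union of the top 5%
by peak-to-peak excursion and by SD), and averaged with left-side responses
inverted so Wave 1 is positive for both sides.

**Synthetic data.** Generators emit pose tracks (8 keypoints, 640×480 px,
30 frames/s), event logs, startle sessions per hearing state, and ABR
recordings (template + cross-talk + noise + planted outliers), all
deterministic under a seed and all with ground truth attached.

## Worked example

```r
library(soundseekr)

# a 500-trial session of an untrained (random-search) agent
session <- simulate_session(agent_policy("random"), n_trials = 500, seed = 7)
scores  <- score_trials(session)
summarize_session(scores)
#> # A tibble: 1 × 3
#>   n_trials fraction_correct mean_ports_poked
#>      <int>            <dbl>            <dbl>
#> 1      500            0.112             4.27
```

Both metrics sit at chance (≈ 0.143 and ≈ 4). A mock learning curve — three
random-search sessions followed by three direct-navigation sessions — shows
the criterion detector at work:

```r
sessions <- lapply(1:6, function(d) {
  pol <- if (d < 4) agent_policy("random") else agent_policy("direct")
  summarize_session(score_trials(simulate_session(pol, n_trials = 100, seed = d)))
})
curve <- learning_criterion(dplyr::bind_rows(sessions))
criterion_session(curve)
#> [1] 4
```

Sessions 1–3 score ≈ 4 ports poked ("early"); from session 4 the agent is
perfect (1.0 ports poked, "late"). And the ABR pipeline on a synthetic
recording:

```r
rec <- gen_abr_recording(side = "left", seed = 11)
res <- process_abr(rec)
res
#> <abr_result> side=left, 712 epochs kept (38 rejected), polarity inverted
cor(res$waveform$uV, rec$template_epoch)
#> [1] 0.999
```

All 38 planted artifact epochs are among the rejected, and the averaged
waveform recovers the planted template almost exactly. `autoplot()` methods
exist for burst trains, parameter-performance curves, startle results and
ABR averages; `tidy()`/`glance()` give tabular access to fitted results.

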