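#' Synthetic-data generator configuration
#'
#' Bundles the ground-truth parameters for the synthetic data generators:
#' the cm-to-px affine for the arena camera (`px = px_per_cm * cm +
#' px_offset`, 640x480 frame at 30 frames/s), keypoint jitter, locomotion
#' speed, the startle response profile per hearing state, and the ABR
#' generative model (template, cross-talk FIR, noise, outlier fraction).
#'
#' @param px_per_cm Camera scale, px per cm.
#' @param px_offset Pixel coordinates of the arena center, `c(x, y)`.
#' @param jitter_px Keypoint tracking jitter SD, px.
#' @param speed_cm_s Locomotion speed along trajectory legs, cm/s.
#' @param frame_rate Video frame rate, frames/s.
#' @param keypoints Tracked body-part names (snout, head, trunk, four limbs,
#'   tail base).
#' @param startle_amplitude Named vector: startle movement amplitude
#'   (px/frame) per hearing state. Bilateral hearing loss abolishes the
#'   response.
#' @param startle_latency_frames Response latency after onset, frames.
#' @param startle_frames Response duration, frames.
#' @param baseline_step_px Baseline Brownian-wander step SD, px/frame.
#' @param abr_n_clicks Number of click repetitions per ABR recording.
#' @param abr_sample_rate ABR sampling rate, Hz.
#' @param abr_isi_ms Inter-click interval, ms.
#' @param abr_noise_sd Neural background noise SD (same units as the
#'   template).
#' @param abr_outlier_frac Fraction of epochs contaminated by large
#'   (10x-amplitude) movement artifacts.
#' @param abr_crosstalk_fir FIR through which the speaker voltage leaks into
#'   the neural channel.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(px_per_cm = 10, px_offset = c(320, 240),
                         jitter_px = 2, speed_cm_s = 15, frame_rate = 30,
                         keypoints = c("snout", "head", "trunk",
                                       "forelimb_l", "forelimb_r",
                                       "hindlimb_l", "hindlimb_r",
                                       "tail_base"),
                         startle_amplitude = c(intact = 12, sham = 12,
                                               unilateral_left = 12,
                                               unilateral_right = 12,
                                               bilateral = 0),
                         startle_latency_frames = 0, startle_frames = 5,
                         baseline_step_px = 1,
                         abr_n_clicks = 750, abr_sample_rate = 16000,
                         abr_isi_ms = 40, abr_noise_sd = 0.3,
                         abr_outlier_frac = 0.05,
                         abr_crosstalk_fir = c(0.8, -0.5, 0.3, -0.2, 0.1,
                                               -0.05)) {
  if (jitter_px < 0 || baseline_step_px < 0 || abr_noise_sd < 0) {
    abort("jitter/step/noise SDs must be >= 0")
  }
  if (any(startle_amplitude < 0)) abort("startle amplitudes must be >= 0")
  if (abr_outlier_frac < 0 || abr_outlier_frac >= 1) {
    abort("`abr_outlier_frac` must be in [0, 1)")
  }
  structure(
    list(px_per_cm = px_per_cm, px_offset = px_offset, jitter_px = jitter_px,
         speed_cm_s = speed_cm_s, frame_rate = frame_rate,
         keypoints = keypoints, startle_amplitude = startle_amplitude,
         startle_latency_frames = startle_latency_frames,
         startle_frames = startle_frames,
         baseline_step_px = baseline_step_px,
         abr_n_clicks = abr_n_clicks, abr_sample_rate = abr_sample_rate,
         abr_isi_ms = abr_isi_ms, abr_noise_sd = abr_noise_sd,
         abr_outlier_frac = abr_outlier_frac,
         abr_crosstalk_fir = abr_crosstalk_fir),
    class = "synth_config"
  )
}

# fixed body-part offsets (cm) relative to the snout; orientation is not
# modelled — only the snout drives entry detection
keypoint_offsets <- function(keypoints) {
  base <- list(
    snout = c(0, 0), head = c(-0.8, 0), trunk = c(-2.5, 0),
    forelimb_l = c(-1.5, 0.8), forelimb_r = c(-1.5, -0.8),
    hindlimb_l = c(-3, 0.8), hindlimb_r = c(-3, -0.8),
    tail_base = c(-4, 0)
  )
  missing <- setdiff(keypoints, names(base))
  for (m in missing) base[[m]] <- c(-2, 0)
  base[keypoints]
}

#' Generate a synthetic pose-tracked session
#'
#' Simulates a session with [simulate_session()], then renders the agent's
#' waypoint trajectories as a keypoint pose track at the video frame rate:
#' the snout follows the piecewise-linear path, the remaining body parts
#' trail it at fixed offsets, coordinates are mapped to pixels through the
#' config's affine, and Gaussian tracking jitter is added to every keypoint.
#' The event log is time-locked to the trajectory and the simulated session
#' (with its ground-truth visit sequences) is returned for round-trip
#' validation.
#'
#' @param policy An [agent_policy()].
#' @param arena An [arena_geometry()].
#' @param n_trials Number of trials.
#' @param config A [synth_config()].
#' @param mode Stimulus mode.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   output.
#'
#' @return List: `pose` (long px tibble `frame`, `node`, `x`, `y`),
#'   `events` (event log with `t` in s), `session` (ground truth),
#'   `transform` (`list(scale, offset)`), `frame_rate`.
#' @export
gen_pose_session <- function(policy, arena = arena_geometry(), n_trials = 20,
                             config = synth_config(),
                             mode = "fixed", seed = NULL) {
  with_seed_or_current(seed, {
    session <- simulate_session(policy, arena, n_trials, mode = mode,
                                speed_cm_s = config$speed_cm_s)
    path <- list_rbind(session$path)
    t_end <- max(path$t)
    n_frames <- ceiling(t_end * config$frame_rate) + 1L
    ft <- (seq_len(n_frames) - 1) / config$frame_rate
    sx <- approx(path$t, path$x, xout = ft, rule = 2, ties = "ordered")$y
    sy <- approx(path$t, path$y, xout = ft, rule = 2, ties = "ordered")$y
    offs <- keypoint_offsets(config$keypoints)
    rows <- lapply(seq_along(config$keypoints), function(j) {
      o <- offs[[j]]
      tibble(
        frame = seq_len(n_frames), node = config$keypoints[j],
        x = config$px_per_cm * (sx + o[1]) + config$px_offset[1] +
          rnorm(n_frames, 0, config$jitter_px),
        y = config$px_per_cm * (sy + o[2]) + config$px_offset[2] +
          rnorm(n_frames, 0, config$jitter_px)
      )
    })
    list(
      pose = list_rbind(rows),
      events = session_events(session),
      session = session,
      transform = list(scale = config$px_per_cm, offset = config$px_offset),
      frame_rate = config$frame_rate
    )
  })
}

#' Generate a synthetic startle session
#'
#' Emulates the startle assay: a mouse wanders a rectangular chamber under
#' continuous background noise while startle-eliciting bursts (80/90 dB,
#' interleaved) play at random intervals drawn uniformly from 5-30 s.
#' Baseline movement is a reflected Brownian wander of the body center with
#' all keypoints trailing at fixed offsets plus jitter. For hearing states
#' with a startle response, each onset adds a movement burst of the
#' configured amplitude for `startle_frames` frames; the bilateral profile
#' produces no burst.
#'
#' @param ear_state Hearing state (a name of `config$startle_amplitude`).
#' @param n_stimuli Number of startle stimuli (>= 1).
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#'
#' @return List: `pose` (long px tibble), `onsets` (tibble `frame`,
#'   `level_db`), `frame_rate`, `amplitude` (ground-truth response
#'   amplitude, px/frame).
#' @export
gen_startle_session <- function(ear_state = "intact", n_stimuli = 20,
                                config = synth_config(), seed = NULL) {
  if (n_stimuli < 1) abort("`n_stimuli` must be >= 1")
  if (!ear_state %in% names(config$startle_amplitude)) {
    abort("unknown `ear_state` for the startle profile")
  }
  amp <- unname(config$startle_amplitude[ear_state])
  fps <- config$frame_rate
  with_seed_or_current(seed, {
    isi_s <- runif(n_stimuli, 5, 30)
    onset_frames <- 2 * fps + cumsum(round(isi_s * fps))
    n_frames <- max(onset_frames) + 2 * fps
    levels <- rep(c(80, 90), length.out = n_stimuli)

    # reflected Brownian wander of the body center in the video frame
    box <- c(40, 600, 40, 440)
    step_x <- rnorm(n_frames, 0, config$baseline_step_px)
    step_y <- rnorm(n_frames, 0, config$baseline_step_px)
    resp <- numeric(n_frames)
    for (f0 in onset_frames) {
      i0 <- f0 + config$startle_latency_frames
      i1 <- min(i0 + config$startle_frames - 1, n_frames)
      resp[i0:i1] <- amp
    }
    theta <- runif(n_frames, 0, 2 * pi)
    step_x <- step_x + resp * cos(theta)
    step_y <- step_y + resp * sin(theta)
    reflect <- function(p, lo, hi) {
      p <- abs(p - lo) + lo
      hi - abs(hi - p)
    }
    cx <- reflect(320 + cumsum(step_x), box[1], box[2])
    cy <- reflect(240 + cumsum(step_y), box[3], box[4])

    offs <- keypoint_offsets(config$keypoints)
    rows <- lapply(seq_along(config$keypoints), function(j) {
      o <- offs[[j]] * config$px_per_cm
      tibble(
        frame = seq_len(n_frames), node = config$keypoints[j],
        x = cx + o[1] + rnorm(n_frames, 0, config$jitter_px / 4),
        y = cy + o[2] + rnorm(n_frames, 0, config$jitter_px / 4)
      )
    })
    list(pose = list_rbind(rows),
         onsets = tibble(frame = onset_frames, level_db = levels),
         frame_rate = fps, amplitude = amp)
  })
}

#' Canonical ABR template
#'
#' A stereotyped short-latency evoked waveform: three gaussian-windowed
#' oscillatory waves (Wave 1 at 1.5 ms the largest) spanning roughly the
#' first 6 ms after the click, in the spectral band that survives the 100 Hz
#' high-pass.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param dur_ms Template duration, ms.
#' @return Numeric template (peak amplitude 1).
#' @export
abr_template <- function(sample_rate = 16000, dur_ms = 8) {
  t <- seq(0, dur_ms / 1000, by = 1 / sample_rate)
  lat <- c(1.5, 2.8, 4.2) / 1000
  amp <- c(1, 0.6, 0.4)
  w <- 0.45 / 1000
  out <- numeric(length(t))
  for (i in seq_along(lat)) {
    out <- out + amp[i] * exp(-((t - lat[i])^2) / (2 * w^2)) *
      cos(2 * pi * 900 * (t - lat[i]))
  }
  out / max(abs(out))
}

#' Generate a synthetic ABR recording
#'
#' Builds a continuous paired recording at the ABR sampling rate: the speaker
#' channel carries a click train; the neural channel carries the template
#' response at each trigger (sign-flipped for left-side stimulation, matching
#' the electrode montage), plus the speaker signal leaked through the
#' cross-talk FIR, plus white noise. A configured fraction of epochs is
#' contaminated with 10x-amplitude artifacts (the planted outliers). All
#' ground truth (template, FIR, outlier indices) is returned.
#'
#' @param side `"left"` or `"right"` speaker placement.
#' @param level_dba Click level, dBA (60 or 70).
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#'
#' @return A list usable by [process_abr()]: `neural`, `speaker`,
#'   `sample_rate`, `triggers`, `side`, `level_dba`, plus ground truth
#'   `template` (canonical positive waveform), `template_epoch` (template
#'   aligned to the -2..10 ms epoch window), `outlier_epochs`, `fir`.
#' @export
gen_abr_recording <- function(side = c("right", "left"), level_dba = 70,
                              config = synth_config(), seed = NULL) {
  side <- match.arg(side)
  if (!level_dba %in% c(60, 70)) {
    warn("click level is typically 60 or 70 dBA")
  }
  fs <- config$abr_sample_rate
  n_clicks <- config$abr_n_clicks
  isi <- round(config$abr_isi_ms / 1000 * fs)
  pre <- round(0.002 * fs)
  post <- round(0.010 * fs)
  triggers <- pre + 100 + isi * (0:(n_clicks - 1))
  n <- max(triggers) + post + 100

  tmpl <- abr_template(fs)
  sign <- if (side == "left") -1 else 1
  with_seed_or_current(seed, {
    # clicks alternate polarity (condensation/rarefaction), the standard
    # way to decorrelate the stimulus artifact from the evoked response:
    # the cross-talk flips sign epoch to epoch while the response does not
    speaker <- numeric(n)
    click_len <- max(1, round(0.0001 * fs))
    for (i in seq_along(triggers)) {
      tr <- triggers[i]
      pol <- if (i %% 2 == 0) -1 else 1
      speaker[tr:(tr + click_len - 1)] <- pol
    }
    neural <- rnorm(n, 0, config$abr_noise_sd)
    for (tr in triggers) {
      idx <- tr:(tr + length(tmpl) - 1)
      neural[idx] <- neural[idx] + sign * tmpl
    }
    leak <- stats::filter(speaker, config$abr_crosstalk_fir, sides = 1)
    leak[is.na(leak)] <- 0
    neural <- neural + as.numeric(leak)

    n_out <- round(config$abr_outlier_frac * n_clicks)
    outlier_epochs <- if (n_out > 0) sort(sample.int(n_clicks, n_out))
                      else integer(0)
    for (e in outlier_epochs) {
      idx <- (triggers[e] - pre):(triggers[e] + post)
      neural[idx] <- neural[idx] + rnorm(length(idx), 0, 10)
    }
    template_epoch <- c(numeric(pre), tmpl,
                        numeric(post + 1 - length(tmpl)))
    list(neural = neural, speaker = speaker, sample_rate = fs,
         triggers = triggers, side = side, level_dba = level_dba,
         template = tmpl, template_epoch = template_epoch,
         outlier_epochs = outlier_epochs, fir = config$abr_crosstalk_fir)
  })
}
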