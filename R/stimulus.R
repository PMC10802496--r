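#' Acoustic stimulus parameter sets
#'
#' A stimulus parameter set describes one trial's noise-burst stream: a
#' narrowband noise token (center frequency, bandwidth, duration, level) played
#' as a renewal process whose inter-burst intervals follow a gamma distribution
#' with mean `1/rate` and standard deviation `irregularity`. The two presets
#' mirror the task's training variants: `"fixed"` uses the same parameters on
#' every trial (10 kHz center frequency, 3 kHz bandwidth, 10 ms bursts,
#' 70 dB SPL, 4 bursts/s, 31 ms irregularity); `"variable"` draws fresh
#' parameters per trial from the ranges 5-15 kHz, 65-90 dB SPL, 3-10 Hz and
#' 1-100 ms.
#'
#' @param center_freq_khz Center frequency of the narrowband noise, kHz.
#' @param bandwidth_khz Noise bandwidth, kHz.
#' @param burst_duration_ms Duration of each burst, ms.
#' @param level_db Sound level, dB SPL.
#' @param rate_hz Burst repetition rate, bursts per second (reciprocal of the
#'   mean inter-burst interval).
#' @param irregularity_ms Standard deviation of the inter-burst interval, ms.
#'
#' @return A one-row tibble of class `stim_params`.
#' @examples
#' stim_params()
#' @export
stim_params <- function(center_freq_khz = 10, bandwidth_khz = 3,
                        burst_duration_ms = 10, level_db = 70,
                        rate_hz = 4, irregularity_ms = 31) {
  if (rate_hz <= 0) abort("`rate_hz` must be > 0")
  if (irregularity_ms < 0) abort("`irregularity_ms` must be >= 0")
  if (bandwidth_khz <= 0) abort("`bandwidth_khz` must be > 0")
  if (burst_duration_ms <= 0) abort("`burst_duration_ms` must be > 0")
  out <- tibble(
    center_freq_khz = center_freq_khz, bandwidth_khz = bandwidth_khz,
    burst_duration_ms = burst_duration_ms, level_db = level_db,
    rate_hz = rate_hz, irregularity_ms = irregularity_ms
  )
  class(out) <- c("stim_params", class(out))
  out
}

#' Draw per-trial stimulus parameters
#'
#' In `"fixed"` mode every trial receives the fixed preset. In `"variable"`
#' mode each trial draws independently from the training ranges: center
#' frequency, repetition rate and irregularity are drawn log-uniformly (these
#' axes are naturally logarithmic) and level uniformly in dB.
#'
#' @param n Number of trials to draw parameters for.
#' @param mode `"fixed"` or `"variable"`.
#' @param seed Optional integer seed for reproducible draws.
#'
#' @return A tibble with `n` rows and the `stim_params` columns.
#' @examples
#' sample_trial_params(3, mode = "variable", seed = 1)
#' @export
sample_trial_params <- function(n = 1, mode = c("fixed", "variable"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    out <- stim_params()[rep(1L, n), ]
    return(as_tibble(out))
  }
  with_seed_or_current(seed, {
    tibble(
      center_freq_khz = exp(runif(n, log(5), log(15))),
      bandwidth_khz = 3,
      burst_duration_ms = 10,
      level_db = runif(n, 65, 90),
      rate_hz = exp(runif(n, log(3), log(10))),
      irregularity_ms = exp(runif(n, log(1), log(100)))
    )
  })
}

#' Sample gamma-distributed inter-burst intervals
#'
#' Intervals are i.i.d. gamma with mean `1/rate_hz` and standard deviation
#' `irregularity_ms / 1000`, i.e. shape \eqn{k = (\mu/\sigma)^2} and scale
#' \eqn{\theta = \sigma^2/\mu}. This parameterization lets the repetition rate
#' and the irregularity be controlled independently. `irregularity_ms = 0` is
#' the degenerate limit: a perfectly periodic train with constant interval
#' `1/rate_hz`. Sampling stops once the cumulative sum of intervals would
#' exceed `duration_s`.
#'
#' @param rate_hz Burst rate, bursts/s (> 0).
#' @param irregularity_ms SD of the inter-burst interval, ms (>= 0).
#' @param duration_s Stream duration, s (> 0).
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of intervals in seconds, cumulating to <=
#'   `duration_s`.
#' @examples
#' sample_intervals(rate_hz = 4, irregularity_ms = 31, duration_s = 5, seed = 1)
#' @export
sample_intervals <- function(rate_hz, irregularity_ms, duration_s,
                             seed = NULL) {
  if (rate_hz <= 0) abort("`rate_hz` must be > 0")
  if (irregularity_ms < 0) abort("`irregularity_ms` must be >= 0")
  if (duration_s <= 0) abort("`duration_s` must be > 0")
  mu <- 1 / rate_hz
  sigma <- irregularity_ms / 1000
  if (sigma == 0) {
    n <- floor(duration_s / mu)
    return(rep(mu, n))
  }
  shape <- (mu / sigma)^2
  scale <- sigma^2 / mu
  with_seed_or_current(seed, {
    # draw in blocks until the cumulative time covers the stream
    out <- numeric(0)
    total <- 0
    block <- max(16L, ceiling(1.5 * duration_s * rate_hz))
    while (total < duration_s) {
      draws <- rgamma(block, shape = shape, scale = scale)
      out <- c(out, draws)
      total <- total + sum(draws)
    }
    keep <- cumsum(out) <= duration_s
    out[keep]
  })
}

#' Generate a burst train
#'
#' Realizes the renewal process for one stimulus stream: burst onset times are
#' the cumulative sums of gamma inter-burst intervals, with the first burst at
#' the first interval (the stream conceptually starts mid-process).
#'
#' @param params A `stim_params` row (or one-row tibble with its columns).
#' @param duration_s Stream duration in seconds.
#' @param seed Optional integer seed.
#'
#' @return A `burst_train` object: a tibble with column `onset_s` (strictly
#'   increasing, all in `[0, duration_s)`), with the parameters and duration
#'   stored as attributes `params` and `duration_s`.
#' @examples
#' burst_train(stim_params(), duration_s = 10, seed = 1)
#' @export
burst_train <- function(params = stim_params(), duration_s = 10, seed = NULL) {
  iv <- sample_intervals(params$rate_hz, params$irregularity_ms, duration_s,
                         seed = seed)
  onsets <- cumsum(iv)
  onsets <- onsets[onsets < duration_s]
  out <- tibble(onset_s = onsets)
  attr(out, "params") <- params
  attr(out, "duration_s") <- duration_s
  class(out) <- c("burst_train", class(out))
  out
}

# RMS amplitude (digital full scale) for a level in dB SPL, under the
# convention that a full-scale sine corresponds to `ref_db_spl`.
level_to_rms <- function(level_db, ref_db_spl = 94) {
  (1 / sqrt(2)) * 10^((level_db - ref_db_spl) / 20)
}

#' Synthesize a single narrowband noise burst
#'
#' White noise band-pass filtered to `center_freq_khz +/- bandwidth_khz/2`
#' with a zero-phase Butterworth filter, shaped with raised-cosine on/off
#' ramps (`ramp_ms`, default 1 ms) to limit spectral splatter, and scaled so
#' its RMS corresponds to `level_db` under a full-scale-sine = `ref_db_spl`
#' reference.
#'
#' @param params A `stim_params` row.
#' @param sample_rate Output sample rate, Hz. Must exceed twice the upper band
#'   edge.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   bursts.
#' @param ramp_ms Raised-cosine ramp duration, ms.
#' @param ref_db_spl Level mapping reference: dB SPL assigned to a digital
#'   full-scale sine.
#'
#' @return Numeric waveform of `round(burst_duration_ms/1000 * sample_rate)`
#'   samples.
#' @examples
#' w <- synth_burst(stim_params(), sample_rate = 192000, seed = 1)
#' length(w)
#' @export
synth_burst <- function(params = stim_params(), sample_rate = 192000,
                        seed = NULL, ramp_ms = 1, ref_db_spl = 94) {
  f_hi <- (params$center_freq_khz + params$bandwidth_khz / 2) * 1000
  f_lo <- (params$center_freq_khz - params$bandwidth_khz / 2) * 1000
  if (sample_rate <= 2 * f_hi) {
    abort("`sample_rate` must exceed twice the upper band edge (Nyquist)")
  }
  n <- round(params$burst_duration_ms / 1000 * sample_rate)
  if (n < 1) abort("`burst_duration_ms` too short for one sample")
  pad <- max(256L, n)
  bf <- signal::butter(4, c(f_lo, f_hi) / (sample_rate / 2), type = "pass")
  w <- with_seed_or_current(seed, {
    noise <- rnorm(n + 2 * pad)
    filtered <- signal::filtfilt(bf, noise)
    filtered[(pad + 1):(pad + n)]
  })
  # raised-cosine ramps
  nr <- min(round(ramp_ms / 1000 * sample_rate), floor(n / 2))
  if (nr > 0) {
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    w[seq_len(nr)] <- w[seq_len(nr)] * ramp
    w[(n - nr + 1):n] <- w[(n - nr + 1):n] * rev(ramp)
  }
  rms <- sqrt(mean(w^2))
  if (rms > 0) w <- w * level_to_rms(params$level_db, ref_db_spl) / rms
  w
}

#' Render a burst train to a waveform
#'
#' Places one synthesized burst at every onset of the train, over a silent
#' background. Bursts whose inter-onset interval is shorter than the burst
#' duration overlap; overlapping bursts are summed (with a warning) rather
#' than truncated, preserving the train statistics.
#'
#' @param train A [burst_train()] object.
#' @param sample_rate Sample rate, Hz.
#' @param seed Optional integer seed (each burst is an independent noise
#'   token).
#'
#' @return Numeric waveform of `duration_s * sample_rate` samples.
#' @export
render_stream <- function(train, sample_rate = 192000, seed = NULL) {
  params <- attr(train, "params")
  duration_s <- attr(train, "duration_s")
  if (is.null(params) || is.null(duration_s)) {
    abort("`train` must be a `burst_train` with params/duration attributes")
  }
  n_total <- round(duration_s * sample_rate)
  wave <- numeric(n_total)
  onsets <- train$onset_s
  if (length(onsets) == 0) return(wave)
  if (any(diff(onsets) < params$burst_duration_ms / 1000)) {
    warn("overlapping bursts (interval < burst duration): summing waveforms")
  }
  with_seed_or_current(seed, {
    for (t0 in onsets) {
      b <- synth_burst(params, sample_rate)
      i0 <- round(t0 * sample_rate) + 1L
      i1 <- min(i0 + length(b) - 1L, n_total)
      if (i1 >= i0) wave[i0:i1] <- wave[i0:i1] + b[seq_len(i1 - i0 + 1L)]
    }
  })
  wave
}

#' Synthesize the error feedback sound
#'
#' Incorrect pokes trigger a dissonant two-tone "tritone": the base frequency
#' plus the note six semitones above it (frequency ratio `2^(6/12)`). Levels
#' follow the same full-scale-sine reference as [synth_burst()].
#'
#' @param base_freq_khz Base frequency, kHz (the task uses 8 kHz).
#' @param duration_ms Sound duration, ms.
#' @param level_db Level, dB SPL.
#' @param sample_rate Sample rate, Hz.
#' @param ramp_ms Raised-cosine ramp, ms.
#' @param ref_db_spl Level-mapping reference.
#' @return Numeric waveform.
#' @export
synth_error_sound <- function(base_freq_khz = 8, duration_ms = 250,
                              level_db = 70, sample_rate = 192000,
                              ramp_ms = 1, ref_db_spl = 94) {
  f1 <- base_freq_khz * 1000
  f2 <- f1 * 2^(6 / 12)
  if (sample_rate <= 2 * f2) abort("`sample_rate` too low for the tritone")
  t <- seq_len(round(duration_ms / 1000 * sample_rate)) / sample_rate
  w <- sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)
  nr <- min(round(ramp_ms / 1000 * sample_rate), floor(length(w) / 2))
  if (nr > 0) {
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    w[seq_len(nr)] <- w[seq_len(nr)] * ramp
    w[(length(w) - nr + 1):length(w)] <- tail(w, nr) * rev(ramp)
  }
  w * level_to_rms(level_db, ref_db_spl) / sqrt(mean(w^2))
}

#' @export
autoplot.burst_train <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$onset_s)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$onset_s, y = 0, yend = 1)) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Noise-burst onsets") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
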