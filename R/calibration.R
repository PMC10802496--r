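#' Fit a per-frequency calibration curve
#'
#' Given the measured power spectrum of the audio signal path (white-noise
#' test signal recorded at the arena center), computes the dB correction
#' needed at each frequency to reach a uniform spectrum: the gain is the
#' difference between a flat target level (the mean measured dB level over the
#' grid, by default) and the measured level at each frequency.
#'
#' @param measured_spectrum A data frame with columns `freq_khz` and either
#'   `power_db` or linear `power` (> 0, converted via `10*log10`).
#' @param target_db Target flat level in dB; default the mean measured level.
#'
#' @return A `calibration_curve`: tibble with columns `freq_khz`, `gain_db`.
#' @examples
#' spec <- tibble::tibble(freq_khz = 5:20, power_db = 0)
#' fit_calibration(spec)
#' @export
fit_calibration <- function(measured_spectrum, target_db = NULL) {
  stopifnot(is.data.frame(measured_spectrum))
  if (!"freq_khz" %in% names(measured_spectrum)) {
    abort("`measured_spectrum` needs a `freq_khz` column")
  }
  if ("power_db" %in% names(measured_spectrum)) {
    level <- measured_spectrum$power_db
  } else if ("power" %in% names(measured_spectrum)) {
    if (any(measured_spectrum$power <= 0)) {
      abort("measured power must be strictly positive")
    }
    level <- 10 * log10(measured_spectrum$power)
  } else {
    abort("`measured_spectrum` needs a `power_db` or `power` column")
  }
  if (any(!is.finite(level))) abort("measured spectrum must be finite")
  target_db <- target_db %||% mean(level)
  out <- tibble(freq_khz = measured_spectrum$freq_khz,
                gain_db = target_db - level)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Apply a calibration curve to a waveform
#'
#' Applies the per-frequency dB gains as a zero-phase FFT-domain filter:
#' the gain is interpolated onto the waveform's frequency grid (held at its
#' edge values outside the curve's range), applied to the magnitude spectrum,
#' and the waveform reconstructed by inverse FFT.
#'
#' @param waveform Numeric signal.
#' @param curve A [fit_calibration()] result.
#' @param sample_rate Sample rate of `waveform`, Hz.
#'
#' @return The corrected waveform (same length).
#' @export
apply_calibration <- function(waveform, curve, sample_rate) {
  n <- length(waveform)
  if (n == 0) return(waveform)
  freqs <- seq(0, n - 1) / n * sample_rate
  freqs <- ifelse(freqs > sample_rate / 2, sample_rate - freqs, freqs)
  g <- approx(curve$freq_khz * 1000, curve$gain_db, xout = freqs,
              rule = 2)$y
  spec <- fft(waveform) * 10^(g / 20)
  Re(fft(spec, inverse = TRUE)) / n
}

#' Estimate a smoothed power spectrum
#'
#' Welch-style estimate: the signal is split into `n_segments` non-overlapping
#' Hann-windowed segments whose periodograms are averaged. Used to measure the
#' signal path during calibration.
#'
#' @param waveform Numeric signal.
#' @param sample_rate Sample rate, Hz.
#' @param n_segments Number of segments to average.
#'
#' @return Tibble with columns `freq_khz`, `power` (linear), `power_db`.
#' @export
estimate_spectrum <- function(waveform, sample_rate, n_segments = 16) {
  n <- length(waveform)
  seg_len <- floor(n / n_segments)
  if (seg_len < 8) abort("waveform too short for the requested segmentation")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  half <- floor(seg_len / 2)
  acc <- numeric(half)
  for (k in seq_len(n_segments)) {
    seg <- waveform[((k - 1) * seg_len + 1):(k * seg_len)] * win
    p <- Mod(fft(seg))^2
    acc <- acc + p[2:(half + 1)]
  }
  acc <- acc / n_segments
  tibble(
    freq_khz = (seq_len(half)) / seg_len * sample_rate / 1000,
    power = acc,
    power_db = 10 * log10(acc)
  )
}

#' Write a calibration curve or burst train to CSV
#'
#' @param x A `calibration_curve` or `burst_train`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_soundseek_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a waveform as a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' mono. Values are expected in `[-1, 1]`; PCM output is clipped.
#'
#' @param waveform Numeric signal in `[-1, 1]`.
#' @param path Output path.
#' @param sample_rate Sample rate, Hz.
#' @param bit_depth 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = 192000, bit_depth = 16) {
  if (!bit_depth %in% c(16, 32)) abort("`bit_depth` must be 16 or 32")
  n <- length(waveform)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    x <- pmin(pmax(waveform, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}
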