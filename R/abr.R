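#' Remove speaker cross-talk from a neural recording
#'
#' The amplifier picks up some of the speaker drive voltage on the neural
#' channel. The contamination is modelled as a causal FIR filter of the
#' speaker signal: the filter is fit by least squares (regressing the neural
#' voltage on the lagged speaker voltage) and its prediction subtracted. As a
#' least-squares projection this can never increase the residual power.
#'
#' @param neural Neural voltage series.
#' @param speaker Simultaneously recorded speaker voltage (same length).
#' @param filter_len FIR length in taps (default 32, i.e. 2 ms at 16 kHz).
#'
#' @return The cleaned neural series, with the fitted filter in attribute
#'   `fir`.
#' @export
remove_crosstalk <- function(neural, speaker, filter_len = 32) {
  n <- length(neural)
  if (length(speaker) != n) abort("`neural` and `speaker` lengths differ")
  if (filter_len < 1) abort("`filter_len` must be >= 1")
  if (sd(speaker) == 0) {
    warn("speaker channel has zero variance; nothing to remove")
    return(neural)
  }
  X <- matrix(0, n, filter_len)
  for (k in seq_len(filter_len)) {
    X[k:n, k] <- speaker[seq_len(n - k + 1)]
  }
  fit <- stats::.lm.fit(X, neural)
  cleaned <- neural - X %*% fit$coefficients
  out <- as.numeric(cleaned)
  attr(out, "fir") <- fit$coefficients
  out
}

#' Zero-phase high-pass filter
#'
#' Butterworth high-pass applied forward and backward
#' (zero phase), removing drift and other low-frequency components below the
#' cutoff. ABR preprocessing uses a 100 Hz cutoff.
#'
#' @param x Signal.
#' @param sample_rate Sample rate, Hz.
#' @param cutoff Cutoff frequency, Hz (< Nyquist).
#' @param order Butterworth order per pass (applied twice).
#' @return Filtered signal.
#' @export
highpass <- function(x, sample_rate, cutoff = 100, order = 2) {
  if (cutoff >= sample_rate / 2) abort("`cutoff` must be below Nyquist")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "high")
  n <- length(x)
  # odd-reflection padding suppresses the forward-backward edge transients
  p <- min(n - 1, 3 * ceiling(sample_rate / cutoff))
  if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    as.numeric(signal::filtfilt(bf, xp))[(p + 1):(p + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Cut trigger-aligned epochs from a continuous recording
#'
#' @param x Continuous signal.
#' @param triggers Click onset sample indices (1-based, strictly increasing).
#' @param sample_rate Sample rate, Hz.
#' @param pre_ms,post_ms Epoch window around each trigger, ms.
#' @return Matrix, one row per epoch; attributes `time_ms` (epoch-relative
#'   time axis) and `triggers_used`. Triggers whose window exceeds the record
#'   are skipped with a warning.
#' @export
extract_epochs <- function(x, triggers, sample_rate, pre_ms = 2,
                           post_ms = 10) {
  if (is.unsorted(triggers, strictly = TRUE)) {
    abort("`triggers` must be strictly increasing")
  }
  pre <- round(pre_ms / 1000 * sample_rate)
  post <- round(post_ms / 1000 * sample_rate)
  ok <- triggers - pre >= 1 & triggers + post <= length(x)
  if (any(!ok)) warn(sprintf("%d trigger(s) too close to record edge; skipped",
                             sum(!ok)))
  triggers <- triggers[ok]
  if (length(triggers) < 2) abort("need >= 2 usable epochs")
  epochs <- t(vapply(triggers, function(tr) x[(tr - pre):(tr + post)],
                     numeric(pre + post + 1)))
  attr(epochs, "time_ms") <- seq(-pre, post) / sample_rate * 1000
  attr(epochs, "triggers_used") <- triggers
  epochs
}

#' Reject outlier epochs
#'
#' Discards the union of the top 5% of epochs by peak-to-peak voltage
#' excursion and the top 5% by per-epoch standard deviation. The count per
#' rule is `ceiling(prop * n)`; ties are broken by epoch index, keeping
#' earlier epochs.
#'
#' @param epochs Epoch matrix (rows = epochs).
#' @param prop Proportion rejected per rule.
#' @return List: `kept` (matrix of surviving epochs), `report` (tibble
#'   `epoch`, `excursion`, `sd`, `by_excursion`, `by_sd`, `rejected`).
#' @export
reject_outliers <- function(epochs, prop = 0.05) {
  n <- nrow(epochs)
  if (is.null(n) || n < 2) abort("need >= 2 epochs")
  excursion <- apply(epochs, 1, function(e) diff(range(e)))
  sds <- apply(epochs, 1, sd)
  k <- ceiling(prop * n)
  top_by <- function(metric) {
    # decreasing metric; ties resolved toward later epochs being rejected
    ord <- order(-metric, -seq_len(n))
    sort(ord[seq_len(k)])
  }
  rej_exc <- top_by(excursion)
  rej_sd <- top_by(sds)
  rejected <- sort(union(rej_exc, rej_sd))
  report <- tibble(
    epoch = seq_len(n), excursion = excursion, sd = sds,
    by_excursion = seq_len(n) %in% rej_exc,
    by_sd = seq_len(n) %in% rej_sd,
    rejected = seq_len(n) %in% rejected
  )
  list(kept = epochs[-rejected, , drop = FALSE], report = report)
}

#' Average ABR epochs with polarity correction
#'
#' Averages the kept epochs over a fixed window around the trigger. Because
#' the non-inverting electrode sits at the left ear, Wave 1 is negative for
#' left-side stimulation; responses to sounds from the left are inverted so
#' that Wave 1 is expected positive for both sides.
#'
#' @param epochs Epoch matrix (rows = epochs), e.g. [reject_outliers()]'s
#'   `kept`.
#' @param side `"left"` or `"right"` speaker position.
#' @param n_rejected Number of epochs rejected upstream (bookkeeping).
#' @return An `abr_result`: list with `waveform` (tibble `time_ms`, `uV`),
#'   `n_epochs_kept`, `n_rejected`, `polarity_applied`, `side`.
#' @export
average_abr <- function(epochs, side = c("right", "left"), n_rejected = 0) {
  side <- match.arg(side)
  if (is.null(nrow(epochs)) || nrow(epochs) == 0) abort("no epochs to average")
  avg <- colMeans(epochs)
  invert <- side == "left"
  if (invert) avg <- -avg
  tm <- attr(epochs, "time_ms") %||% seq_along(avg)
  structure(
    list(
      waveform = tibble(time_ms = tm, uV = avg),
      n_epochs_kept = nrow(epochs), n_rejected = n_rejected,
      polarity_applied = invert, side = side
    ),
    class = "abr_result"
  )
}

#' Full ABR preprocessing pipeline
#'
#' Runs the preprocessing chain on a raw recording: speaker cross-talk
#' removal ([remove_crosstalk()]), zero-phase high-pass above 100 Hz
#' ([highpass()]), trigger-aligned epoching ([extract_epochs()]), top-5%
#' outlier rejection ([reject_outliers()]), and polarity-corrected averaging
#' ([average_abr()]).
#'
#' @param recording List with elements `neural`, `speaker`, `sample_rate`,
#'   `triggers`, `side` (and optionally `level_dba`), e.g. from
#'   [gen_abr_recording()].
#' @param filter_len Cross-talk FIR length, taps.
#' @param cutoff High-pass cutoff, Hz.
#' @param pre_ms,post_ms Epoch window, ms.
#' @param prop Outlier proportion per rejection rule.
#' @return An `abr_result` with the rejection `report` attached.
#' @export
process_abr <- function(recording, filter_len = 32, cutoff = 100,
                        pre_ms = 2, post_ms = 10, prop = 0.05) {
  cleaned <- remove_crosstalk(recording$neural, recording$speaker, filter_len)
  filtered <- highpass(cleaned, recording$sample_rate, cutoff)
  epochs <- extract_epochs(filtered, recording$triggers,
                           recording$sample_rate, pre_ms, post_ms)
  tm <- attr(epochs, "time_ms")
  rej <- reject_outliers(epochs, prop)
  attr(rej$kept, "time_ms") <- tm
  out <- average_abr(rej$kept, side = recording$side,
                     n_rejected = sum(rej$report$rejected))
  out$report <- rej$report
  out
}

#' @export
print.abr_result <- function(x, ...) {
  cat(sprintf(
    "<abr_result> side=%s, %d epochs kept (%d rejected)%s\n",
    x$side, x$n_epochs_kept, x$n_rejected,
    if (x$polarity_applied) ", polarity inverted" else ""
  ))
  invisible(x)
}

#' @export
tidy.abr_result <- function(x, ...) x$waveform

#' @export
glance.abr_result <- function(x, ...) {
  tibble(side = x$side, n_epochs_kept = x$n_epochs_kept,
         n_rejected = x$n_rejected, polarity_applied = x$polarity_applied,
         peak_uV = max(x$waveform$uV))
}

#' @export
autoplot.abr_result <- function(object, ...) {
  ggplot2::ggplot(object$waveform,
                  ggplot2::aes(x = .data$time_ms, y = .data$uV)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from click (ms)", y = expression(mu * V),
                  title = sprintf("Averaged ABR (%s side, n = %d)",
                                  object$side, object$n_epochs_kept)) +
    ggplot2::theme_minimal()
}
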