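#' Per-frame movement speed from a pose track
#'
#' The movement measure underlying startle quantification: for each frame,
#' the Euclidean distance moved by each body part since the previous frame,
#' averaged across all body parts. Keypoints missing on either of the two
#' frames are excluded from that frame's mean.
#'
#' @param track Long pose tibble (`frame`, `node`, `x`, `y`), px.
#' @return Tibble `frame`, `speed` (px/frame); the first frame has no
#'   preceding frame and so `speed = NA`.
#' @examples
#' tr <- tibble::tibble(frame = rep(1:3, 2), node = rep(c("snout", "tail"), each = 3),
#'                      x = c(0, 3, 6, 0, 3, 6), y = c(0, 4, 8, 0, 4, 8))
#' movement_speed(tr)
#' @export
movement_speed <- function(track) {
  frames <- sort(unique(track$frame))
  if (length(frames) < 2) abort("need at least 2 frames")
  wide <- track |>
    arrange(.data$frame) |>
    tidyr::pivot_wider(names_from = "node", values_from = c("x", "y"),
                       id_cols = "frame")
  xs <- as.matrix(wide[grep("^x_", names(wide))])
  ys <- as.matrix(wide[grep("^y_", names(wide))])
  if (ncol(xs) < 1) abort("need at least 1 keypoint")
  dx <- diff(xs)
  dy <- diff(ys)
  disp <- sqrt(dx^2 + dy^2)
  speed <- rowMeans(disp, na.rm = TRUE)
  speed[is.nan(speed)] <- NA_real_
  tibble(frame = wide$frame, speed = c(NA_real_, speed))
}

#' Align movement speed to stimulus onsets and quantify startle
#'
#' Cuts the speed series around each startle-eliciting stimulus and
#' quantifies the response as the mean movement speed over the first
#' `window` frames from the onset frame on (5 frames at 30 frames/s spans
#' 167 ms). The session magnitude is the mean over stimuli; 80 and 90 dB
#' stimuli are pooled indiscriminately, as behavior does not differ between
#' them. Onsets too close to the end of the track are skipped with a
#' warning.
#'
#' @param speed Speed tibble from [movement_speed()] (or a numeric vector).
#' @param onsets Onset tibble (`frame`, optional `level_db`) or a frame
#'   vector.
#' @param window Response window length, frames (>= 1).
#' @param baseline_frames Frames before onset used for the optional baseline
#'   mean reported per stimulus (raw magnitude remains the primary measure).
#'
#' @return A `startle_result`: list with `per_stimulus` (tibble `onset`,
#'   `level_db`, `magnitude`, `baseline`), `traces` (long tibble `stimulus`,
#'   `rel_frame`, `speed`), and session `magnitude`. [tidy()] returns the
#'   per-stimulus table, [glance()] the session magnitude.
#' @export
align_and_magnitude <- function(speed, onsets, window = 5,
                                baseline_frames = 5) {
  if (window < 1) abort("`window` must be >= 1")
  if (is.data.frame(speed)) {
    v <- speed$speed[order(speed$frame)]
  } else {
    v <- as.numeric(speed)
  }
  if (!is.data.frame(onsets)) onsets <- tibble(frame = as.integer(onsets))
  if (!"level_db" %in% names(onsets)) onsets$level_db <- NA_real_
  n <- length(v)
  rows <- list()
  traces <- list()
  skipped <- 0L
  for (i in seq_len(nrow(onsets))) {
    f0 <- onsets$frame[i]
    if (f0 < 1 || f0 + window - 1 > n) {
      skipped <- skipped + 1L
      next
    }
    win <- v[f0:(f0 + window - 1)]
    b0 <- max(1, f0 - baseline_frames)
    base <- if (f0 > 1) mean(v[b0:(f0 - 1)], na.rm = TRUE) else NA_real_
    rows[[i]] <- tibble(onset = f0, level_db = onsets$level_db[i],
                        magnitude = mean(win, na.rm = TRUE),
                        baseline = base)
    lo <- max(1, f0 - baseline_frames)
    seg <- v[lo:min(n, f0 + 2 * window)]
    traces[[i]] <- tibble(stimulus = i,
                          rel_frame = seq(lo - f0, by = 1,
                                          length.out = length(seg)),
                          speed = seg)
  }
  if (skipped > 0) {
    warn(sprintf("%d onset(s) too close to the track end; skipped", skipped))
  }
  per_stimulus <- list_rbind(rows)
  if (nrow(per_stimulus) == 0) abort("no usable onsets")
  structure(
    list(per_stimulus = per_stimulus, traces = list_rbind(traces),
         magnitude = mean(per_stimulus$magnitude), window = window),
    class = "startle_result"
  )
}

#' @export
print.startle_result <- function(x, ...) {
  cat(sprintf(
    "<startle_result> %d stimuli, session magnitude %.2f px/frame (window %d frames)\n",
    nrow(x$per_stimulus), x$magnitude, x$window
  ))
  invisible(x)
}

#' @export
tidy.startle_result <- function(x, ...) x$per_stimulus

#' @export
glance.startle_result <- function(x, ...) {
  tibble(n_stimuli = nrow(x$per_stimulus), magnitude = x$magnitude,
         window = x$window)
}

#' @export
autoplot.startle_result <- function(object, ...) {
  avg <- object$traces |>
    group_by(.data$rel_frame) |>
    summarise(speed = mean(.data$speed, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$rel_frame, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "frames from stimulus onset", y = "speed (px/frame)",
                  title = "Startle-aligned movement speed") +
    ggplot2::theme_minimal()
}
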