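#' Detect chamber entries from a pose track
#'
#' A chamber entry is the video frame on which the snout passes the internal
#' dividers: the first frame the snout keypoint lies inside a chamber polygon
#' after having been in the central region. The visit ends when the snout
#' returns to the center; re-crossings of the same divider within the
#' debounce window (default 3 frames, 100 ms at 30 frames/s) are merged into
#' the prior visit so tracking jitter at a divider does not double-count.
#' Missing snout samples are linearly interpolated up to `max_gap` frames;
#' longer gaps leave the frames unclassified.
#'
#' @param track Pose track: long tibble with columns `frame`, `node`, `x`,
#'   `y` (a `"snout"` node is required). Coordinates in cm (arena frame), or
#'   px with `transform` supplied.
#' @param arena An [arena_geometry()].
#' @param transform Optional px-to-cm affine, `list(scale, offset)` with
#'   `px = scale * cm + offset`; applied inversely to the track.
#' @param debounce_frames Center frames required to end a visit.
#' @param max_gap Longest missing-sample gap (frames) to interpolate.
#'
#' @return Tibble of visits: `entry_frame`, `exit_frame`, `chamber`.
#' @export
detect_entries <- function(track, arena, transform = NULL,
                           debounce_frames = 3, max_gap = 5) {
  snout <- filter(track, .data$node == "snout") |> arrange(.data$frame)
  if (nrow(snout) == 0) abort("track has no `snout` keypoint")
  frames <- seq(min(snout$frame), max(snout$frame))
  x <- rep(NA_real_, length(frames))
  y <- rep(NA_real_, length(frames))
  idx <- match(snout$frame, frames)
  x[idx] <- snout$x
  y[idx] <- snout$y
  if (all(is.na(x))) abort("snout coordinates all missing")
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap)
    y <- zoo::na.approx(y, na.rm = FALSE, maxgap = max_gap)
  }
  if (!is.null(transform)) {
    x <- (x - transform$offset[1]) / transform$scale
    y <- (y - transform$offset[2]) / transform$scale
  }
  reg <- assign_region(x, y, arena)
  reg[is.na(reg) | is.na(x)] <- -1L  # center / unclassifiable

  # merge brief center excursions flanked by the same chamber (debounce)
  repeat {
    r <- rle(reg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$values == -1L & r$lengths < debounce_frames)
    short <- short[short > 1 & short < length(r$values)]
    short <- short[r$values[short - 1] == r$values[short + 1] &
                     r$values[short - 1] >= 0]
    if (length(short) == 0) break
    for (i in short) reg[starts[i]:ends[i]] <- r$values[i - 1]
  }

  r <- rle(reg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0
  tibble(
    entry_frame = frames[starts[keep]],
    exit_frame = frames[ends[keep]],
    chamber = as.integer(r$values[keep])
  )
}

#' Classify chamber entries
#'
#' Applies the entry taxonomy to one trial's visit sequence:
#'
#' * *duplicate*: re-entering a chamber already visited on the same trial;
#' * *cycling*: entering a chamber ring-adjacent to the one just exited (the
#'   first entry of a trial is never cycling);
#' * *previous-goal*: entry into the previously rewarded chamber;
#' * *with poke* / *without poke (check)*: after discarding duplicates and
#'   previous-goal entries, kept entries divide into those that culminate in
#'   a poke of that chamber's port and those that do not.
#'
#' A poke counts for the visit during which it occurs (between that entry and
#' the next, or the trial end). If a poke lands on a discarded duplicate
#' visit, the default `"first_entry"` attribution marks the kept first entry
#' of that chamber as with-poke, honoring both additivity and the reading
#' that the chamber's entry "eventually culminated" in a poke;
#' `"own_visit"` leaves the poke on the duplicate visit instead.
#'
#' @param entries Visit tibble (from [detect_entries()] or a simulator trial):
#'   columns `chamber` and an entry time — `t` (s) or `entry_frame`.
#' @param pokes Poke tibble with columns `t` (s, or `frame`) and `port`.
#' @param goal,prev_goal Goal and previous-goal port ids (`prev_goal` may be
#'   `NA`).
#' @param arena An [arena_geometry()].
#' @param frame_rate Frames/s, used when times are given as frames.
#' @param attribution `"first_entry"` or `"own_visit"` (see above).
#'
#' @return List with `entries` (flagged tibble: adds `is_duplicate`,
#'   `is_cycling`, `is_prev_goal`, `with_poke`, `is_check`) and `metrics`
#'   (one-row tibble: `n_entries`, `n_duplicate`, `n_cycling`,
#'   `n_entries_kept`, `n_with_poke`, `n_without_poke`).
#' @export
classify_entries <- function(entries, pokes, goal, prev_goal = NA,
                             arena = arena_geometry(), frame_rate = 30,
                             attribution = c("first_entry", "own_visit")) {
  attribution <- match.arg(attribution)
  n <- nrow(entries)
  # frame f covers time (f - 1) / frame_rate (frame 1 is t = 0)
  t_entry <- if ("t" %in% names(entries)) entries$t
             else (entries$entry_frame - 1) / frame_rate
  t_poke <- if ("t" %in% names(pokes)) pokes$t
            else (pokes$frame - 1) / frame_rate
  if (is.unsorted(t_entry)) abort("`entries` must be time-ordered")
  ch <- entries$chamber

  if (any(!pokes$port %in% ch)) {
    warn("poke(s) into port(s) with no detected chamber entry")
  }

  is_dup <- duplicated(ch)
  is_cyc <- c(FALSE, is_adjacent(ch[-1], ch[-n], arena))
  if (n == 1) is_cyc <- FALSE
  is_prev <- if (is.na(prev_goal)) rep(FALSE, n) else ch == prev_goal

  t_next <- c(t_entry[-1], Inf)
  with_poke <- vapply(seq_len(n), function(i) {
    any(t_poke >= t_entry[i] & t_poke < t_next[i] & pokes$port == ch[i])
  }, logical(1))

  if (attribution == "first_entry" && n > 0) {
    for (c_id in unique(ch[with_poke])) {
      first_i <- which(ch == c_id)[1]
      with_poke[first_i] <- TRUE
    }
  }

  kept <- !is_dup & !is_prev
  flagged <- entries |>
    mutate(
      is_duplicate = is_dup, is_cycling = is_cyc, is_prev_goal = is_prev,
      with_poke = with_poke, is_check = kept & !with_poke
    )
  metrics <- tibble(
    n_entries = n,
    n_duplicate = sum(is_dup),
    n_cycling = sum(is_cyc),
    n_entries_kept = sum(kept),
    n_with_poke = sum(kept & with_poke),
    n_without_poke = sum(kept & !with_poke)
  )
  list(entries = flagged, metrics = metrics)
}

#' Run the entry pipeline over a whole pose session
#'
#' Splits a session-long pose track into trial windows using the event log
#' (`trial_start` to `reward`), detects entries within each window, and
#' classifies them against the trial's pokes and goals. Entries outside any
#' trial window (e.g. during the inter-trial delay) are dropped.
#'
#' @param pose Long pose tibble (`frame`, `node`, `x`, `y`).
#' @param events Event-log tibble from [session_events()].
#' @param arena An [arena_geometry()].
#' @param frame_rate Video frame rate, frames/s.
#' @param transform Optional px-to-cm affine (see [detect_entries()]).
#' @param ... Passed to [detect_entries()] and [classify_entries()].
#'
#' @return List with `entries` (flagged visits, all trials, with `trial`
#'   column) and `metrics` (per-trial metric tibble with `trial`, `goal`,
#'   `prev_goal`).
#' @export
session_entry_metrics <- function(pose, events, arena = arena_geometry(),
                                  frame_rate = 30, transform = NULL, ...) {
  visits <- detect_entries(pose, arena, transform = transform)
  visits$t <- (visits$entry_frame - 1) / frame_rate

  rewards <- filter(events, .data$type == "reward") |> arrange(.data$trial)
  starts <- filter(events, .data$type == "trial_start") |> arrange(.data$trial)
  goals <- rewards$port
  prev_goals <- lag(goals)

  ent_rows <- list()
  met_rows <- list()
  for (i in seq_len(nrow(rewards))) {
    w0 <- starts$t[i]
    w1 <- rewards$t[i]
    in_win <- visits$t >= w0 & visits$t <= w1 + 0.5 / frame_rate
    trial_visits <- visits[in_win, ]
    pokes <- filter(events, .data$type == "poke", .data$trial == i)
    if (nrow(trial_visits) == 0) next
    cl <- classify_entries(trial_visits, pokes, goals[i], prev_goals[i],
                           arena, frame_rate = frame_rate, ...)
    ent_rows[[i]] <- mutate(cl$entries, trial = i)
    met_rows[[i]] <- mutate(cl$metrics, trial = i, goal = goals[i],
                            prev_goal = prev_goals[i])
  }
  list(entries = list_rbind(ent_rows), metrics = list_rbind(met_rows))
}

#' Chance level of kept entries per trial
#'
#' Expected number of kept chamber entries (duplicates and previous-goal
#' entries discarded) for an agent searching the chambers in uniformly random
#' order. With the previous goal excluded there are `n_chambers - 1` eligible
#' chambers and the goal's visit rank is uniform on `1..(n_chambers-1)`, so
#' the exact expectation is `n_chambers / 2` — 4 in the eight-chamber arena.
#'
#' @param n_chambers Number of chambers.
#' @param method `"enumeration"` (exact) or `"monte_carlo"`.
#' @param n Monte-Carlo sample size.
#' @param seed Optional seed for the Monte-Carlo estimate.
#' @return Expected kept entries per trial.
#' @examples
#' entries_chance_level(8)
#' @export
entries_chance_level <- function(n_chambers = 8,
                                 method = c("enumeration", "monte_carlo"),
                                 n = 1e5, seed = NULL) {
  method <- match.arg(method)
  m <- n_chambers - 1  # eligible chambers (previous goal excluded)
  if (m < 1) abort("`n_chambers` must be >= 2")
  if (method == "enumeration") return(mean(seq_len(m)))
  # simulate random visit orders: the goal's visit rank is where search stops
  with_seed_or_current(seed, {
    keys <- matrix(runif(n * m), nrow = n)
    ranks <- 1 + rowSums(keys[, -1, drop = FALSE] < keys[, 1])
    mean(ranks)
  })
}
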