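#' Simulate a single trial
#'
#' Runs one trial of the sound-seeking task under a policy: the agent starts
#' in the arena center, visits chambers according to the policy until it pokes
#' the goal port, and the trial ends at the rewarded poke. Each chamber visit
#' produces a trajectory leg center -> entryway -> port -> center rendered as
#' piecewise-linear waypoints at constant locomotion speed, which downstream
#' pose synthesis interpolates at the video frame rate.
#'
#' @param policy An [agent_policy()].
#' @param arena An [arena_geometry()].
#' @param goal Goal port id.
#' @param prev_goal Previous trial's goal, or `NA` on the first trial.
#' @param level_db Sound level of the trial's stimulus (drives the checker's
#'   detection probability).
#' @param t0 Trial start time, s (session clock).
#' @param speed_cm_s Locomotion speed along waypoint legs, cm/s.
#' @param dwell_s Dwell time at a port when poking, s.
#' @param check_dwell_s Dwell time for an entry without poke, s.
#' @param seed Optional integer seed.
#'
#' @return A `trial_record` list: `goal`, `prev_goal`, `pokes` (tibble
#'   `t`, `port`), `entries` (tibble `t`, `chamber`, `poke`), `path`
#'   (tibble `t`, `x`, `y` waypoints), `reward_time`.
#' @export
run_trial <- function(policy, arena, goal, prev_goal = NA, level_db = 70,
                      t0 = 0, speed_cm_s = 15, dwell_s = 0.4,
                      check_dwell_s = 0.2, seed = NULL) {
  if (!is.na(prev_goal) && goal == prev_goal) {
    abort("`goal` must differ from `prev_goal`")
  }
  if (goal < 0 || goal >= arena$n_ports) abort("unknown goal port")
  visits <- with_seed_or_current(
    seed, plan_visits(policy, arena, goal, prev_goal, level_db)
  )

  k <- arena$n_ports
  centers <- 2 * pi * visits$chamber / k
  r_port <- arena$apothem_out - 2.5          # dwell point just inside the wall
  r_cross <- arena$inner_radius * cos(pi / k) # divider-line crossing radius
  leg_t <- r_port / speed_cm_s
  cross_t <- r_cross / speed_cm_s

  t <- t0
  wx <- 0; wy <- 0; wt <- t0
  pokes_t <- numeric(0); pokes_p <- integer(0)
  entry_t <- numeric(0)
  for (i in seq_len(nrow(visits))) {
    cx <- r_port * cos(centers[i]); cy <- r_port * sin(centers[i])
    entry_t <- c(entry_t, t + cross_t)
    t_in <- t + leg_t
    dw <- if (visits$poke[i]) dwell_s else check_dwell_s
    if (visits$poke[i]) {
      pokes_t <- c(pokes_t, t_in + dw / 2)
      pokes_p <- c(pokes_p, visits$chamber[i])
    }
    t_out <- t_in + dw
    t_back <- t_out + leg_t
    wt <- c(wt, t_in, t_out, t_back)
    wx <- c(wx, cx, cx, 0)
    wy <- c(wy, cy, cy, 0)
    t <- t_back
  }
  reward_time <- pokes_t[length(pokes_t)]
  structure(
    list(
      goal = goal, prev_goal = prev_goal,
      pokes = tibble(t = pokes_t, port = pokes_p),
      entries = tibble(t = entry_t, chamber = visits$chamber,
                       poke = visits$poke),
      path = tibble(t = wt, x = wx, y = wy),
      reward_time = reward_time
    ),
    class = "trial_record"
  )
}

#' Simulate a session of sound-seeking trials
#'
#' Runs `n_trials` sequential trials. Each trial's goal is drawn by
#' [select_goal()] with the previous trial's goal excluded, its stimulus
#' parameters by [sample_trial_params()] under the requested mode, and its
#' behavior by [run_trial()]. The next trial begins `inter_trial_s` after the
#' previous reward.
#'
#' @param policy An [agent_policy()].
#' @param arena An [arena_geometry()].
#' @param n_trials Number of trials (>= 1).
#' @param mode Stimulus mode, `"fixed"` or `"variable"`.
#' @param seed Optional integer seed for the whole session.
#' @param inter_trial_s Delay between reward and next trial start, s.
#' @param ... Passed to [run_trial()] (speeds, dwell times).
#'
#' @return A `soundseek_session` tibble, one row per trial: `trial`, `goal`,
#'   `prev_goal`, `t_start`, `reward_time`, the stimulus parameter columns,
#'   and list-columns `pokes`, `entries`, `path`. The arena and policy are
#'   stored as attributes.
#' @examples
#' s <- simulate_session(agent_policy("random"), n_trials = 5, seed = 1)
#' s$goal
#' @export
simulate_session <- function(policy, arena = arena_geometry(), n_trials = 100,
                             mode = c("fixed", "variable"), seed = NULL,
                             inter_trial_s = 1, ...) {
  mode <- match.arg(mode)
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  with_seed_or_current(seed, {
    stim <- sample_trial_params(n_trials, mode)
    prev_goal <- NA_integer_
    t0 <- 0
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      goal <- select_goal(prev_goal, arena$n_ports)
      tr <- run_trial(policy, arena, goal, prev_goal,
                      level_db = stim$level_db[i], t0 = t0, ...)
      rows[[i]] <- tibble(
        trial = i, goal = goal, prev_goal = prev_goal, t_start = t0,
        reward_time = tr$reward_time,
        pokes = list(tr$pokes), entries = list(tr$entries),
        path = list(tr$path)
      )
      prev_goal <- goal
      # next trial begins after the inter-trial delay, once the return leg
      # of the trajectory is complete (paths must not overlap in time)
      t0 <- max(tr$reward_time + inter_trial_s, max(tr$path$t))
    }
    out <- dplyr::bind_cols(list_rbind(rows), stim)
    attr(out, "arena") <- arena
    attr(out, "policy") <- policy
    class(out) <- c("soundseek_session", class(out))
    out
  })
}

#' Flatten a session into an event log
#'
#' Produces the long event-log form rigs emit: one row per event
#' (`trial_start`, `poke`, `reward`) with session-clock timestamps. This is
#' the interchange format the scoring functions read, and what
#' [write_events_jsonl()] / [read_events_jsonl()] serialize.
#'
#' @param session A [simulate_session()] result.
#' @return Tibble with columns `t`, `type`, `port`, `trial`.
#' @export
session_events <- function(session) {
  rows <- pmap(
    list(session$trial, session$t_start, session$reward_time,
         session$pokes, session$goal),
    function(trial, t_start, reward_time, pokes, goal) {
      bind_rows(
        tibble(t = t_start, type = "trial_start", port = NA_integer_,
               trial = as.integer(trial)),
        tibble(t = pokes$t, type = "poke", port = as.integer(pokes$port),
               trial = as.integer(trial)),
        tibble(t = reward_time, type = "reward", port = as.integer(goal),
               trial = as.integer(trial))
      )
    }
  )
  arrange(list_rbind(rows), .data$t, .data$type)
}

#' Write / read an event log as JSON lines
#'
#' One JSON object per line with fields `t`, `type`, `port`, `trial`.
#'
#' @param events Event tibble from [session_events()].
#' @param path File path.
#' @return `path` invisibly; `read_events_jsonl()` returns the event tibble.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble(t = as.numeric(obj$t), type = as.character(obj$type),
           port = if (is.null(obj$port)) NA_integer_ else as.integer(obj$port),
           trial = as.integer(obj$trial))
  })
  list_rbind(rows)
}
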