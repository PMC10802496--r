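#' Agent policies for the sound-seeking task
#'
#' Constructs a search policy for the simulated agent. Four kinds are
#' available, mirroring the strategies mice exhibit:
#'
#' * `"random"`: pokes distinct eligible ports (the previous goal is excluded)
#'   in uniformly random order until the goal is found — the chance-level
#'   strategy (expected 4 ports poked, 1/7 correct in the 8-port arena).
#' * `"cycling"`: visits the ring of chambers in a fixed direction from a
#'   start port, poking each port in turn — the traplining-like strategy.
#' * `"direct"`: goes straight to the goal — perfect performance.
#' * `"checker"`: enters chambers in ring order from a random start and pokes
#'   a chamber's port only when it detects sound there. Detection of the goal
#'   chamber's sound is Bernoulli with probability
#'   `detect_prob(level_db, ear_state)`; non-goal chambers are poked with
#'   probability `false_alarm`. After `max_laps` full laps without reward the
#'   checker falls back to poking every port in ring order, which guarantees
#'   termination even when detection is essentially impossible (bilateral
#'   hearing loss).
#'
#' @param kind One of `"random"`, `"cycling"`, `"direct"`, `"checker"`.
#' @param start Cycling/checker start port; `NULL` draws one uniformly per
#'   trial.
#' @param direction `+1` (counterclockwise) or `-1` (clockwise) ring
#'   direction.
#' @param ear_state Checker hearing state: `"intact"`, `"unilateral_left"`,
#'   `"unilateral_right"`, `"bilateral"`, or `"sham"`.
#' @param detect_prob Function `(level_db, ear_state) -> [0,1]`; default
#'   [detect_prob_default()].
#' @param false_alarm Probability the checker pokes a non-goal chamber's port.
#' @param max_laps Full laps without detection before the serial-poking
#'   fallback engages.
#'
#' @return An `agent_policy` list.
#' @examples
#' agent_policy("checker", ear_state = "unilateral_left")
#' @export
agent_policy <- function(kind = c("random", "cycling", "direct", "checker"),
                         start = NULL, direction = 1L,
                         ear_state = "intact",
                         detect_prob = detect_prob_default,
                         false_alarm = 0, max_laps = 2L) {
  kind <- match.arg(kind)
  if (!direction %in% c(1L, -1L)) abort("`direction` must be +1 or -1")
  if (false_alarm < 0 || false_alarm > 1) {
    abort("`false_alarm` must be in [0, 1]")
  }
  states <- c("intact", "unilateral_left", "unilateral_right", "bilateral",
              "sham")
  if (!ear_state %in% states) {
    abort(paste("`ear_state` must be one of:", paste(states, collapse = ", ")))
  }
  structure(
    list(kind = kind, start = start, direction = as.integer(direction),
         ear_state = ear_state, detect_prob = detect_prob,
         false_alarm = false_alarm, max_laps = as.integer(max_laps)),
    class = "agent_policy"
  )
}

#' Default sound-detection probability by hearing state
#'
#' Logistic psychometric function of sound level with a state-dependent
#' threshold: intact/sham hearing detects the in-chamber sound essentially
#' always at training levels; unilateral loss elevates the threshold
#' moderately (the spared ear still hears inside the chamber); bilateral
#' malleus removal elevates thresholds far above the training range, so
#' detection probability is near zero.
#'
#' @param level_db Sound level, dB SPL.
#' @param ear_state Hearing state string (see [agent_policy()]).
#' @return Detection probability in `[0, 1]`.
#' @export
detect_prob_default <- function(level_db, ear_state = "intact") {
  thr <- switch(ear_state,
    intact = 40, sham = 40,
    unilateral_left = 50, unilateral_right = 50,
    bilateral = 110,
    abort("unknown `ear_state`")
  )
  stats::plogis((level_db - thr) / 5)
}

#' Choose the goal port for a trial
#'
#' The goal is drawn uniformly at random over all ports except the previous
#' trial's goal — the same speaker is never the goal on two consecutive
#' trials. On a session's first trial (`prev_goal = NA`) all ports are
#' eligible.
#'
#' @param prev_goal Previous goal port id, or `NA` for the first trial.
#' @param n_ports Number of ports.
#' @param seed Optional integer seed.
#' @return A port id in `0:(n_ports-1)`.
#' @examples
#' select_goal(prev_goal = 3)
#' @export
select_goal <- function(prev_goal = NA, n_ports = 8, seed = NULL) {
  if (n_ports < 2) abort("`n_ports` must be >= 2")
  eligible <- 0:(n_ports - 1)
  if (!is.na(prev_goal)) {
    if (!prev_goal %in% eligible) abort("`prev_goal` is not a valid port")
    eligible <- setdiff(eligible, prev_goal)
  }
  with_seed_or_current(seed, eligible[sample.int(length(eligible), 1)])
}

# Port/chamber visit plan for one trial: data frame (chamber, poke) ending
# with a poke into the goal.
plan_visits <- function(policy, arena, goal, prev_goal, level_db) {
  k <- arena$n_ports
  switch(policy$kind,
    direct = tibble(chamber = goal, poke = TRUE),
    random = {
      eligible <- 0:(k - 1)
      if (!is.na(prev_goal)) eligible <- setdiff(eligible, prev_goal)
      order <- sample(eligible)
      order <- order[seq_len(which(order == goal))]
      tibble(chamber = order, poke = TRUE)
    },
    cycling = {
      start <- policy$start %||% (sample.int(k, 1) - 1L)
      seqn <- (start + policy$direction * (0:(2 * k))) %% k
      seqn <- seqn[seq_len(which(seqn == goal)[1])]
      tibble(chamber = seqn, poke = TRUE)
    },
    checker = {
      start <- policy$start %||% (sample.int(k, 1) - 1L)
      p_goal <- policy$detect_prob(level_db, policy$ear_state)
      chambers <- integer(0)
      pokes <- logical(0)
      pos <- start
      steps <- 0L
      repeat {
        fallback <- steps >= policy$max_laps * k
        is_goal <- pos == goal
        poke <- if (fallback) TRUE
        else if (is_goal) runif(1) < p_goal
        else runif(1) < policy$false_alarm
        chambers <- c(chambers, pos)
        pokes <- c(pokes, poke)
        if (poke && is_goal) break
        pos <- (pos + policy$direction) %% k
        steps <- steps + 1L
      }
      tibble(chamber = chambers, poke = pokes)
    }
  )
}
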