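#' Score one trial
#'
#' Applies the task's scoring rules to an ordered poke sequence. Pokes into
#' the previously rewarded port are disregarded entirely (mice often
#' perseverate there, and it can never be the goal). After that filtering,
#' `ports_poked` is the number of *distinct* ports poked up to and including
#' the first goal poke, and the trial is correct iff the first remaining poke
#' is the goal — equivalently iff `ports_poked == 1`. With the previous goal
#' excluded, `ports_poked` ranges from 1 (correct) to 7 in the 8-port arena.
#'
#' @param pokes Ordered vector of poked port ids (the raw trial log).
#' @param goal Goal port id.
#' @param prev_goal Previous goal port id, or `NA` on a session's first trial
#'   (then nothing is excluded and `ports_poked` may reach 8).
#'
#' @return A one-row tibble: `correct` (logical), `ports_poked` (integer).
#' @examples
#' score_trial(c(7, 2, 5, 2, 3), goal = 3, prev_goal = 7)
#' @export
score_trial <- function(pokes, goal, prev_goal = NA) {
  if (!is.na(prev_goal)) {
    if (goal == prev_goal) abort("`goal` must differ from `prev_goal`")
    pokes <- pokes[pokes != prev_goal]
  }
  hit <- which(pokes == goal)
  if (length(hit) == 0) abort("malformed trial: goal never poked")
  pokes <- pokes[seq_len(hit[1])]
  tibble(correct = pokes[1] == goal,
         ports_poked = as.integer(n_distinct(pokes)))
}

#' Score every trial of a session
#'
#' Accepts either a [simulate_session()] tibble (list-column `pokes` plus
#' `goal`/`prev_goal`) or a long event log as produced by [session_events()]
#' (columns `t`, `type`, `port`, `trial`; the goal of a trial is the port of
#' its `reward` event and the previous goal is the preceding trial's goal).
#'
#' @param x Session tibble or event-log tibble.
#' @return The per-trial score tibble: `trial`, `goal`, `prev_goal`,
#'   `correct`, `ports_poked`, `first_trial` (no previous goal to exclude).
#' @examples
#' s <- simulate_session(agent_policy("random"), n_trials = 10, seed = 1)
#' score_trials(s)
#' @export
score_trials <- function(x) {
  if (all(c("pokes", "goal", "prev_goal") %in% names(x))) {
    trials <- tibble(
      trial = x$trial %||% seq_len(nrow(x)),
      goal = x$goal, prev_goal = x$prev_goal,
      poke_ports = map(x$pokes, ~ .x$port)
    )
  } else if (all(c("t", "type", "port", "trial") %in% names(x))) {
    per_trial <- x |>
      filter(.data$type %in% c("poke", "reward")) |>
      arrange(.data$trial, .data$t) |>
      group_by(.data$trial) |>
      summarise(
        goal = .data$port[.data$type == "reward"][1],
        poke_ports = list(.data$port[.data$type == "poke"]),
        .groups = "drop"
      ) |>
      arrange(.data$trial)
    trials <- per_trial |>
      mutate(prev_goal = lag(.data$goal)) |>
      select("trial", "goal", "prev_goal", "poke_ports")
  } else {
    abort("`x` must be a session tibble or an event-log tibble")
  }
  scores <- pmap(
    list(trials$poke_ports, trials$goal, trials$prev_goal),
    score_trial
  ) |> list_rbind()
  out <- dplyr::bind_cols(
    select(trials, "trial", "goal", "prev_goal"),
    scores
  ) |> mutate(first_trial = is.na(.data$prev_goal))
  # carry stimulus parameter columns through when present
  stim_cols <- intersect(names(x), c("center_freq_khz", "level_db", "rate_hz",
                                     "irregularity_ms"))
  if (length(stim_cols) > 0 && nrow(x) == nrow(out)) {
    out <- dplyr::bind_cols(out, x[stim_cols])
  }
  out
}

#' Summarize a scored session
#'
#' @param scores [score_trials()] output (or any tibble with `correct` and
#'   `ports_poked`).
#' @param exclude_first_trial Drop trials with no previous goal (a session's
#'   first trial) from the means, preserving the `[1, 7]` range contract of
#'   `ports_poked`. The trial still counts toward `n_trials`.
#'
#' @return One-row tibble: `n_trials`, `fraction_correct`,
#'   `mean_ports_poked`.
#' @export
summarize_session <- function(scores, exclude_first_trial = TRUE) {
  if (nrow(scores) == 0) abort("no trials to summarize")
  incl <- scores
  if (exclude_first_trial && "first_trial" %in% names(scores)) {
    incl <- filter(scores, !.data$first_trial)
    if (nrow(incl) == 0) incl <- scores
  }
  tibble(
    n_trials = nrow(scores),
    fraction_correct = mean(incl$correct),
    mean_ports_poked = mean(incl$ports_poked)
  )
}

#' Locate the learning criterion session
#'
#' The learning criterion is the first session on which performance is better
#' than `threshold` ports poked per trial (strictly fewer). Sessions strictly
#' before it are labelled `"early"`, the criterion session and all later ones
#' `"late"`. If no session qualifies the criterion index is `NA` and all
#' sessions are `"early"`.
#'
#' @param summaries Tibble of per-session summaries in chronological order
#'   (needs a `mean_ports_poked` column).
#' @param threshold Criterion, ports poked per trial.
#'
#' @return `summaries` with columns `session` (1-based) and `epoch` added;
#'   the criterion index is in attribute `criterion_session` and via
#'   [criterion_session()].
#' @examples
#' s <- tibble::tibble(mean_ports_poked = c(4, 3.1, 2.4, 2.6))
#' learning_criterion(s)
#' @export
learning_criterion <- function(summaries, threshold = 2.5) {
  if (nrow(summaries) == 0) abort("need at least one session")
  idx <- which(summaries$mean_ports_poked < threshold)
  crit <- if (length(idx) == 0) NA_integer_ else idx[1]
  out <- summaries |>
    mutate(
      session = row_number(),
      epoch = if (is.na(crit)) "early"
              else ifelse(row_number() >= crit, "late", "early")
    )
  attr(out, "criterion_session") <- crit
  out
}

#' @rdname learning_criterion
#' @param x A [learning_criterion()] result.
#' @export
criterion_session <- function(x) attr(x, "criterion_session")

#' Performance as a function of an acoustic parameter
#'
#' For variable-parameter sessions: bins trials by an acoustic parameter on a
#' log-spaced grid and reports the mean ports poked per bin, together with
#' the Pearson correlation (and p-value) between the log parameter and ports
#' poked across trials.
#'
#' @param scored Trial tibble from [score_trials()] carrying the stimulus
#'   parameter columns.
#' @param param Parameter column name (e.g. `"level_db"`,
#'   `"center_freq_khz"`, `"rate_hz"`, `"irregularity_ms"`).
#' @param n_bins Number of log-spaced bins.
#'
#' @return A `param_performance` object; see [tidy()] for the per-bin table
#'   and [glance()] for the correlation statistic.
#' @export
performance_by_param <- function(scored, param, n_bins = 5) {
  if (!param %in% names(scored)) abort(paste0("no column `", param, "`"))
  v <- scored[[param]]
  if (diff(range(v)) == 0) {
    abort("parameter is constant (fixed-mode session); nothing to correlate")
  }
  lv <- log(v)
  breaks <- seq(min(lv), max(lv), length.out = n_bins + 1)
  bin <- cut(lv, breaks, include.lowest = TRUE, labels = FALSE)
  bins <- tibble(bin = bin, ports_poked = scored$ports_poked, value = v) |>
    group_by(.data$bin) |>
    summarise(
      mid = exp(mean(log(range(.data$value)))),
      mean_ports_poked = mean(.data$ports_poked),
      n = n(), .groups = "drop"
    )
  ct <- cor.test(lv, scored$ports_poked, method = "pearson")
  structure(
    list(param = param, bins = bins, estimate = unname(ct$estimate),
         p.value = ct$p.value, n = length(v)),
    class = "param_performance"
  )
}

#' @export
print.param_performance <- function(x, ...) {
  cat(sprintf("<param_performance> %s: r = %.3f, p = %.3g (n = %d trials)\n",
              x$param, x$estimate, x$p.value, x$n))
  print(x$bins)
  invisible(x)
}

#' @export
tidy.param_performance <- function(x, ...) x$bins

#' @export
glance.param_performance <- function(x, ...) {
  tibble(param = x$param, estimate = x$estimate, p.value = x$p.value,
         n = x$n)
}

#' @export
autoplot.param_performance <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mid, y = .data$mean_ports_poked)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$param, y = "ports poked per trial") +
    ggplot2::theme_minimal()
}

#' Write per-session scores as CSV
#'
#' @param summaries A [learning_criterion()] (or [summarize_session()])
#'   tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
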