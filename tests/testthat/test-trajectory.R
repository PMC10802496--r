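test_that("a track that never leaves the center yields no entries", {
  tr <- make_snout_track(list(list(chamber = NA, frames = 50)))
  expect_equal(nrow(detect_entries(tr, arena_geometry())), 0)
})

test_that("waypoint visits are detected in order", {
  tr <- make_snout_track(list(
    list(chamber = NA, frames = 10), list(chamber = 2, frames = 10),
    list(chamber = NA, frames = 10), list(chamber = 3, frames = 10),
    list(chamber = NA, frames = 5)
  ))
  ent <- detect_entries(tr, arena_geometry())
  expect_equal(ent$chamber, c(2L, 3L))
  expect_equal(ent$entry_frame, c(11L, 31L))
})

test_that("divider jitter within the debounce window is a single entry", {
  tr <- make_snout_track(list(
    list(chamber = NA, frames = 10), list(chamber = 2, frames = 4),
    list(chamber = NA, frames = 2),  # brief flicker back to center
    list(chamber = 2, frames = 4), list(chamber = NA, frames = 10)
  ))
  ent <- detect_entries(tr, arena_geometry(), debounce_frames = 3)
  expect_equal(ent$chamber, 2L)
  # a sustained (>= debounce) center excursion splits the visits
  tr2 <- make_snout_track(list(
    list(chamber = NA, frames = 10), list(chamber = 2, frames = 4),
    list(chamber = NA, frames = 3),
    list(chamber = 2, frames = 4), list(chamber = NA, frames = 10)
  ))
  expect_equal(detect_entries(tr2, arena_geometry())$chamber, c(2L, 2L))
})

test_that("short snout gaps are interpolated, all-missing tracks rejected", {
  tr <- make_snout_track(list(
    list(chamber = NA, frames = 10), list(chamber = 4, frames = 12),
    list(chamber = NA, frames = 10)
  ))
  tr$x[14:16] <- NA
  tr$y[14:16] <- NA
  ent <- detect_entries(tr, arena_geometry(), max_gap = 5)
  expect_equal(ent$chamber, 4L)
  tr_bad <- tr
  tr_bad$node <- "tail_base"
  expect_error(detect_entries(tr_bad, arena_geometry()), "snout")
  tr_na <- tr
  tr_na$x <- NA_real_
  tr_na$y <- NA_real_
  expect_error(detect_entries(tr_na, arena_geometry()), "missing")
})

test_that("ring-order visits are flagged as cycling", {
  entries <- tibble::tibble(t = 1:4, chamber = c(0L, 1L, 2L, 3L))
  pokes <- tibble::tibble(t = 4.5, port = 3L)
  cl <- classify_entries(entries, pokes, goal = 3, prev_goal = 6)
  expect_equal(cl$metrics$n_cycling, 3L)
  expect_equal(cl$metrics$n_duplicate, 0L)
  expect_equal(cl$metrics$n_entries_kept, 4L)
})

test_that("duplicate visits and poke attribution follow the chosen rule", {
  entries <- tibble::tibble(t = c(1, 2, 3), chamber = c(5L, 2L, 5L))
  pokes <- tibble::tibble(t = 3.5, port = 5L)  # poke on the duplicate visit
  first_rule <- classify_entries(entries, pokes, goal = 5, prev_goal = 0)
  expect_equal(first_rule$metrics$n_duplicate, 1L)
  expect_equal(first_rule$metrics$n_entries_kept, 2L)
  # kept first entry of chamber 5 inherits the poke
  expect_equal(first_rule$metrics$n_with_poke, 1L)
  expect_equal(first_rule$metrics$n_without_poke, 1L)
  own_rule <- classify_entries(entries, pokes, goal = 5, prev_goal = 0,
                               attribution = "own_visit")
  expect_equal(own_rule$metrics$n_with_poke, 0L)
  expect_equal(own_rule$metrics$n_without_poke, 2L)
})

test_that("a checking agent's entries split into one poke and three checks", {
  entries <- tibble::tibble(t = 1:4, chamber = c(1L, 2L, 3L, 4L))
  pokes <- tibble::tibble(t = 4.2, port = 4L)
  cl <- classify_entries(entries, pokes, goal = 4, prev_goal = 7)
  expect_equal(cl$metrics$n_with_poke, 1L)
  expect_equal(cl$metrics$n_without_poke, 3L)
  expect_equal(sum(cl$entries$is_check), 3L)
})

test_that("previous-goal entries are discarded from kept counts", {
  entries <- tibble::tibble(t = 1:3, chamber = c(7L, 2L, 4L))
  pokes <- tibble::tibble(t = 3.5, port = 4L)
  cl <- classify_entries(entries, pokes, goal = 4, prev_goal = 7)
  expect_equal(cl$metrics$n_entries_kept, 2L)
  expect_true(cl$entries$is_prev_goal[1])
})

test_that("a poke without a detected entry raises a warning", {
  entries <- tibble::tibble(t = 1, chamber = 4L)
  pokes <- tibble::tibble(t = c(0.5, 1.5), port = c(2L, 4L))
  expect_warning(classify_entries(entries, pokes, goal = 4, prev_goal = 7),
                 "no detected")
})

test_that("entry metrics are additive and duplicate-free on simulations", {
  for (pol in list(agent_policy("random"),
                   agent_policy("checker", ear_state = "unilateral_left"))) {
    s <- simulate_session(pol, n_trials = 40, seed = 31)
    for (i in seq_len(nrow(s))) {
      cl <- classify_entries(s$entries[[i]], s$pokes[[i]], s$goal[i],
                             s$prev_goal[i])
      m <- cl$metrics
      expect_equal(m$n_with_poke + m$n_without_poke, m$n_entries_kept)
      kept <- cl$entries$chamber[!cl$entries$is_duplicate &
                                   !cl$entries$is_prev_goal]
      expect_equal(anyDuplicated(kept), 0L)
      expect_lte(m$n_cycling, max(m$n_entries - 1L, 0L))
    }
  }
})

test_that("kept-entry chance level is n_chambers/2 by enumeration", {
  expect_equal(entries_chance_level(8), 4)
  expect_equal(entries_chance_level(2), 1)
  mc <- entries_chance_level(8, method = "monte_carlo", n = 1e5, seed = 32)
  se <- 2 / sqrt(1e5)
  expect_lt(abs(mc - 4), 3 * se)
})

test_that("synthetic pose round-trip recovers the ground-truth visits", {
  g <- gen_pose_session(agent_policy("random"), n_trials = 100, seed = 33)
  m <- session_entry_metrics(g$pose, g$events, frame_rate = g$frame_rate,
                             transform = g$transform)
  expect_equal(nrow(m$metrics), 100)
  truth <- lapply(g$session$entries, function(e) as.integer(e$chamber))
  det <- split(m$entries$chamber, m$entries$trial)
  ok <- vapply(seq_along(truth), function(i) {
    identical(as.integer(det[[as.character(i)]]), truth[[i]])
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("jitter-free direct-policy tracks give exactly one entry per trial", {
  cfg <- synth_config(jitter_px = 0)
  g <- gen_pose_session(agent_policy("direct"), n_trials = 10,
                        config = cfg, seed = 34)
  m <- session_entry_metrics(g$pose, g$events, frame_rate = g$frame_rate,
                             transform = g$transform)
  expect_equal(m$metrics$n_entries, rep(1L, 10))
})

test_that("pose tracks round-trip through the CSV and HDF5 dialects", {
  g <- gen_pose_session(agent_policy("direct"), n_trials = 2, seed = 35)
  pose <- g$pose
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(pose, csv)
  back <- read_pose_csv(csv)
  expect_equal(as.data.frame(back), as.data.frame(pose), tolerance = 1e-6)

  h5 <- withr::local_tempfile(fileext = ".h5")
  write_pose_h5(pose, h5)
  back5 <- dplyr::arrange(read_pose_h5(h5), node, frame)
  orig <- dplyr::arrange(pose, node, frame)
  expect_equal(back5$x, orig$x, tolerance = 1e-12)
  expect_equal(back5$y, orig$y, tolerance = 1e-12)
  expect_equal(back5$node, orig$node)
})
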