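test_that("single-poke and perseverative-poke trials score as correct", {
  expect_equal(score_trial(3, goal = 3, prev_goal = 7),
               tibble::tibble(correct = TRUE, ports_poked = 1L))
  # pokes into the previously rewarded port do not affect scoring
  expect_equal(score_trial(c(7, 3), goal = 3, prev_goal = 7),
               tibble::tibble(correct = TRUE, ports_poked = 1L))
})

test_that("distinct wrong ports are counted once each", {
  sc <- score_trial(c(2, 5, 2, 3), goal = 3, prev_goal = 7)
  expect_false(sc$correct)
  expect_equal(sc$ports_poked, 3L)
})

test_that("pokes after the first goal poke are ignored", {
  sc <- score_trial(c(3, 1, 4, 6), goal = 3, prev_goal = 7)
  expect_true(sc$correct)
  expect_equal(sc$ports_poked, 1L)
})

test_that("a trial whose log never reaches the goal is malformed", {
  expect_error(score_trial(c(1, 2), goal = 3, prev_goal = 7), "malformed")
  expect_error(score_trial(c(1, 3), goal = 3, prev_goal = 3), "differ")
})

test_that("scoring is invariant to inserting previous-goal pokes", {
  withr::local_seed(11)
  for (rep in 1:50) {
    prev <- sample(0:7, 1)
    goal <- sample(setdiff(0:7, prev), 1)
    n <- sample(1:6, 1)
    body <- sample(setdiff(0:7, c(prev, goal)), n)
    pokes <- c(body, goal)
    base <- score_trial(pokes, goal, prev)
    k <- sample(1:4, 1)
    pos <- sort(sample(0:length(pokes), k, replace = TRUE))
    noisy <- pokes
    for (p in rev(pos)) noisy <- append(noisy, prev, after = p)
    expect_equal(score_trial(noisy, goal, prev), base)
  }
})

test_that("random-search ports poked is uniform on 1..(n-1): enumeration", {
  # brute-force oracle on a 6-port arena: enumerate every visit order of the
  # 5 eligible ports and score each with score_trial
  eligible <- c(0, 1, 2, 4, 5)  # prev_goal = 3 excluded
  goal <- 4
  counts <- integer(5)
  for (perm in all_perms(eligible)) {
    pokes <- perm[seq_len(which(perm == goal))]
    sc <- score_trial(pokes, goal, prev_goal = 3)
    counts[sc$ports_poked] <- counts[sc$ports_poked] + 1L
  }
  expect_equal(counts, rep(factorial(5) / 5, 5))  # uniform on 1..5
  expect_equal(sum(counts * 1:5) / sum(counts), 3)  # E = n_ports/2
})

test_that("empirical ports-poked distribution is uniform on 1..7", {
  s <- simulate_session(agent_policy("random"), n_trials = 3500, seed = 21)
  sc <- score_trials(s)
  pp <- sc$ports_poked[!sc$first_trial]
  expect_true(all(pp >= 1 & pp <= 7))
  tab <- table(factor(pp, levels = 1:7)) / length(pp)
  se <- sqrt((1 / 7) * (6 / 7) / length(pp))
  expect_true(all(abs(tab - 1 / 7) < 4 * se))
})

test_that("session summaries compute exact counts and bounded means", {
  sc <- tibble::tibble(correct = rep(TRUE, 5), ports_poked = rep(1L, 5),
                       first_trial = rep(FALSE, 5))
  expect_equal(summarize_session(sc),
               tibble::tibble(n_trials = 5L, fraction_correct = 1,
                              mean_ports_poked = 1))
  expect_error(summarize_session(sc[0, ]), "no trials")
})

test_that("a session's first trial can reach 8 ports but is excluded", {
  sc1 <- score_trial(c(0, 1, 2, 3, 4, 5, 6, 7), goal = 7, prev_goal = NA)
  expect_equal(sc1$ports_poked, 8L)
  scores <- tibble::tibble(
    correct = c(FALSE, TRUE), ports_poked = c(8L, 1L),
    first_trial = c(TRUE, FALSE)
  )
  sm <- summarize_session(scores)
  expect_equal(sm$mean_ports_poked, 1)
  expect_equal(sm$n_trials, 2L)
  sm_all <- summarize_session(scores, exclude_first_trial = FALSE)
  expect_equal(sm_all$mean_ports_poked, 4.5)
})

test_that("scoring an event log matches scoring the session directly", {
  s <- simulate_session(agent_policy("random"), n_trials = 30, seed = 22)
  direct <- score_trials(s)
  via_events <- score_trials(session_events(s))
  expect_equal(via_events$correct, direct$correct)
  expect_equal(via_events$ports_poked, direct$ports_poked)
})

test_that("the learning criterion is the first session below 2.5", {
  sm <- tibble::tibble(mean_ports_poked = c(4.0, 3.1, 2.4, 2.6))
  out <- learning_criterion(sm)
  expect_equal(criterion_session(out), 3L)
  expect_equal(out$epoch, c("early", "early", "late", "late"))
  # strict comparison: exactly 2.5 does not qualify
  none <- learning_criterion(tibble::tibble(mean_ports_poked = c(3, 2.5)))
  expect_true(is.na(criterion_session(none)))
  expect_equal(none$epoch, c("early", "early"))
  one <- learning_criterion(tibble::tibble(mean_ports_poked = 1.0))
  expect_equal(criterion_session(one), 1L)
})

test_that("performance_by_param rejects constant parameters", {
  s <- simulate_session(agent_policy("random"), n_trials = 20, seed = 23,
                        mode = "fixed")
  sc <- score_trials(s)
  expect_error(performance_by_param(sc, "level_db"), "constant")
})

test_that("a level-dependent checker yields a negative level correlation", {
  pol <- agent_policy("checker",
                      detect_prob = function(level, state) {
                        stats::plogis((level - 76) / 4)
                      })
  s <- simulate_session(pol, n_trials = 400, mode = "variable", seed = 24)
  sc <- score_trials(s)
  pp <- performance_by_param(sc, "level_db", n_bins = 4)
  expect_lt(glance(pp)$estimate, 0)
  expect_lt(glance(pp)$p.value, 0.01)
  expect_equal(nrow(tidy(pp)), 4)
})

test_that("the Pearson glue holds its nominal type-I error", {
  withr::local_seed(25)
  rejections <- 0L
  n_reps <- 200
  for (i in seq_len(n_reps)) {
    fake <- tibble::tibble(level_db = runif(60, 65, 90),
                           ports_poked = sample(1:7, 60, replace = TRUE))
    pp <- performance_by_param(fake, "level_db", n_bins = 3)
    if (pp$p.value < 0.05) rejections <- rejections + 1L
  }
  # binomial(200, 0.05): 3 SD above the mean is ~ 19
  expect_lte(rejections, 19)
})

test_that("a single bin reproduces the session mean", {
  s <- simulate_session(agent_policy("random"), n_trials = 50,
                        mode = "variable", seed = 26)
  sc <- score_trials(s)
  pp <- performance_by_param(sc, "rate_hz", n_bins = 1)
  expect_equal(tidy(pp)$mean_ports_poked, mean(sc$ports_poked))
})
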