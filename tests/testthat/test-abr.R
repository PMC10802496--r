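test_that("an exactly FIR-coupled channel is removed to numerical zero", {
  withr::local_seed(51)
  speaker <- rnorm(5000)
  h <- c(0.8, -0.5, 0.3, -0.2)
  # causal FIR with zero initial state (same lag convention as the fit)
  lagged <- sapply(0:3, function(k) c(rep(0, k), speaker[seq_len(5000 - k)]))
  neural <- as.numeric(lagged %*% h)
  cleaned <- remove_crosstalk(neural, speaker, filter_len = 16)
  expect_lt(mean(cleaned^2) / mean(neural^2), 1e-6)
})

test_that("a silent speaker channel leaves the neural signal untouched", {
  neural <- rnorm(100)
  expect_warning(out <- remove_crosstalk(neural, numeric(100)), "variance")
  expect_identical(out, neural)
})

test_that("cross-talk removal never increases residual power", {
  withr::local_seed(52)
  for (i in 1:10) {
    neural <- rnorm(2000)
    speaker <- rnorm(2000)
    cleaned <- remove_crosstalk(neural, speaker, filter_len = 8)
    expect_lte(mean(cleaned^2), mean(neural^2) + 1e-12)
  }
})

test_that("crosstalk-contaminated template is recovered by regression", {
  rec <- gen_abr_recording(
    config = synth_config(abr_n_clicks = 300, abr_noise_sd = 0.1,
                          abr_outlier_frac = 0), seed = 53
  )
  cleaned <- remove_crosstalk(rec$neural, rec$speaker)
  ep <- extract_epochs(cleaned, rec$triggers, rec$sample_rate)
  avg <- colMeans(ep)
  expect_gt(cor(avg, rec$template_epoch), 0.99)
})

test_that("the high-pass removes DC and slow drift but keeps the band", {
  fs <- 16000
  t <- seq(0, 1, by = 1 / fs)
  expect_lt(max(abs(highpass(rep(2, fs), fs))), 0.05)
  s1k <- sin(2 * pi * 1000 * t)
  out <- highpass(s1k, fs)
  mid <- seq(fs / 4, 3 * fs / 4)
  expect_equal(sd(out[mid]), sd(s1k[mid]), tolerance = 0.01)
  s10 <- sin(2 * pi * 10 * t)
  att <- sd(highpass(s10, fs)[mid]) / sd(s10[mid])
  expect_lt(20 * log10(att), -20)
  expect_error(highpass(s1k, fs, cutoff = 9000), "Nyquist")
})

test_that("epoch extraction windows triggers and skips edge cases", {
  x <- seq_len(1000)
  expect_warning(
    ep <- extract_epochs(x, c(5, 300, 600, 995), 16000, pre_ms = 1,
                         post_ms = 2),
    "skipped"
  )
  expect_equal(nrow(ep), 2)
  expect_equal(ncol(ep), 16 + 32 + 1)
  expect_equal(ep[1, ], x[(300 - 16):(300 + 32)])
  expect_error(extract_epochs(x, c(300, 200), 16000), "increasing")
})

test_that("identical epochs are rejected by the ceiling-and-ties rule", {
  withr::local_seed(60)
  ep <- matrix(rep(rnorm(50), each = 100), nrow = 100)
  out <- reject_outliers(ep)
  # ceiling(0.05 * 100) = 5 per criterion; all tie, later epochs rejected,
  # and both criteria pick the same 5
  expect_equal(sum(out$report$rejected), 5)
  expect_equal(which(out$report$rejected), 96:100)
  expect_equal(nrow(out$kept), 95)
})

test_that("large-amplitude epochs are rejected by both criteria", {
  withr::local_seed(54)
  ep <- matrix(rnorm(100 * 50), nrow = 100)
  bad <- c(10, 30, 55, 70, 99)
  ep[bad, ] <- 10 * ep[bad, ]
  out <- reject_outliers(ep)
  expect_true(all(out$report$by_excursion[bad]))
  expect_true(all(out$report$by_sd[bad]))
  expect_equal(which(out$report$rejected), bad)
})

test_that("small epoch sets reject one epoch per criterion", {
  ep <- matrix(rnorm(10 * 20), nrow = 10)
  out <- reject_outliers(ep)
  expect_lte(sum(out$report$rejected), 2)
  expect_equal(sum(out$report$by_excursion), 1)
  expect_equal(sum(out$report$by_sd), 1)
  expect_error(reject_outliers(ep[1, , drop = FALSE]), "2 epochs")
})

test_that("averaging preserves identical epochs and applies polarity", {
  ep <- matrix(rep(sin(seq(0, 2 * pi, length.out = 30)), each = 4), nrow = 4)
  right <- average_abr(ep, side = "right")
  expect_equal(right$waveform$uV, ep[1, ])
  expect_false(right$polarity_applied)
  left <- average_abr(ep, side = "left")
  expect_equal(left$waveform$uV, -ep[1, ])
  expect_true(left$polarity_applied)
  expect_error(average_abr(ep[0, , drop = FALSE]), "no epochs")
})

test_that("averaging variance scales as 1/n on white-noise epochs", {
  withr::local_seed(55)
  ep <- matrix(rnorm(800 * 40), nrow = 800)
  v100 <- mean(colMeans(ep[1:100, ])^2)
  v400 <- mean(colMeans(ep[1:400, ])^2)
  expect_equal(v100 / v400, 4, tolerance = 0.5)
})

test_that("a noiseless crosstalk-free recording averages to the template", {
  cfg <- synth_config(abr_n_clicks = 20, abr_noise_sd = 0,
                      abr_outlier_frac = 0, abr_crosstalk_fir = 0)
  rec <- gen_abr_recording(side = "right", config = cfg, seed = 56)
  ep <- extract_epochs(rec$neural, rec$triggers, rec$sample_rate)
  avg <- average_abr(ep, side = "right")
  expect_equal(avg$waveform$uV, rec$template_epoch, tolerance = 1e-12)
})

test_that("left and right recordings average to opposite raw polarities", {
  cfg <- synth_config(abr_n_clicks = 20, abr_noise_sd = 0,
                      abr_outlier_frac = 0, abr_crosstalk_fir = 0)
  l <- gen_abr_recording(side = "left", config = cfg, seed = 57)
  r <- gen_abr_recording(side = "right", config = cfg, seed = 57)
  ep_l <- extract_epochs(l$neural, l$triggers, l$sample_rate)
  ep_r <- extract_epochs(r$neural, r$triggers, r$sample_rate)
  expect_equal(colMeans(ep_l), -colMeans(ep_r), tolerance = 1e-12)
  # and the polarity correction makes both match the canonical template
  expect_equal(average_abr(ep_l, "left")$waveform$uV,
               average_abr(ep_r, "right")$waveform$uV, tolerance = 1e-12)
})

test_that("the full pipeline recovers the template and all planted outliers", {
  rec <- gen_abr_recording(side = "left", seed = 58)  # 750 clicks, defaults
  res <- process_abr(rec)
  expect_gt(cor(res$waveform$uV, rec$template_epoch), 0.95)
  rejected <- which(res$report$rejected)
  expect_true(all(rec$outlier_epochs %in% rejected))
  expect_equal(res$n_epochs_kept + res$n_rejected, length(rec$triggers))
})
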