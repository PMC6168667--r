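rate <- 512

emg_rec <- function(emg1, emg2) {
  n <- length(emg1)
  chans <- data.frame(name = c("Fz", "EMG1", "EMG2"),
                      role = c("scalp", "emg", "emg"),
                      position_label = c("Fz", "", ""))
  ppi_recording(rbind(rep(0, n), emg1, emg2), rate, chans)
}

make_trials <- function(trials_mat, condition, rate = 512,
                        window_ms = c(-300, 300), baseline_ms = c(-50, 0)) {
  off <- ppigate:::window_offsets(window_ms, rate)
  bl <- ppigate:::window_index(baseline_ms, rate, off$start, off$n)
  structure(list(trials = trials_mat,
                 baseline_mean = rowMeans(trials_mat[, bl, drop = FALSE]),
                 condition = condition,
                 trial_index = seq_len(nrow(trials_mat)),
                 window_ms = window_ms, baseline_ms = baseline_ms,
                 rate = rate, n_excluded = 0L), class = "envelope_trials")
}

test_that("bipolar EMG derivation is the channel difference", {
  set.seed(21)
  a <- rnorm(256); b <- rnorm(256)
  expect_equal(derive_emg_channel(emg_rec(a, a)), rep(0, 256))
  expect_equal(derive_emg_channel(emg_rec(a, rep(0, 256))), a)
  expect_equal(derive_emg_channel(emg_rec(a, b)), a - b)
  expect_equal(derive_emg_channel(emg_rec(a, b), "mean"), (a + b) / 2)
  chans1 <- data.frame(name = c("Fz", "EMG1"), role = c("scalp", "emg"),
                       position_label = "")
  expect_error(derive_emg_channel(
    ppi_recording(matrix(0, 2, 64), rate, chans1)), "2 emg")
})

test_that("envelope of a rectified in-band sine approaches 2/pi", {
  expect_equal(emg_envelope(rep(0, 4096), rate), rep(0, 4096))
  x <- sin(2 * pi * 100 * (0:8191) / rate)
  env <- emg_envelope(x, rate)
  mid <- env[2000:6000]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.05)
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.1)   # steady-state ripple
  expect_true(all(env >= 0))
})

test_that("below-band input is strongly attenuated by the envelope chain", {
  x <- sin(2 * pi * 5 * (0:8191) / rate)
  env <- emg_envelope(x, rate)
  expect_lt(sqrt(mean(env^2)) / sqrt(mean(x^2)), 0.05)
})

test_that("segmentation yields 307-sample trials and excludes edge events", {
  env <- rep(1, 3 * rate)
  ev <- ppi_events(c(round(0.1 * rate), rate, 2 * rate), c("P", "P", "P60"))
  expect_message(tr <- segment_envelope(env, ev, rate), "excluded")
  expect_equal(ncol(tr$trials), 307)          # round(0.6 * 512)
  expect_equal(nrow(tr$trials), 2)            # 100 ms-margin event dropped
  expect_equal(tr$n_excluded, 1L)
  expect_equal(tr$baseline_mean, c(1, 1))     # constant envelope
})

test_that("ASR is the baseline-subtracted in-window maximum", {
  n <- 307
  off <- ppigate:::window_offsets(c(-300, 300), rate)
  t_ms <- (off$start + seq_len(n) - 1) / rate * 1000
  flat <- rep(1, n)

  peak_at <- function(ms, height) {
    x <- flat
    x[which.min(abs(t_ms - ms))] <- height
    x
  }
  tr <- make_trials(rbind(peak_at(60, 6), peak_at(150, 6),
                          pmax(peak_at(30, 4), peak_at(110, 7))),
                    c("P", "P", "P"))
  tab <- score_asr(tr)
  expect_equal(tab$asr_uv[1], 5)   # 6 uV peak at 60 ms over 1 uV baseline
  expect_equal(tab$asr_uv[2], 0)   # peak at 150 ms lies outside 20-120 ms
  expect_equal(tab$asr_uv[3], 6)   # max of the two in-window peaks

  # brute-force window oracle on random envelopes
  set.seed(22)
  m <- matrix(abs(rnorm(20 * n)), nrow = 20)
  tr2 <- make_trials(m, rep("P", 20))
  tab2 <- score_asr(tr2)
  # window boundaries round to the nearest sample; [a, b] inclusive for the
  # scoring window, [a, b) for the baseline
  lo <- round(0.020 * rate) - off$start + 1; hi <- round(0.120 * rate) - off$start + 1
  blw <- (round(-0.050 * rate) - off$start + 1):(-off$start)
  brute <- apply(m[, lo:hi], 1, max) - rowMeans(m[, blw])
  expect_equal(tab2$asr_uv, pmax(brute, 0))

  # raw maximum when baseline subtraction is disabled
  tab3 <- score_asr(tr2, baseline_subtract = FALSE)
  expect_equal(tab3$asr_uv, apply(m[, lo:hi], 1, max))
})

test_that("trial rejection applies the strict mean + 3 SD rules", {
  n <- 307
  base <- matrix(1, 10, n)
  tr <- make_trials(base, rep("P", 10))
  tab <- reject_trials(score_asr(tr))
  expect_false(any(tab$rejected))             # zero variance, strict '>'

  # one amplitude outlier: 9 trials around 5 uV, one at 50 uV
  set.seed(23)
  m <- matrix(1, 10, n)
  off <- ppigate:::window_offsets(c(-300, 300), rate)
  t_ms <- (off$start + seq_len(n) - 1) / rate * 1000
  win <- which(t_ms >= 20 & t_ms <= 120)
  m[cbind(1:10, win[seq(2, 47, by = 5)])] <- c(rnorm(9, 5, 0.1), 50)
  tabm <- reject_trials(score_asr(make_trials(m, rep("P", 10))))
  expect_equal(which(tabm$rejected), 10L)
  expect_match(tabm$reason[10], "amplitude_outlier")
  expect_equal(outliers_oracle(tabm$peak_uv), tabm$rejected)

  # one baseline outlier with a normal in-window maximum
  m2 <- matrix(1, 10, n)
  m2[, win] <- 5
  blw <- which(t_ms >= -50 & t_ms < 0)
  m2[10, blw] <- 20
  tabb <- reject_trials(score_asr(make_trials(m2, rep("P", 10))))
  expect_equal(which(tabb$rejected), 10L)
  expect_equal(tabb$reason[10], "baseline_outlier")
  expect_equal(outliers_oracle(tabb$baseline_uv), tabb$rejected)

  # conjunctive rule keeps a trial flagged on one criterion only
  tabc <- reject_trials(score_asr(make_trials(m2, rep("P", 10))),
                        rule = "conjunctive")
  expect_false(any(tabc$rejected))
})

test_that("scaling the envelope scales ASR exactly and keeps rejections", {
  set.seed(24)
  n <- 307
  m <- matrix(abs(rnorm(30 * n, 2)), nrow = 30)
  cond <- rep(c("P", "P60", "P120"), each = 10)
  t1 <- reject_trials(score_asr(make_trials(m, cond)))
  t2 <- reject_trials(score_asr(make_trials(3.7 * m, cond)))
  expect_equal(t2$asr_uv, 3.7 * t1$asr_uv)
  expect_equal(t2$rejected, t1$rejected)
})

test_that("responder threshold is 20 digital units, boundary inclusive", {
  n <- 307
  mk <- function(level) {
    off <- ppigate:::window_offsets(c(-300, 300), rate)
    t_ms <- (off$start + seq_len(n) - 1) / rate * 1000
    x <- rep(0, n)
    x[which.min(abs(t_ms - 60))] <- level
    make_trials(matrix(x, 1), "P")
  }
  expect_false(classify_responder(score_asr(mk(0.5)))$is_responder)
  st <- classify_responder(score_asr(mk(20 * 0.0488)))
  expect_true(st$is_responder)                 # exactly at threshold
  expect_equal(st$threshold_uv, 0.976)
  expect_true(classify_responder(score_asr(mk(10)))$is_responder)
  tab <- score_asr(mk(10))
  tab$rejected <- TRUE
  expect_error(classify_responder(tab), "no kept")
})
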