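rate <- 512

scalp_epochs <- function(data_ch_x_samples, n_epochs, channels = NULL) {
  n_ch <- nrow(data_ch_x_samples)
  n_sm <- ncol(data_ch_x_samples) / n_epochs
  if (is.null(channels)) {
    channels <- data.frame(name = paste0("ch", seq_len(n_ch)), role = "scalp",
                           position_label = "")
  }
  structure(list(
    data = aperm(array(data_ch_x_samples, c(n_ch, n_sm, n_epochs)),
                 c(3, 1, 2)),
    channels = channels,
    condition = rep("P", n_epochs),
    trial_index = seq_len(n_epochs),
    window_ms = c(-1000, 1000), baseline_ms = NULL, rate = rate,
    n_excluded = 0L), class = "epoch_set")
}

test_that("Infomax separates a known two-channel mixture (Amari index)", {
  set.seed(31)
  n <- 10240
  s1 <- sample(c(-1, 1), n, replace = TRUE) * rexp(n)   # super-Gaussian
  s2 <- rnorm(n)
  A <- matrix(c(1, 0.6, -0.4, 1), 2)
  ep <- scalp_epochs(A %*% rbind(s1, s2), n_epochs = 10)
  dec <- fit_ica(ep, seed = 1)
  expect_lt(amari_index(dec$unmixing, A), 0.05)
})

test_that("already-independent whitened sources give a scaled permutation", {
  set.seed(32)
  n <- 10240
  s <- rbind(sample(c(-1, 1), n, TRUE) * rexp(n),
             sample(c(-1, 1), n, TRUE) * rexp(n))
  ep <- scalp_epochs(s, n_epochs = 10)
  dec <- fit_ica(ep, seed = 1)
  expect_lt(amari_index(dec$unmixing, diag(2)), 0.05)
})

test_that("the decomposition is deterministic and self-consistent", {
  set.seed(33)
  n <- 8192
  A <- matrix(rnorm(9), 3)
  S <- matrix(sample(c(-1, 1), 3 * n, TRUE) * rexp(3 * n), 3)
  X <- A %*% S
  ep <- scalp_epochs(X, n_epochs = 8)
  d1 <- fit_ica(ep, seed = 7)
  d2 <- fit_ica(ep, seed = 7)
  expect_identical(d1$unmixing, d2$unmixing)

  # unmixing . mixing = identity; activations = unmixing . centered data
  expect_equal(d1$unmixing %*% d1$mixing, diag(3), tolerance = 1e-6)
  expect_equal(d1$activations, d1$unmixing %*% (X - rowMeans(X)))

  # reconstruction with no component removed reproduces the input
  back <- remove_components(ep, d1, rep(FALSE, 3))
  expect_equal(back$data, ep$data, tolerance = 1e-6)
})

test_that("rank-deficient scalp data are refused with advice", {
  x <- rnorm(4096)
  ep <- scalp_epochs(rbind(x, x, rnorm(4096)), n_epochs = 4)
  expect_error(fit_ica(ep, 1), "rank-deficient")
})

test_that("autocorrelation criterion matches the cosine closed form", {
  n_sm <- 1024; n_ep <- 10
  tt <- (seq_len(n_sm * n_ep) - 1) / rate
  sine <- sin(2 * pi * 5 * tt)
  set.seed(34)
  noise <- rnorm(n_sm * n_ep)
  const <- rep(2, n_sm * n_ep)
  dec <- fake_ica(array(rbind(sine, noise, const), c(3, n_sm, n_ep)))
  r <- score_autocorrelation(dec, lag_ms = 20)
  lag <- round(0.020 * rate)
  expect_equal(r[1], cos(2 * pi * 5 * lag / rate), tolerance = 0.01)
  expect_lt(abs(r[2]), 0.1)
  expect_equal(r[3], 1)                       # degenerate convention
})

test_that("focal topography z-scores match direct arithmetic", {
  # uniform topography: z = 0
  dec_u <- fake_ica(array(0, c(3, 8, 1)), mixing = matrix(1, 3, 3))
  expect_equal(score_focal_topography(dec_u), rep(0, 3))

  # one of 20 channels carries all the weight
  w <- c(10, rep(0, 19))
  mix <- cbind(w, matrix(1, 20, 19))
  dec <- fake_ica(array(0, c(20, 8, 1)), mixing = mix)
  z <- score_focal_topography(dec)
  expect_equal(unname(z[1]), max((w - mean(w)) / sd(w)))
  expect_gt(z[1], 3.5)

  # two equal large weights among 20, same oracle
  w2 <- c(5, 5, rep(0, 18))
  mix2 <- cbind(w2, matrix(1, 20, 19))
  z2 <- score_focal_topography(fake_ica(array(0, c(20, 8, 1)), mixing = mix2))
  expect_equal(unname(z2[1]), max((w2 - mean(w2)) / sd(w2)))
})

test_that("focal trial activity flags a single extreme epoch", {
  # the z threshold of 10 needs a session-sized epoch count: with n epochs the
  # largest attainable z is (n-1)/sqrt(n), below 10 for n < 102, so the
  # criterion is tested at the full design's 170 trials
  set.seed(35)
  n_sm <- 256; n_ep <- 170
  base <- array(rnorm(2 * n_sm * n_ep), c(2, n_sm, n_ep))
  same <- array(rep(rnorm(n_sm), n_ep), c(1, n_sm, n_ep))
  expect_equal(score_focal_trial(fake_ica(same)), 0)   # identical epochs

  blown <- base
  blown[1, , 7] <- blown[1, , 7] * 100
  z <- score_focal_trial(fake_ica(blown))
  m <- apply(abs(blown[1, , ]), 2, max)
  expect_equal(unname(z[1]), max((m - mean(m)) / sd(m)))
  expect_gt(z[1], 10)

  mild <- base
  mild[2, , 7] <- mild[2, , 7] * 2
  z2 <- score_focal_trial(fake_ica(mild))
  m2 <- apply(abs(mild[2, , ]), 2, max)
  expect_equal(unname(z2[2]), max((m2 - mean(m2)) / sd(m2)))
  expect_lt(z2[2], 10)
})

test_that("stimulus-locked SNR separates locked, flat and mirrored components", {
  n_sm <- 1024; n_ep <- 40
  post <- c(rep(0, 512), sin(2 * pi * 8 * (0:511) / rate))
  locked <- array(rep(post, n_ep), c(1, n_sm, n_ep))
  expect_equal(score_snr(fake_ica(locked)), Inf)        # zero baseline SD

  set.seed(36)
  flat <- array(rnorm(n_sm * n_ep), c(1, n_sm, n_ep))
  r <- score_snr(fake_ica(flat))
  expect_gt(r, 0.9); expect_lt(r, 1.1)

  mirrored <- array(rep(rev(post), n_ep), c(1, n_sm, n_ep))
  expect_lt(score_snr(fake_ica(mirrored)), 1)
})

test_that("reference correlation matches construction", {
  set.seed(37)
  n_sm <- 1024; n_ep <- 10
  n <- n_sm * n_ep
  eog <- rnorm(n)
  comp1 <- eog                                  # identical to EOG
  comp2 <- rnorm(n)                             # independent
  comp3 <- 0.3 * eog + rnorm(n, sd = sd(eog))   # r = 0.3/sqrt(1.09) = 0.287
  dec <- fake_ica(array(rbind(comp1, comp2, comp3), c(3, n_sm, n_ep)))
  refs <- rbind(EOG = eog, EMG1 = rnorm(n), EMG2 = rnorm(n))
  r <- score_reference_correlation(dec, refs)
  expect_equal(r[1], 1, tolerance = 1e-10)
  expect_lt(r[2], 0.2)
  expect_equal(r[3], 0.3 / sqrt(1.09), tolerance = 0.05)
  expect_gt(r[3], 0.2)

  refs0 <- rbind(EOG = eog, EMG1 = rep(0, n))
  expect_warning(score_reference_correlation(dec, refs0), "zero-variance")
})

test_that("final decision is the union of criterion flags", {
  sc <- data.frame(component = 1:3,
                   autocorr_r = c(0.9, 0.1, 0.9),
                   focal_topo_z = 1, focal_trial_z = 1,
                   snr_ratio = 2, max_ref_corr = c(0, 0, 0.9),
                   flag_autocorr = c(FALSE, TRUE, FALSE),
                   flag_focal_topo = FALSE, flag_focal_trial = FALSE,
                   flag_snr = FALSE,
                   flag_ref_corr = c(FALSE, FALSE, TRUE))
  out <- classify_components(sc)
  expect_equal(out$final_artifact, c(FALSE, TRUE, TRUE))
  out2 <- classify_components(sc, combine = "vote")
  expect_equal(out2$final_artifact, c(FALSE, FALSE, FALSE))
})

test_that("classification is invariant to component sign and scale", {
  set.seed(38)
  n_sm <- 512; n_ep <- 12
  act <- array(rnorm(3 * n_sm * n_ep), c(3, n_sm, n_ep))
  mix <- matrix(rnorm(9), 3)
  refs <- matrix(rnorm(2 * n_sm * n_ep), 2)
  rownames(refs) <- c("EOG", "EMG1")
  d1 <- fake_ica(act, mixing = mix)
  scale <- c(-3, 0.5, -0.1)
  d2 <- fake_ica(array(act * scale, dim(act)),
                 mixing = t(t(mix) / scale))
  s1 <- score_components(d1, refs)
  s2 <- score_components(d2, refs)
  for (col in c("flag_autocorr", "flag_focal_topo", "flag_focal_trial",
                "flag_snr", "flag_ref_corr", "final_artifact")) {
    expect_equal(s1[[col]], s2[[col]], info = col)
  }
})

test_that("removing a channel-unique source silences that channel", {
  set.seed(39)
  n <- 8192
  s_shared <- sample(c(-1, 1), n, TRUE) * rexp(n)
  s_unique <- sample(c(-1, 1), n, TRUE) * rexp(n)
  # source 2 lives only on channel 3
  A <- rbind(c(1, 0), c(0.8, 0), c(0.2, 1))
  X <- A %*% rbind(s_shared, s_unique) + matrix(rnorm(3 * n, sd = 0.01), 3)
  ep <- scalp_epochs(X, n_epochs = 8)
  dec <- fit_ica(ep, seed = 2)
  # find the component whose mixing column matches the planted unique source
  sim <- apply(dec$mixing, 2, function(m) {
    abs(sum(m * A[, 2])) / sqrt(sum(m^2) * sum(A[, 2]^2))
  })
  remove <- seq_len(3) == which.max(sim)
  cleaned <- remove_components(ep, dec, remove)
  resid <- as.vector(cleaned$data[, 3, ]) - mean(X[3, ])
  expect_lt(sd(resid), 0.25 * sd(X[3, ]))
  expect_error(remove_components(ep, dec, rep(TRUE, 3)), "all components")
})

test_that("the classifier removes a planted blink and spares the neural source", {
  s <- tiny_sim(seed = 5)
  rec <- rereference(s$recording)
  rec$data <- zero_phase_filter(rec$data, filter_spec("highpass", 0.25),
                                rec$rate)
  ep <- epoch_eeg(rec, s$events)
  dec <- fit_ica(ep, seed = 1)
  refs <- flatten_epochs(epoch_eeg(rec, s$events, roles = c("eog", "emg"),
                                   baseline_ms = NULL))
  sc <- score_components(dec, refs)
  gains <- unlist(s$truth$blink_mixing)[dec$channels$name]
  cosine <- apply(dec$mixing, 2, function(m) {
    abs(sum(m * gains)) / sqrt(sum(m^2) * sum(gains^2))
  })
  blink_comp <- which.max(cosine)
  expect_true(sc$final_artifact[blink_comp])
  expect_gt(sc$max_ref_corr[blink_comp], 0.2)  # caught via EOG correlation
})
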