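#' Synthetic PPI session configuration
#'
#' Defaults reproduce the experimental design of the method: 512 Hz, two
#' pseudorandomized blocks of 20 trials per condition (P, P30, P60, P120) with
#' five pulse-alone trials before block 1 and after block 2 (170 trials), and
#' ground-truth effect sizes of 35/55/35 % muscular PPI and 40/55/40 % neural
#' PPI for the 30/60/120 ms intervals. Each pulse plants (a) a band-limited
#' EMG burst under a gamma-shaped envelope on the bipolar EMG pair, (b) a
#' blink artifact mixed into EOG and scalp channels through a fixed
#' frontal-dominant gain vector, with amplitude proportional to the trial's
#' startle amplitude (stronger startle, bigger blink), (c) an N1/P2 ERP
#' template on the scalp channels scaled by the condition's neural factor, and
#' (d) 1/f EEG noise, white sensor noise and common-phase mains interference.
#'
#' @param ... overrides of any default (nested lists merged).
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    rate = 512,
    n_per_condition_per_block = 20L,
    n_blocks = 2L,
    n_edge_p = 5L,
    iti_s = c(2.6, 3.2),
    edge_margin_s = 2.0,
    seed = 1L,
    startle = list(
      amplitude_uv = 50,              # pulse-alone EMG burst scale
      muscular_ppi = c(P30 = 35, P60 = 55, P120 = 35),
      jitter_sdlog = 0.2,             # per-trial lognormal amplitude jitter
      envelope_peak_ms = 60,          # gamma envelope peak latency
      envelope_shape = 3,
      burst_band_hz = c(24, 200),
      burst_dur_ms = 250
    ),
    neural = list(
      n1_uv = -8, n1_latency_ms = 100, n1_width_ms = 18,
      p2_uv = 10, p2_latency_ms = 200, p2_width_ms = 25,
      neural_ppi = c(P30 = 40, P60 = 55, P120 = 40),
      gains = c(Fp1 = 0.5, Fp2 = 0.5, F3 = 0.8, Fz = 1.0, F4 = 0.8,
                C3 = 0.8, Cz = 0.95, C4 = 0.8, P3 = 0.6, Pz = 0.7, P4 = 0.6)
    ),
    blink = list(
      uv_per_startle_uv = 1.6,        # blink peak on EOG per uV of startle
      peak_ms = 100, width_ms = 300,
      gains = c(EOG = 1.0, Fp1 = 0.9, Fp2 = 0.9, F3 = 0.5, Fz = 0.5,
                F4 = 0.5, C3 = 0.2, Cz = 0.2, C4 = 0.2,
                P3 = 0.05, Pz = 0.05, P4 = 0.05)
    ),
    noise = list(
      eeg_pink_sd = 5,                # 1/f noise on scalp + EOG, uV
      white_sd = 1,                   # sensor noise, all channels
      mains_uv = 2,                   # 60 Hz amplitude (plus a 120 Hz harmonic
                                      # at half amplitude), non-reference channels
      emg_sd = 1,                     # extra white noise on the EMG pair
      ref_sd = 0.3                    # earlobe reference noise
    )
  )
  cfg <- merge_config(cfg, list(...))
  stopifnot(cfg$startle$amplitude_uv >= 0,
            all(cfg$startle$muscular_ppi >= 0 & cfg$startle$muscular_ppi <= 100),
            all(cfg$neural$neural_ppi >= 0 & cfg$neural$neural_ppi <= 100),
            all(is.finite(cfg$blink$gains)), cfg$iti_s[1] <= cfg$iti_s[2])
  structure(cfg, class = "sim_config")
}

#' Simulate one PPI session with ground truth
#'
#' Generates the continuous 16-channel recording (11 scalp, EMG1/EMG2, EOG,
#' two earlobe references), the event list, and the planted ground truth. All
#' randomness comes from one generator seeded with `subject_seed`, so an
#' identical seed reproduces the session bit for bit. The EMG burst carrier is
#' drawn once per subject and reused across trials, so that with jitter and
#' noise disabled the scored startle scales exactly with the planted
#' condition amplitude.
#'
#' @param cfg a [simulation_config()].
#' @param subject_seed integer seed (defaults to `cfg$seed`).
#' @return List of class `sim_session`: `recording` ([ppi_recording()]),
#'   `events` ([ppi_events()]), `truth` (list: `muscular_ppi`, `neural_ppi`,
#'   `trials` data.frame with per-trial planted startle and blink amplitudes,
#'   `erp_template` channels x epoch-samples matrix at unit scale,
#'   `neural_scale` per condition, `blink_mixing` gain vector,
#'   `epoch_window_ms`).
#' @export
simulate_session <- function(cfg = simulation_config(), subject_seed = cfg$seed) {
  rate <- cfg$rate
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(subject_seed) %% .Machine$integer.max)

  # --- trial sequence -------------------------------------------------------
  conds <- ppi_conditions()
  block_seq <- function() sample(rep(conds, cfg$n_per_condition_per_block))
  condition <- c(rep("P", cfg$n_edge_p),
                 unlist(lapply(seq_len(cfg$n_blocks), function(b) block_seq())),
                 rep("P", cfg$n_edge_p))
  n_block_trials <- 4L * cfg$n_per_condition_per_block
  block <- c(rep(NA_integer_, cfg$n_edge_p),
             rep(seq_len(cfg$n_blocks), each = n_block_trials),
             rep(NA_integer_, cfg$n_edge_p))
  n_trials <- length(condition)
  iti <- stats::runif(n_trials - 1, cfg$iti_s[1], cfg$iti_s[2])
  if (any(iti < 2.1)) stop("inter-trial interval too short for -1..1 s epochs",
                           call. = FALSE)
  onset_s <- cfg$edge_margin_s + c(0, cumsum(iti))
  onset <- as.integer(round(onset_s * rate))
  n_samples <- as.integer(round((onset_s[n_trials] + cfg$edge_margin_s) * rate))
  events <- ppi_events(onset, condition, block)

  chans <- default_channels()
  data <- matrix(0, nrow = nrow(chans), ncol = n_samples,
                 dimnames = list(chans$name, NULL))

  # --- planted per-trial amplitudes ----------------------------------------
  mus_scale <- c(P = 1, (100 - cfg$startle$muscular_ppi) / 100)
  names(mus_scale) <- conds
  jit <- if (cfg$startle$jitter_sdlog > 0) {
    stats::rlnorm(n_trials, meanlog = -cfg$startle$jitter_sdlog^2 / 2,
                  sdlog = cfg$startle$jitter_sdlog)
  } else {
    rep(1, n_trials)
  }
  startle_amp <- cfg$startle$amplitude_uv * mus_scale[condition] * jit
  blink_amp <- cfg$blink$uv_per_startle_uv * startle_amp

  # --- EMG bursts (one fixed band-limited carrier per subject) -------------
  n_burst <- round(cfg$startle$burst_dur_ms / 1000 * rate)
  carrier <- stats::rnorm(n_burst + 2 * rate)
  carrier <- zero_phase_filter(carrier,
                               filter_spec("bandpass", cfg$startle$burst_band_hz),
                               rate)[rate + seq_len(n_burst)]
  carrier <- carrier / stats::sd(carrier)
  tb <- (seq_len(n_burst) - 1) / rate * 1000
  t0 <- cfg$startle$envelope_peak_ms
  k <- cfg$startle$envelope_shape
  genv <- (tb / t0)^k * exp(k * (1 - tb / t0))
  burst <- carrier * genv
  for (i in seq_len(n_trials)) {
    idx <- onset[i] + seq_len(n_burst)
    data["EMG1", idx] <- data["EMG1", idx] + 0.5 * startle_amp[i] * burst
    data["EMG2", idx] <- data["EMG2", idx] - 0.5 * startle_amp[i] * burst
  }

  # --- blink artifact (rank-1 spatial source) ------------------------------
  half_w <- cfg$blink$width_ms / 2
  n_bl <- round(cfg$blink$width_ms / 1000 * rate)
  tl <- (seq_len(n_bl) - 1) / rate * 1000 - half_w + cfg$blink$peak_ms
  blink_wave <- 0.5 * (1 + cos(pi * (tl - cfg$blink$peak_ms) / half_w))
  bg <- cfg$blink$gains
  bl_start <- as.integer(round((cfg$blink$peak_ms - half_w) / 1000 * rate))
  for (i in seq_len(n_trials)) {
    idx <- onset[i] + bl_start + seq_len(n_bl)
    for (chn in names(bg)) {
      data[chn, idx] <- data[chn, idx] + bg[[chn]] * blink_amp[i] * blink_wave
    }
  }

  # --- neural ERP template --------------------------------------------------
  neu_scale <- c(P = 1, (100 - cfg$neural$neural_ppi) / 100)
  names(neu_scale) <- conds
  n_erp <- rate            # template support: 0..1 s post-pulse
  te <- (seq_len(n_erp) - 1) / rate * 1000
  erp_wave <- cfg$neural$n1_uv *
    exp(-(te - cfg$neural$n1_latency_ms)^2 / (2 * cfg$neural$n1_width_ms^2)) +
    cfg$neural$p2_uv *
    exp(-(te - cfg$neural$p2_latency_ms)^2 / (2 * cfg$neural$p2_width_ms^2))
  ng <- cfg$neural$gains
  for (i in seq_len(n_trials)) {
    idx <- onset[i] + seq_len(n_erp)
    s <- neu_scale[condition[i]]
    for (chn in names(ng)) {
      data[chn, idx] <- data[chn, idx] + ng[[chn]] * s * erp_wave
    }
  }

  # --- noise ----------------------------------------------------------------
  nz <- cfg$noise
  eeg_like <- c(names(ng), "EOG")
  if (nz$eeg_pink_sd > 0) {
    for (chn in eeg_like) {
      data[chn, ] <- data[chn, ] + pink_noise(n_samples, nz$eeg_pink_sd)
    }
  }
  if (nz$white_sd > 0) {
    data <- data + matrix(stats::rnorm(length(data), sd = nz$white_sd),
                          nrow = nrow(data))
  }
  if (nz$emg_sd > 0) {
    data["EMG1", ] <- data["EMG1", ] + stats::rnorm(n_samples, sd = nz$emg_sd)
    data["EMG2", ] <- data["EMG2", ] + stats::rnorm(n_samples, sd = nz$emg_sd)
  }
  if (nz$ref_sd > 0) {
    data["A1", ] <- data["A1", ] + stats::rnorm(n_samples, sd = nz$ref_sd)
    data["A2", ] <- data["A2", ] + stats::rnorm(n_samples, sd = nz$ref_sd)
  }
  if (nz$mains_uv > 0) {
    tt <- (seq_len(n_samples) - 1) / rate
    phase <- stats::runif(1, 0, 2 * pi)
    mains <- nz$mains_uv * sin(2 * pi * 60 * tt + phase) +
      0.5 * nz$mains_uv * sin(2 * pi * 120 * tt + phase)
    nonref <- chans$name[chans$role != "reference"]
    data[nonref, ] <- data[nonref, , drop = FALSE] +
      rep(mains, each = length(nonref))
  }

  # --- ground-truth ERP template on the -1..1 s epoch grid -----------------
  off <- window_offsets(c(-1000, 1000), rate)
  tmpl <- matrix(0, nrow = length(ng), ncol = off$n,
                 dimnames = list(names(ng), NULL))
  post <- which(seq(off$start, length.out = off$n) >= 0)[seq_len(n_erp)]
  for (chn in names(ng)) tmpl[chn, post] <- ng[[chn]] * erp_wave

  structure(list(
    recording = ppi_recording(data, rate, chans),
    events = events,
    truth = list(
      muscular_ppi = cfg$startle$muscular_ppi,
      neural_ppi = cfg$neural$neural_ppi,
      trials = data.frame(onset = onset, condition = condition, block = block,
                          startle_amp = unname(startle_amp),
                          blink_amp = unname(blink_amp)),
      erp_template = tmpl,
      neural_scale = neu_scale,
      blink_mixing = bg,
      epoch_window_ms = c(-1000, 1000),
      seed = as.integer(subject_seed)
    )
  ), class = "sim_session")
}

# 1/f-amplitude noise by spectral shaping of white Gaussian noise. The FFT
# length is padded to the next highly composite integer (mixed-radix FFTs on
# prime lengths are quadratic) and the series truncated afterwards.
pink_noise <- function(n, sd) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(m)
  f <- c(1, seq_len(m - 1))                 # guard DC bin
  shaped <- Re(stats::fft(stats::fft(white) / sqrt(pmin(f, m - f + 1)),
                          inverse = TRUE))[seq_len(n)]
  sd * shaped / stats::sd(shaped)
}

#' Noise-free simulation configuration
#'
#' Convenience wrapper: all noise sources, the amplitude jitter and the blink
#' artifact set to zero. Under this configuration the pipeline recovers the
#' planted %PPI exactly (the startle carrier is fixed per subject, so scored
#' amplitudes scale exactly with the planted condition factors).
#'
#' @param ... further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
noiseless_config <- function(...) {
  base <- list(
    startle = list(jitter_sdlog = 0),
    blink = list(uv_per_startle_uv = 0),
    noise = list(eeg_pink_sd = 0, white_sd = 0, mains_uv = 0, emg_sd = 0,
                 ref_sd = 0)
  )
  do.call(simulation_config, merge_config(base, list(...)))
}

#' Write a simulated session as an on-disk fixture
#'
#' Writes the BrainVision triplet, the BIDS-style `events.tsv` and
#' `ground_truth.json` (planted %PPI and per-trial amplitudes) into `dir`.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @param name base file name (default `"session"`).
#' @param binary_format BrainVision sample encoding, `"float32"` or `"int16"`.
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture <- function(session, dir, name = "session",
                          binary_format = "float32") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vhdr <- file.path(dir, paste0(name, ".vhdr"))
  write_brainvision(session$recording, vhdr, events = session$events,
                    binary_format = binary_format)
  ev <- file.path(dir, "events.tsv")
  write_events(session$events, ev, session$recording$rate)
  gt <- file.path(dir, "ground_truth.json")
  truth <- session$truth
  truth$erp_template <- NULL            # matrices stay in memory, not in JSON
  for (nm in c("muscular_ppi", "neural_ppi", "neural_scale")) {
    truth[[nm]] <- as.list(truth[[nm]])  # keep names in the JSON object
  }
  jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(vhdr = vhdr, events = ev, ground_truth = gt))
}
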