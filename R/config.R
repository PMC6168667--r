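#' Pipeline configuration
#'
#' Builds the full parameter set of the PPI pipeline. Every numeric default is
#' the published value of the method: 0.25 Hz zero-phase high-pass and 60 Hz
#' notch cascade on the continuous signal; 24--200 Hz EMG band with a 15.9 Hz
#' rectified envelope, scored as the maximum in 20--120 ms over a 50 ms
#' pre-stimulus baseline; -1..1 s EEG epochs with a -650..-150 ms baseline and
#' 40 Hz low-pass; Infomax ICA with the automated component classifier
#' (autocorrelation lag 20 ms / auto threshold, focal topography z 3.5, focal
#' trial z 10, stimulus-locked SNR ratio 1, EOG/EMG correlation r 0.2); N1 in
#' 60--165 ms and P2 in 165--275 ms; non-responder threshold 20 digital units
#' at 0.0488 uV per unit.
#'
#' @param ... named overrides of any default, e.g. `highpass_hz = 0.5` or
#'   `emg = list(baseline_subtract = FALSE)`. Nested lists are merged, not
#'   replaced wholesale.
#' @return A list of class `ppi_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(notch_base_hz = 50)
#' cfg$emg$band_hz
pipeline_config <- function(...) {
  cfg <- list(
    highpass_hz = 0.25,
    filter_order = 4L,
    notch_enabled = TRUE,
    notch_base_hz = 60,
    notch_halfwidth_hz = 2,
    adc_resolution = 0.0488,
    responder_digital_units = 20,
    emg = list(
      derivation = "bipolar",          # or "mean"
      band_hz = c(24, 200),
      envelope_lowpass_hz = 15.9,
      window_ms = c(-300, 300),
      baseline_ms = c(-50, 0),
      asr_window_ms = c(20, 120),
      baseline_subtract = TRUE,
      reject_rule = "disjunctive"      # or "conjunctive"
    ),
    eeg = list(
      epoch_ms = c(-1000, 1000),
      baseline_ms = c(-650, -150),
      lowpass_hz = 40,
      n1_window_ms = c(60, 165),
      p2_window_ms = c(165, 275),
      analysis_channels = c("Fz", "Cz", "Pz")
    ),
    ica = list(
      seed = 1L,
      max_iter = 512L,
      tol = 1e-7,
      max_fit_samples = 20000L,
      autocorr_lag_ms = 20,
      autocorr_threshold = "auto",     # or a fixed r in (0, 1)
      focal_topo_z = 3.5,
      focal_trial_z = 10,
      snr_ratio_threshold = 1,
      ref_corr_threshold = 0.2,
      combine = "union"                # or "vote"
    ),
    sync_emg_rejection_to_eeg = FALSE
  )
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "ppi_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  win_ok <- function(w) length(w) == 2 && w[1] < w[2]
  stop_if(cfg$highpass_hz <= 0, "highpass_hz must be positive")
  stop_if(cfg$adc_resolution <= 0, "adc_resolution must be positive")
  stop_if(!win_ok(cfg$emg$window_ms), "emg window_ms must be (start < end)")
  stop_if(!win_ok(cfg$emg$baseline_ms), "emg baseline_ms must be (start < end)")
  stop_if(!win_ok(cfg$emg$asr_window_ms), "emg asr_window_ms must be (start < end)")
  stop_if(!win_ok(cfg$eeg$epoch_ms), "eeg epoch_ms must be (start < end)")
  stop_if(!win_ok(cfg$eeg$baseline_ms), "eeg baseline_ms must be (start < end)")
  stop_if(!win_ok(cfg$eeg$n1_window_ms), "eeg n1_window_ms must be (start < end)")
  stop_if(!win_ok(cfg$eeg$p2_window_ms), "eeg p2_window_ms must be (start < end)")
  stop_if(cfg$emg$band_hz[1] >= cfg$emg$band_hz[2], "emg band_hz must ascend")
  stop_if(cfg$ica$focal_topo_z <= 0 || cfg$ica$focal_trial_z <= 0 ||
            cfg$ica$snr_ratio_threshold <= 0 || cfg$ica$ref_corr_threshold <= 0,
          "ICA classifier thresholds must be positive")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML file mirrors [pipeline_config()]; absent fields keep their
#' defaults, so a config file only needs the values it changes.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `ppi_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a `ppi_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ms -> sample-offset helpers shared by every windowing operation.
# Onsets are 0-based sample indices; a window (a, b) in ms maps to the
# half-open sample range [round(a*rate/1000), round(a*rate/1000) + n) with
# n = round((b - a)*rate/1000), so segment length depends only on duration.
ms_to_samples <- function(ms, rate) as.integer(round(ms * rate / 1000))

window_offsets <- function(window_ms, rate) {
  start <- ms_to_samples(window_ms[1], rate)
  n <- as.integer(round(diff(window_ms) * rate / 1000))
  list(start = start, n = n)
}

# Index vector (1-based, within a segment whose first sample is seg_start
# samples from the event) of the half-open ms window [a, b).
window_index <- function(window_ms, rate, seg_start, seg_len) {
  lo <- ms_to_samples(window_ms[1], rate) - seg_start + 1L
  hi <- ms_to_samples(window_ms[2], rate) - seg_start
  idx <- seq.int(max(1L, lo), min(seg_len, hi))
  if (lo > hi) stop("empty window after rounding", call. = FALSE)
  idx
}

# Inclusive ms window [a, b] (used by the peak-search and ASR windows).
window_index_incl <- function(window_ms, rate, seg_start, seg_len) {
  lo <- ms_to_samples(window_ms[1], rate) - seg_start + 1L
  hi <- ms_to_samples(window_ms[2], rate) - seg_start + 1L
  if (lo < 1L || hi > seg_len) stop("window outside segment", call. = FALSE)
  seq.int(lo, hi)
}
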