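#' Derive the orbicularis EMG channel
#'
#' The two periocular electrodes form one EMG signal. The standard bipolar
#' derivation EMG1 - EMG2 is the default; `derivation = "mean"` averages the
#' two channels instead.
#'
#' @param rec a [ppi_recording()] with exactly two `emg` channels.
#' @param derivation `"bipolar"` (EMG1 - EMG2) or `"mean"`.
#' @return Numeric vector, the derived EMG series in uV.
#' @export
derive_emg_channel <- function(rec, derivation = c("bipolar", "mean")) {
  derivation <- match.arg(derivation)
  idx <- channels_by_role(rec, "emg")
  if (length(idx) != 2) {
    stop("EMG derivation requires exactly 2 emg channels, found ",
         length(idx), call. = FALSE)
  }
  if (derivation == "bipolar") {
    rec$data[idx[1], ] - rec$data[idx[2], ]
  } else {
    (rec$data[idx[1], ] + rec$data[idx[2], ]) / 2
  }
}

#' Rectified EMG envelope
#'
#' Band-pass filters the EMG to the 24--200 Hz muscle band, full-wave
#' rectifies, then low-pass filters at 15.9 Hz. Small negative excursions from
#' low-pass ringing are clamped to zero so the envelope is nonnegative.
#'
#' @param emg numeric vector, EMG in uV.
#' @param rate sampling rate in Hz; must exceed 400 Hz so the 200 Hz band edge
#'   stays below Nyquist.
#' @param band_hz band-pass corner pair (default `c(24, 200)`).
#' @param lowpass_hz envelope smoothing cutoff (default 15.9).
#' @param order Butterworth design order per pass.
#' @return Nonnegative numeric vector, the envelope in uV.
#' @export
emg_envelope <- function(emg, rate, band_hz = c(24, 200), lowpass_hz = 15.9,
                         order = 4L) {
  if (rate <= 2 * band_hz[2]) {
    stop("rate must exceed twice the upper band edge (", 2 * band_hz[2],
         " Hz)", call. = FALSE)
  }
  x <- zero_phase_filter(emg, filter_spec("bandpass", band_hz, order), rate)
  env <- zero_phase_filter(abs(x), filter_spec("lowpass", lowpass_hz, order), rate)
  pmax(env, 0)
}

#' Segment the EMG envelope around pulse onsets
#'
#' Cuts one -300..+300 ms segment per event and stores the mean over the 50 ms
#' pre-stimulus baseline. Events without a full margin on both sides are
#' excluded (reported, never silently dropped).
#'
#' @param env envelope series from [emg_envelope()].
#' @param events a [ppi_events()] table.
#' @param rate sampling rate in Hz.
#' @param window_ms segment window relative to the pulse (default
#'   `c(-300, 300)`).
#' @param baseline_ms baseline window (default `c(-50, 0)`, half-open).
#' @return List of class `envelope_trials`: `trials` (trial x sample matrix),
#'   `baseline_mean`, `condition`, `trial_index` (row of `events`), `window_ms`,
#'   `rate`, `n_excluded`.
#' @export
segment_envelope <- function(env, events, rate, window_ms = c(-300, 300),
                             baseline_ms = c(-50, 0)) {
  off <- window_offsets(window_ms, rate)
  ok <- events_in_bounds(events, length(env), rate, window_ms)
  if (!any(ok)) stop("no events with a full segment window", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " event(s) too close to the recording edge excluded ",
            "from EMG segmentation")
  }
  kept <- which(ok)
  trials <- t(vapply(kept, function(i) {
    s <- events$onset[i] + off$start            # 0-based first sample
    env[(s + 1):(s + off$n)]
  }, numeric(off$n)))
  bl_idx <- window_index(baseline_ms, rate, off$start, off$n)
  structure(list(
    trials = trials,
    baseline_mean = rowMeans(trials[, bl_idx, drop = FALSE]),
    condition = events$condition[kept],
    trial_index = kept,
    window_ms = window_ms,
    baseline_ms = baseline_ms,
    rate = rate,
    n_excluded = sum(!ok)
  ), class = "envelope_trials")
}

#' Score the acoustic startle reflex per trial
#'
#' The ASR is the maximum of the envelope in the 20--120 ms post-pulse window
#' (endpoints inclusive after ms-to-sample rounding). With
#' `baseline_subtract = TRUE` (default) the trial's pre-stimulus baseline mean
#' is subtracted and the result floored at zero, so a trial with no blink
#' scores 0 rather than a negative amplitude.
#'
#' @param trials an `envelope_trials` object from [segment_envelope()].
#' @param asr_window_ms scoring window (default `c(20, 120)`).
#' @param baseline_subtract subtract the per-trial baseline mean?
#' @return data.frame of class `asr_table`: one row per trial with `trial`,
#'   `condition`, `baseline_uv`, `peak_uv` (raw in-window maximum), `asr_uv`,
#'   `rejected`, `reason`.
#' @export
score_asr <- function(trials, asr_window_ms = c(20, 120),
                      baseline_subtract = TRUE) {
  off <- window_offsets(trials$window_ms, trials$rate)
  idx <- window_index_incl(asr_window_ms, trials$rate, off$start, off$n)
  peak <- apply(trials$trials[, idx, drop = FALSE], 1, max)
  asr <- if (baseline_subtract) pmax(peak - trials$baseline_mean, 0) else peak
  out <- data.frame(
    trial = trials$trial_index,
    condition = trials$condition,
    baseline_uv = trials$baseline_mean,
    peak_uv = peak,
    asr_uv = asr,
    rejected = FALSE,
    reason = "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("asr_table", "data.frame")
  out
}

#' Reject outlier startle trials
#'
#' A trial is an amplitude outlier when its raw in-window maximum exceeds
#' mean + 3 SD of the in-window maxima of the other trials of its condition,
#' and a baseline outlier when its baseline mean exceeds mean + 3 SD of the
#' subject's other baseline means. The reference statistics leave the
#' candidate trial out, so a single extreme trial cannot inflate the spread it
#' is compared against; the comparison is strict, so a zero-variance set
#' rejects nothing, and the rule is single-pass (statistics are never
#' recomputed after removal). With the default disjunctive rule either
#' criterion rejects; `"conjunctive"` requires both.
#'
#' @param table an `asr_table` from [score_asr()].
#' @param rule `"disjunctive"` (default) or `"conjunctive"`.
#' @return The table with `rejected` and `reason` filled in. Conditions left
#'   with fewer than 3 kept trials are flagged in attribute `low_n_conditions`.
#' @export
reject_trials <- function(table, rule = c("disjunctive", "conjunctive")) {
  rule <- match.arg(rule)
  loo_outlier <- function(x) {
    vapply(seq_along(x), function(i) {
      if (length(x) < 3) return(FALSE)       # leave-one-out SD undefined
      rest <- x[-i]
      # the relative epsilon keeps numerically identical trials (floating-
      # point jitter only) from rejecting their own maximum
      x[i] > mean(rest) + 3 * stats::sd(rest) + 1e-9 * abs(mean(rest))
    }, TRUE)
  }
  amp_out <- logical(nrow(table))
  for (cond in unique(table$condition)) {
    i <- table$condition == cond
    amp_out[i] <- loo_outlier(table$peak_uv[i])
  }
  bl_out <- loo_outlier(table$baseline_uv)
  rej <- if (rule == "disjunctive") amp_out | bl_out else amp_out & bl_out
  table$rejected <- rej
  table$reason <- ifelse(rej,
                         trimws(paste(ifelse(amp_out, "amplitude_outlier", ""),
                                      ifelse(bl_out, "baseline_outlier", ""))),
                         "")
  low <- vapply(split(!table$rejected, table$condition), sum, 0L) < 3
  attr(table, "low_n_conditions") <- names(low)[low]
  table
}

#' Condition-mean ASR over kept trials
#'
#' @param table an `asr_table` (after [reject_trials()]).
#' @return data.frame with `condition`, `mean_asr_uv`, `n_kept`.
#' @export
asr_condition_means <- function(table) {
  kept <- table[!table$rejected, , drop = FALSE]
  conds <- intersect(ppi_conditions(), unique(table$condition))
  data.frame(
    condition = conds,
    mean_asr_uv = vapply(conds, function(k) {
      v <- kept$asr_uv[kept$condition == k]
      if (length(v)) mean(v) else NA_real_
    }, 0),
    n_kept = vapply(conds, function(k) sum(kept$condition == k), 0L),
    row.names = NULL
  )
}

#' Classify a subject as startle responder or non-responder
#'
#' A subject is a non-responder when the mean ASR over kept pulse-alone trials
#' falls below 20 digital units of the acquisition system (with the default
#' 0.0488 uV/unit resolution: 0.976 uV). The boundary itself counts as a
#' responder ("less than" excludes).
#'
#' @param table an `asr_table` after rejection.
#' @param adc_resolution uV per digital unit.
#' @param digital_units threshold in digital units (default 20).
#' @return List of class `responder_status`: `mean_p_asr`, `threshold_uv`,
#'   `is_responder`.
#' @export
classify_responder <- function(table, adc_resolution = 0.0488,
                               digital_units = 20) {
  kept <- table[!table$rejected & table$condition == "P", , drop = FALSE]
  if (nrow(kept) == 0) stop("no kept pulse-alone trials", call. = FALSE)
  thr <- digital_units * adc_resolution
  m <- mean(kept$asr_uv)
  structure(list(mean_p_asr = m, threshold_uv = thr,
                 is_responder = m >= thr), class = "responder_status")
}
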