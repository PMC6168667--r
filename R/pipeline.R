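#' Run the full pipeline for one subject
#'
#' Orchestrates both measurement branches from a raw recording: earlobe
#' re-referencing and continuous conditioning (0.25 Hz zero-phase high-pass,
#' mains-notch cascade), then the EMG branch (envelope, segmentation, startle
#' scoring, outlier-trial rejection, responder classification) and the EEG
#' branch (epoching with pre-stimulus baseline, Infomax ICA with automated
#' artifact-component removal, 40 Hz epoch low-pass, condition-wise ERP
#' averaging, N1/P2 peak measurement). The identical event set feeds both
#' branches; EMG-rejected trials stay in the EEG branch unless
#' `cfg$sync_emg_rejection_to_eeg` is set, and no statistical epoch rejection
#' is ever applied to the EEG.
#'
#' @param rec raw [ppi_recording()].
#' @param events [ppi_events()].
#' @param cfg a [pipeline_config()].
#' @param subject subject identifier carried into the outputs.
#' @param branches branches to run (`"emg"`, `"eeg"` or both).
#' @param ica run ICA cleaning in the EEG branch? Disable only for
#'   noise-free synthetic data whose scalp covariance is rank-deficient.
#' @param raw_erp also average the epochs before ICA cleaning (into `erp_raw`
#'   and `peaks_raw`), for cleaning-efficacy evaluation.
#' @return List of class `ppi_subject`: `subject`, `asr` (trial table),
#'   `asr_means`, `responder`, `peaks` (N1/P2 table), `ic_scores`, `erp`,
#'   `manifest` (per-stage counts and parameters).
#' @export
run_subject <- function(rec, events, cfg = pipeline_config(), subject = "s01",
                        branches = c("emg", "eeg"), ica = TRUE,
                        raw_erp = FALSE) {
  manifest <- list(subject = subject, rate = rec$rate,
                   n_events = nrow(events), config = unclass(cfg))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  rec <- stage("rereference", rereference(rec))
  nonref <- which(rec$channels$role != "reference")
  rec$data[nonref, ] <- stage("highpass", zero_phase_filter(
    rec$data[nonref, , drop = FALSE],
    filter_spec("highpass", cfg$highpass_hz, cfg$filter_order), rec$rate))
  if (isTRUE(cfg$notch_enabled)) {
    rec$data[nonref, ] <- stage("notch", notch_mains(
      rec$data[nonref, , drop = FALSE], rec$rate, cfg$notch_base_hz,
      cfg$notch_halfwidth_hz, cfg$filter_order))
  }

  out <- list(subject = subject, manifest = manifest)
  if ("emg" %in% branches) {
    emg <- stage("emg_derivation", derive_emg_channel(rec, cfg$emg$derivation))
    env <- stage("emg_envelope", emg_envelope(
      emg, rec$rate, cfg$emg$band_hz, cfg$emg$envelope_lowpass_hz,
      cfg$filter_order))
    trials <- stage("emg_segmentation", segment_envelope(
      env, events, rec$rate, cfg$emg$window_ms, cfg$emg$baseline_ms))
    asr <- stage("asr_scoring", score_asr(trials, cfg$emg$asr_window_ms,
                                          cfg$emg$baseline_subtract))
    asr <- stage("trial_rejection", reject_trials(asr, cfg$emg$reject_rule))
    asr$subject <- subject
    out$asr <- asr
    out$asr_means <- asr_condition_means(asr)
    out$responder <- stage("responder", classify_responder(
      asr, cfg$adc_resolution, cfg$responder_digital_units))
    out$manifest$emg <- list(
      n_trials = nrow(asr),
      n_rejected = sum(asr$rejected),
      n_excluded_margin = trials$n_excluded,
      is_responder = out$responder$is_responder,
      mean_p_asr_uv = out$responder$mean_p_asr,
      threshold_uv = out$responder$threshold_uv
    )
  }
  if ("eeg" %in% branches) {
    ep <- stage("epoching", epoch_eeg(rec, events, roles = "scalp",
                                      cfg$eeg$epoch_ms, cfg$eeg$baseline_ms))
    if (isTRUE(cfg$sync_emg_rejection_to_eeg) && !is.null(out$asr)) {
      keep <- !ep$trial_index %in% out$asr$trial[out$asr$rejected]
      ep$data <- ep$data[keep, , , drop = FALSE]
      ep$condition <- ep$condition[keep]
      ep$trial_index <- ep$trial_index[keep]
    }
    if (isTRUE(raw_erp)) {
      out$erp_raw <- average_erp(lowpass_epochs(ep, cfg$eeg$lowpass_hz,
                                                cfg$filter_order))
      pr <- measure_peaks(out$erp_raw, cfg$eeg$analysis_channels,
                          cfg$eeg$n1_window_ms, cfg$eeg$p2_window_ms)
      pr$subject <- subject
      out$peaks_raw <- pr
    }
    removed <- 0L
    if (isTRUE(ica)) {
      dec <- stage("ica_fit", fit_ica(ep, cfg$ica$seed, cfg$ica$max_iter,
                                      cfg$ica$tol, cfg$ica$max_fit_samples))
      refs <- stage("ica_references", flatten_epochs(epoch_eeg(
        rec, events, roles = c("eog", "emg"), cfg$eeg$epoch_ms,
        baseline_ms = NULL)))
      scores <- stage("ica_classification", score_components(
        dec, refs,
        autocorr_lag_ms = cfg$ica$autocorr_lag_ms,
        autocorr_threshold = cfg$ica$autocorr_threshold,
        focal_topo_z = cfg$ica$focal_topo_z,
        focal_trial_z = cfg$ica$focal_trial_z,
        snr_ratio_threshold = cfg$ica$snr_ratio_threshold,
        ref_corr_threshold = cfg$ica$ref_corr_threshold,
        combine = cfg$ica$combine))
      ep <- stage("ica_removal", remove_components(ep, dec, scores))
      scores$subject <- subject
      out$ic_scores <- scores
      out$ica_info <- list(iterations = dec$iterations,
                           final_change = dec$final_change,
                           unmixing = dec$unmixing,
                           mixing = dec$mixing,
                           channel_names = dec$channels$name)
      removed <- sum(scores$final_artifact)
    }
    ep <- stage("epoch_lowpass", lowpass_epochs(ep, cfg$eeg$lowpass_hz,
                                                cfg$filter_order))
    out$erp <- stage("erp_average", average_erp(ep))
    peaks <- stage("peak_measurement", measure_peaks(
      out$erp, cfg$eeg$analysis_channels, cfg$eeg$n1_window_ms,
      cfg$eeg$p2_window_ms))
    peaks$subject <- subject
    out$peaks <- peaks
    out$manifest$eeg <- list(
      n_epochs = length(ep$condition),
      n_excluded_margin = ep$n_excluded,
      n_components_removed = removed,
      ica = isTRUE(ica)
    )
  }
  structure(out, class = "ppi_subject")
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed.
#'
#' @param n_subjects cohort size.
#' @param sim_cfg a [simulation_config()].
#' @param master_seed master seed.
#' @return List of `sim_session` objects.
#' @export
simulate_group <- function(n_subjects, sim_cfg = simulation_config(),
                           master_seed = sim_cfg$seed) {
  lapply(seq_len(n_subjects), function(i) {
    simulate_session(sim_cfg, subject_seed = (master_seed * 1009L + i) %%
                       .Machine$integer.max)
  })
}

#' Group-level PPI table from per-subject results
#'
#' Long table of condition amplitudes per modality (ASR plus one modality per
#' analysis electrode), restricted to startle responders.
#'
#' @param subjects list of `ppi_subject` results.
#' @param responders_only drop non-responders (default TRUE)?
#' @return data.frame: `subject`, `modality`, `condition`, `amplitude`.
#' @export
group_ppi_table <- function(subjects, responders_only = TRUE) {
  rows <- list()
  for (s in subjects) {
    if (responders_only && !is.null(s$responder) &&
        !s$responder$is_responder) next
    if (!is.null(s$asr_means)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subject, modality = "ASR",
        condition = s$asr_means$condition,
        amplitude = s$asr_means$mean_asr_uv, stringsAsFactors = FALSE)
    }
    if (!is.null(s$peaks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subject, modality = s$peaks$channel,
        condition = s$peaks$condition,
        amplitude = s$peaks$p2n1_uv, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no subjects contribute to the group table",
                          call. = FALSE)
  do.call(rbind, rows)
}

#' Group-level analysis
#'
#' Aggregates responders into the PPI table and runs the statistical battery.
#'
#' @param subjects list of `ppi_subject` results.
#' @param alpha significance level for the omnibus gate.
#' @return List of class `ppi_group`: `ppi_table`, `report`
#'   ([ppi_statistics()] output), `n_responders`, `n_subjects`.
#' @export
run_group <- function(subjects, alpha = 0.05) {
  if (!length(subjects)) stop("empty subject list", call. = FALSE)
  resp <- vapply(subjects, function(s) {
    is.null(s$responder) || s$responder$is_responder
  }, TRUE)
  if (sum(resp) < 3) {
    stop("need at least 3 responders for group statistics, have ", sum(resp),
         call. = FALSE)
  }
  tab <- group_ppi_table(subjects)
  structure(list(
    ppi_table = tab,
    report = ppi_statistics(tab, alpha),
    n_responders = sum(resp),
    n_subjects = length(subjects)
  ), class = "ppi_group")
}

#' Write group results to disk
#'
#' Emits `report.json` (amplitude and %PPI means with SE, omnibus and post-hoc
#' p-values per modality, Kendall correlations), `asr.tsv`, `erp.tsv`,
#' `ic_scores.tsv` and `manifest.json`.
#'
#' @param group a `ppi_group` from [run_group()].
#' @param subjects the per-subject results the group was built from.
#' @param dir output directory.
#' @return Invisibly, the output directory.
#' @export
write_report <- function(group, subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_json <- lapply(group$report, function(entry) {
    if (is.data.frame(entry)) return(entry)
    lapply(entry, function(x) if (inherits(x, "ppi_stat")) unclass(x) else x)
  })
  jsonlite::write_json(
    list(n_subjects = group$n_subjects, n_responders = group$n_responders,
         results = rep_json),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns", force = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  asr <- do.call(rbind, Filter(Negate(is.null), lapply(subjects, `[[`, "asr")))
  if (!is.null(asr)) wt(asr, "asr.tsv")
  peaks <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(subjects, `[[`, "peaks")))
  if (!is.null(peaks)) wt(peaks, "erp.tsv")
  ics <- do.call(rbind, Filter(Negate(is.null),
                               lapply(subjects, `[[`, "ic_scores")))
  if (!is.null(ics)) wt(ics, "ic_scores.tsv")
  manifests <- lapply(subjects, `[[`, "manifest")
  jsonlite::write_json(manifests, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
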