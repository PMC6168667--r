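#' Recover planted ground truth from a simulated session
#'
#' Runs the full pipeline on a simulated session and compares the result with
#' the session's planted values: recovered muscular %PPI (ASR), recovered
#' neural %PPI per analysis electrode, and — when ICA runs — the cleaning
#' efficacy (RMS error of the cleaned against the ground-truth neural ERP,
#' relative to the raw ERP's error) and whether the planted blink and neural
#' sources were flagged by the component classifier. The blink (neural)
#' component is identified as the component whose scalp mixing column is most
#' collinear with the planted blink (neural) gain vector.
#'
#' @param session a `sim_session` from [simulate_session()].
#' @param cfg a [pipeline_config()].
#' @param ica run the ICA cleaning stage (disable for noise-free sessions
#'   whose scalp covariance is rank-deficient)?
#' @param branches pipeline branches to run.
#' @param rms_channel channel for the ERP RMS-error comparison (default Fz).
#' @param ica_metrics compute the cleaning-efficacy metrics (adds a raw-ERP
#'   averaging pass)?
#' @return List of class `ppi_recovery`: `muscular_ppi` (recovered),
#'   `muscular_error` (recovered - planted), `neural_ppi` /`neural_error`
#'   (matrices electrode x interval), `responder`, `n_rejected`; with ICA:
#'   `rms_raw`, `rms_clean`, `rms_reduction` (1 - clean/raw),
#'   `blink_component`, `blink_flagged`, `neural_component`, `neural_flagged`,
#'   plus the full `subject` result.
#' @export
evaluate_recovery <- function(session, cfg = pipeline_config(), ica = TRUE,
                              branches = c("emg", "eeg"),
                              rms_channel = "Fz", ica_metrics = TRUE) {
  truth <- session$truth
  res <- run_subject(session$recording, session$events, cfg,
                     subject = paste0("seed", truth$seed),
                     branches = branches, ica = ica,
                     raw_erp = isTRUE(ica) && isTRUE(ica_metrics))
  out <- list(subject = res)
  if (!is.null(res$asr_means)) {
    amps <- stats::setNames(res$asr_means$mean_asr_uv,
                            res$asr_means$condition)
    out$muscular_ppi <- ppi_from_amplitudes(amps)
    planted <- stats::setNames(truth$muscular_ppi,
                               paste0("PPI", c(30, 60, 120)))
    out$muscular_error <- out$muscular_ppi - planted[names(out$muscular_ppi)]
    out$responder <- res$responder$is_responder
    out$n_rejected <- sum(res$asr$rejected)
  }
  if (!is.null(res$peaks)) {
    chs <- unique(res$peaks$channel)
    out$neural_ppi <- t(vapply(chs, function(ch) {
      p <- res$peaks[res$peaks$channel == ch, ]
      ppi_from_amplitudes(stats::setNames(p$p2n1_uv, p$condition))
    }, numeric(3)))
    planted_n <- stats::setNames(truth$neural_ppi,
                                 paste0("PPI", c(30, 60, 120)))
    out$neural_error <- sweep(out$neural_ppi, 2,
                              planted_n[colnames(out$neural_ppi)])
  }
  if (isTRUE(ica) && isTRUE(ica_metrics) && !is.null(res$ica_info)) {
    # ground-truth ERP at the comparison channel, per condition
    tm <- truth$erp_template[rms_channel, ]
    rms <- function(erp_set) {
      sqrt(mean(unlist(lapply(names(erp_set$waveforms), function(cond) {
        (erp_set$waveforms[[cond]][rms_channel, ] -
           truth$neural_scale[[cond]] * tm)^2
      }))))
    }
    out$rms_raw <- rms(res$erp_raw)
    out$rms_clean <- rms(res$erp)
    out$rms_reduction <- 1 - out$rms_clean / out$rms_raw
    # identify planted sources among the fitted components
    mix <- res$ica_info$mixing
    chn <- res$ica_info$channel_names
    cosine <- function(gains) {
      g <- rep(0, length(chn))
      names(g) <- chn
      common <- intersect(chn, names(gains))
      g[common] <- unlist(gains[common])
      apply(mix, 2, function(m) {
        abs(sum(m * g)) / sqrt(sum(m^2) * sum(g^2))
      })
    }
    flagged <- res$ic_scores$final_artifact
    out$blink_component <- which.max(cosine(truth$blink_mixing))
    out$blink_flagged <- flagged[out$blink_component]
    neural_gains <- as.list(stats::setNames(
      truth$erp_template[, which.max(abs(truth$erp_template["Fz", ]))],
      rownames(truth$erp_template)))
    out$neural_component <- which.max(cosine(neural_gains))
    out$neural_flagged <- flagged[out$neural_component]
  }
  structure(out, class = "ppi_recovery")
}

#' Multi-seed recovery study on simulated cohorts
#'
#' Simulates `n_subjects` per seed, runs the pipeline on each, and aggregates
#' the recovered %PPI into per-seed group means, together with the ICA
#' cleaning-efficacy metrics of each seed's first subject.
#'
#' @param seeds integer vector of master seeds.
#' @param n_subjects subjects per seed.
#' @param sim_cfg a [simulation_config()].
#' @param cfg a [pipeline_config()].
#' @param progress print one line per seed?
#' @param metrics_all compute the ICA efficacy metrics for every subject
#'   (default: first subject of each seed only).
#' @return List: `muscular` (seeds x interval matrix of group-mean recovered
#'   muscular %PPI), `neural` (electrode-named list of such matrices),
#'   `rms_reduction`, `blink_flagged`, `neural_flagged` (one value per
#'   metrics subject), `planted` (list of planted values).
#' @export
recovery_study <- function(seeds, n_subjects = 8,
                           sim_cfg = simulation_config(),
                           cfg = pipeline_config(), progress = FALSE,
                           metrics_all = FALSE) {
  ivs <- paste0("PPI", c(30, 60, 120))
  mus <- matrix(NA_real_, length(seeds), 3,
                dimnames = list(seeds, ivs))
  electrodes <- cfg$eeg$analysis_channels
  neu <- lapply(stats::setNames(electrodes, electrodes), function(e) mus)
  rmsr <- blinkf <- neuralf <- NULL
  for (i in seq_along(seeds)) {
    sessions <- simulate_group(n_subjects, sim_cfg, master_seed = seeds[i])
    recs <- lapply(seq_along(sessions), function(j) {
      evaluate_recovery(sessions[[j]], cfg = cfg,
                        ica_metrics = metrics_all || j == 1L)
    })
    mus[i, ] <- colMeans(do.call(rbind, lapply(recs, `[[`, "muscular_ppi")))
    for (e in electrodes) {
      neu[[e]][i, ] <- colMeans(do.call(rbind, lapply(recs, function(r) {
        r$neural_ppi[e, ]
      })))
    }
    with_metrics <- Filter(function(r) !is.null(r$rms_reduction), recs)
    rmsr <- c(rmsr, vapply(with_metrics, `[[`, 0, "rms_reduction"))
    blinkf <- c(blinkf, vapply(with_metrics, `[[`, TRUE, "blink_flagged"))
    neuralf <- c(neuralf, vapply(with_metrics, `[[`, TRUE, "neural_flagged"))
    if (progress) {
      message(sprintf("seed %d: muscular %s",
                      seeds[i], paste(round(mus[i, ], 1), collapse = "/")))
    }
  }
  list(muscular = mus, neural = neu, rms_reduction = rmsr,
       blink_flagged = blinkf, neural_flagged = neuralf,
       planted = list(muscular = sim_cfg$startle$muscular_ppi,
                      neural = sim_cfg$neural$neural_ppi))
}
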