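#' Infomax ICA decomposition of scalp EEG epochs
#'
#' Fits natural-gradient logistic Infomax to the concatenated scalp epochs.
#' The data are mean-removed per channel and sphered (2 x inverse matrix
#' square root of the covariance) before the weight estimation; the returned
#' unmixing matrix includes the sphering, so
#' `activations = unmixing %*% (data - center)` holds exactly. Components are
#' ordered by descending projected variance and sign-fixed (largest mixing
#' weight positive), making the decomposition deterministic for a given seed.
#'
#' For long sessions the weight fit runs on a seeded subset of whole epochs
#' capped at `max_fit_samples` concatenated samples (well above the
#' 20 x channels^2 rank guidance); activations are then computed for all
#' epochs with the fitted unmixing matrix.
#'
#' @param ep an `epoch_set` of scalp channels (artifact reference channels are
#'   never part of the decomposition).
#' @param seed integer seed for the sample shuffling and epoch subsetting.
#' @param max_iter,tol stopping rule: stop when the squared weight change per
#'   step falls below `tol` (default 1e-7) or after `max_iter` (default 512)
#'   steps.
#' @param max_fit_samples cap on concatenated samples used for weight fitting
#'   (default 20000, roughly 8 times the rank guidance for 11 channels).
#' @return List of class `ppi_ica`: `unmixing` (components x channels),
#'   `mixing` (channels x components), `activations` (components x
#'   epochs*samples), `center`, `channels`, `n_epochs`, `n_samples` (per
#'   epoch), `condition`, `window_ms`, `rate`, `seed`, `iterations`,
#'   `final_change`.
#' @export
fit_ica <- function(ep, seed = 1L, max_iter = 512L, tol = 1e-7,
                    max_fit_samples = 20000L) {
  d <- dim(ep$data)
  n_ep <- d[1]; n_ch <- d[2]; n_sm <- d[3]
  X <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = n_ch)  # ch x (samples*epochs)
  center <- rowMeans(X)
  X <- X - center
  cv <- tcrossprod(X) / (ncol(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    stop("scalp data are rank-deficient; exclude interpolated or bridged ",
         "channels before ICA", call. = FALSE)
  }
  if (ncol(X) < 20 * n_ch^2) {
    warning("fewer than 20 x channels^2 samples for ICA; decomposition may ",
            "be unstable", call. = FALSE)
  }
  sphere <- 2 * eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  # seeded subset of whole epochs for the weight fit
  fit_idx <- seq_len(ncol(X))
  if (ncol(X) > max_fit_samples) {
    k <- max(1L, floor(max_fit_samples / n_sm))
    eps_keep <- sort(sample_seeded(n_ep, k, seed))
    fit_idx <- as.vector(outer(seq_len(n_sm), (eps_keep - 1L) * n_sm, `+`))
  }
  fit <- infomax_weights(sphere %*% X[, fit_idx, drop = FALSE],
                         as.integer(seed), as.integer(max_iter), tol,
                         0.00065 / log(n_ch))
  unmix <- fit$weights %*% sphere
  mix <- solve(unmix)
  act <- unmix %*% X
  # order by projected variance, then fix signs
  pvar <- colSums(mix^2) * rowMeans(act^2)
  o <- order(pvar, decreasing = TRUE)
  unmix <- unmix[o, , drop = FALSE]
  mix <- mix[, o, drop = FALSE]
  act <- act[o, , drop = FALSE]
  flip <- vapply(seq_len(n_ch),
                 function(i) sign(mix[which.max(abs(mix[, i])), i]), 0)
  flip[flip == 0] <- 1
  unmix <- unmix * flip
  act <- act * flip
  mix <- t(t(mix) / flip)
  structure(list(
    unmixing = unmix, mixing = mix, activations = act, center = center,
    channels = ep$channels, n_epochs = n_ep, n_samples = n_sm,
    condition = ep$condition, window_ms = ep$window_ms, rate = ep$rate,
    seed = as.integer(seed), iterations = fit$iterations,
    final_change = fit$final_change
  ), class = "ppi_ica")
}

# deterministic sample() that does not disturb the caller's RNG state
sample_seeded <- function(n, k, seed) {
  rs <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  sample.int(n, k)
}

#' @export
print.ppi_ica <- function(x, ...) {
  cat(sprintf("<ppi_ica> %d components over %d epochs (%d iterations, final weight change %.2e)\n",
              nrow(x$unmixing), x$n_epochs, x$iterations, x$final_change))
  invisible(x)
}

act_by_epoch <- function(dec) {
  array(dec$activations, dim = c(nrow(dec$activations), dec$n_samples,
                                 dec$n_epochs))
}

#' Temporal autocorrelation of component activations
#'
#' Pearson autocorrelation of each component at `lag_ms`, computed per epoch
#' and averaged. Muscle-dominated components have broadband, rapidly decaying
#' activity and score low. Components with (near-)constant activation within
#' an epoch contribute 1 by convention. The flag is set when the value falls
#' below the threshold; the `"auto"` threshold is mean - 2 SD across the
#' decomposition's components.
#'
#' @param dec a `ppi_ica`.
#' @param lag_ms autocorrelation lag in ms (default 20).
#' @param rate sampling rate; defaults to the decomposition's.
#' @return Numeric vector, one r per component.
#' @export
score_autocorrelation <- function(dec, lag_ms = 20, rate = dec$rate) {
  lag <- max(1L, as.integer(round(lag_ms * rate / 1000)))
  a <- act_by_epoch(dec)
  n <- dec$n_samples
  if (lag >= n) stop("autocorrelation lag exceeds epoch length", call. = FALSE)
  vapply(seq_len(dim(a)[1]), function(i) {
    r <- vapply(seq_len(dim(a)[3]), function(e) {
      x <- a[i, , e]
      if (stats::sd(x) < 1e-12) return(1)
      suppressWarnings(stats::cor(x[1:(n - lag)], x[(lag + 1):n]))
    }, 0)
    r[is.na(r)] <- 1
    mean(r)
  }, 0)
}

#' Topographic focality of components
#'
#' Z-scores the absolute mixing-column weights of each component across
#' channels and returns the maximum z. A blink or single-electrode artifact
#' loads one or two channels far above the rest; a genuinely neural component
#' has a spatially distributed topography.
#'
#' @param dec a `ppi_ica`.
#' @return Numeric vector, max |weight| z-score per component.
#' @export
score_focal_topography <- function(dec) {
  apply(abs(dec$mixing), 2, function(w) {
    s <- stats::sd(w)
    if (s < 1e-12) return(0)
    max((w - mean(w)) / s)
  })
}

#' Trial focality of components
#'
#' Per component, the per-epoch maximum absolute activation is z-scored across
#' epochs; the score is the maximum z. A component expressing a single
#' outlying trial (electrode pop, movement) scores high.
#'
#' @param dec a `ppi_ica`.
#' @return Numeric vector, max per-epoch z per component.
#' @export
score_focal_trial <- function(dec) {
  a <- act_by_epoch(dec)
  apply(apply(abs(a), c(1, 3), max), 1, function(m) {
    s <- stats::sd(m)
    if (s < 1e-12) return(0)
    max((m - mean(m)) / s)
  })
}

#' Stimulus-locked signal-to-noise ratio of component ERPs
#'
#' Averages each component's activation across epochs and compares the SD of
#' the post-stimulus period of interest with the SD of the pre-stimulus
#' baseline. Components carrying stimulus-locked activity score above 1;
#' the flag marks components scoring strictly below the threshold. A zero
#' baseline SD yields `Inf` (never flagged).
#'
#' @param dec a `ppi_ica`.
#' @param poi_ms period of interest (default 0 ms to the epoch end).
#' @param bl_ms baseline period (default epoch start to 0 ms).
#' @return Numeric vector of SD ratios.
#' @export
score_snr <- function(dec, poi_ms = c(0, dec$window_ms[2]),
                      bl_ms = c(dec$window_ms[1], 0)) {
  a <- act_by_epoch(dec)
  erp <- apply(a, c(1, 2), mean)        # components x samples
  off <- window_offsets(dec$window_ms, dec$rate)
  i_poi <- window_index(poi_ms, dec$rate, off$start, off$n)
  i_bl <- window_index(bl_ms, dec$rate, off$start, off$n)
  apply(erp, 1, function(w) {
    s_bl <- stats::sd(w[i_bl])
    if (s_bl < 1e-15) return(Inf)
    stats::sd(w[i_poi]) / s_bl
  })
}

#' Correlation of components with artifact reference channels
#'
#' Absolute Pearson correlation of each component's concatenated activation
#' with each epoch-matched reference series (EOG, EMG1, EMG2); the score is
#' the maximum over references. Blink components correlate strongly with EOG,
#' residual muscle components with the EMG pair. Zero-variance references are
#' skipped with a warning.
#'
#' @param dec a `ppi_ica`.
#' @param refs reference x (epochs*samples) matrix, epoch-matched to the
#'   activations (e.g. `epoch_eeg(rec, events, roles = c("eog", "emg"))`
#'   flattened with [flatten_epochs()]).
#' @return Numeric vector, max |r| per component.
#' @export
score_reference_correlation <- function(dec, refs) {
  refs <- as.matrix(refs)
  if (ncol(refs) != ncol(dec$activations)) {
    stop("reference series are not epoch-matched to the activations",
         call. = FALSE)
  }
  keep <- apply(refs, 1, stats::sd) > 1e-12
  if (!all(keep)) warning("zero-variance reference channel(s) skipped", call. = FALSE)
  refs <- refs[keep, , drop = FALSE]
  if (!nrow(refs)) return(rep(0, nrow(dec$activations)))
  cc <- abs(stats::cor(t(dec$activations), t(refs)))
  apply(cc, 1, max)
}

#' Flatten an epoch set to channels x (epochs*samples)
#'
#' Concatenates epochs in epoch order, matching the layout of the ICA
#' activation matrix.
#' @param ep an `epoch_set`.
#' @return Matrix with one row per channel.
#' @export
flatten_epochs <- function(ep) {
  d <- dim(ep$data)
  m <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = d[2])
  rownames(m) <- ep$channels$name
  m
}

#' Score and classify all components
#'
#' Runs the five classification criteria and combines their flags into the
#' final artifact decision: low autocorrelation, focal topography, focal trial
#' activity, sub-unity stimulus-locked SNR, and correlation with the
#' EOG/EMG reference channels. The default combination is the union (any flag
#' removes the component); `combine = "vote"` requires at least two flags.
#'
#' @param dec a `ppi_ica`.
#' @param refs reference matrix as in [score_reference_correlation()], or
#'   `NULL` to skip that criterion.
#' @param autocorr_lag_ms,autocorr_threshold,focal_topo_z,focal_trial_z,snr_ratio_threshold,ref_corr_threshold
#'   classifier parameters; defaults are the published configuration
#'   (lag 20 ms, `"auto"` r threshold, z 3.5, z 10, ratio 1, r 0.2).
#' @param combine `"union"` or `"vote"`.
#' @return data.frame of class `component_scores`: per component the five
#'   scores, the five flags, and `final_artifact`.
#' @export
score_components <- function(dec, refs = NULL,
                             autocorr_lag_ms = 20,
                             autocorr_threshold = "auto",
                             focal_topo_z = 3.5,
                             focal_trial_z = 10,
                             snr_ratio_threshold = 1,
                             ref_corr_threshold = 0.2,
                             combine = c("union", "vote")) {
  combine <- match.arg(combine)
  autocorr_r <- score_autocorrelation(dec, autocorr_lag_ms)
  thr_auto <- if (identical(autocorr_threshold, "auto")) {
    mean(autocorr_r) - 2 * stats::sd(autocorr_r)
  } else {
    as.numeric(autocorr_threshold)
  }
  topo_z <- score_focal_topography(dec)
  trial_z <- score_focal_trial(dec)
  snr <- score_snr(dec)
  refc <- if (is.null(refs)) rep(0, nrow(dec$unmixing)) else
    score_reference_correlation(dec, refs)
  sc <- data.frame(
    component = seq_len(nrow(dec$unmixing)),
    autocorr_r = autocorr_r,
    focal_topo_z = topo_z,
    focal_trial_z = trial_z,
    snr_ratio = snr,
    max_ref_corr = refc,
    flag_autocorr = autocorr_r < thr_auto,
    flag_focal_topo = topo_z > focal_topo_z,
    flag_focal_trial = trial_z > focal_trial_z,
    flag_snr = snr < snr_ratio_threshold,
    flag_ref_corr = refc > ref_corr_threshold
  )
  class(sc) <- c("component_scores", "data.frame")
  classify_components(sc, combine)
}

#' Combine criterion flags into the final artifact decision
#'
#' @param scores a `component_scores` data.frame with the five `flag_*`
#'   columns filled.
#' @param combine `"union"` (any flag) or `"vote"` (at least two).
#' @return `scores` with `final_artifact` set.
#' @export
classify_components <- function(scores, combine = c("union", "vote")) {
  combine <- match.arg(combine)
  fl <- as.matrix(scores[, c("flag_autocorr", "flag_focal_topo",
                             "flag_focal_trial", "flag_snr", "flag_ref_corr")])
  n <- rowSums(fl)
  scores$final_artifact <- if (combine == "union") n >= 1 else n >= 2
  scores
}

#' Reconstruct epochs without the artifactual components
#'
#' Back-projects only the retained components:
#' `cleaned = mixing[, kept] %*% activations[kept, ] + center`. Epoch
#' structure and channel order are preserved. With no component flagged this
#' reproduces the ICA input to numerical precision.
#'
#' @param ep the `epoch_set` the decomposition was fitted on.
#' @param dec the `ppi_ica`.
#' @param scores a classified `component_scores` (or a logical vector of
#'   components to remove).
#' @return The cleaned `epoch_set`.
#' @export
remove_components <- function(ep, dec, scores) {
  remove <- if (is.logical(scores)) scores else scores$final_artifact
  if (length(remove) != nrow(dec$unmixing)) {
    stop("flag vector length does not match component count", call. = FALSE)
  }
  if (all(remove)) {
    stop("all components flagged as artifactual; review classifier thresholds",
         call. = FALSE)
  }
  kept <- which(!remove)
  clean <- dec$mixing[, kept, drop = FALSE] %*%
    dec$activations[kept, , drop = FALSE] + dec$center
  d <- dim(ep$data)
  ep$data <- aperm(array(clean, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  ep
}
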