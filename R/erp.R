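#' Epoch the EEG around pulse onsets
#'
#' Cuts -1..+1 s epochs around every pulse onset and subtracts, per epoch and
#' channel, the mean over the -650..-150 ms pre-stimulus baseline (half-open
#' window after ms-to-sample rounding). Events without a full margin are
#' excluded with a report. No statistical epoch rejection is performed at any
#' point: the same trials feed the neural and the muscular measure.
#'
#' @param rec a [ppi_recording()] (already re-referenced and high-pass
#'   filtered).
#' @param events a [ppi_events()] table.
#' @param roles channel roles to include (default `"scalp"`). Use
#'   `c("eog", "emg")` to extract epoch-matched artifact reference channels.
#' @param epoch_ms epoch window (default `c(-1000, 1000)`).
#' @param baseline_ms baseline window (default `c(-650, -150)`); `NULL` skips
#'   baseline subtraction.
#' @return List of class `epoch_set`: `data` (epochs x channels x samples
#'   array, uV), `channels` (channel table subset), `condition`, `trial_index`,
#'   `window_ms`, `baseline_ms`, `rate`, `n_excluded`.
#' @export
epoch_eeg <- function(rec, events, roles = "scalp",
                      epoch_ms = c(-1000, 1000),
                      baseline_ms = c(-650, -150)) {
  ch <- which(rec$channels$role %in% roles)
  if (!length(ch)) stop("no channels with role(s) ",
                        paste(roles, collapse = "/"), call. = FALSE)
  off <- window_offsets(epoch_ms, rec$rate)
  ok <- events_in_bounds(events, ncol(rec$data), rec$rate, epoch_ms)
  if (!any(ok)) stop("no events with a full epoch window", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " event(s) too close to the recording edge excluded ",
            "from epoching")
  }
  kept <- which(ok)
  data <- array(0, dim = c(length(kept), length(ch), off$n))
  for (k in seq_along(kept)) {
    s <- events$onset[kept[k]] + off$start
    data[k, , ] <- rec$data[ch, (s + 1):(s + off$n), drop = FALSE]
  }
  ep <- structure(list(
    data = data,
    channels = rec$channels[ch, , drop = FALSE],
    condition = events$condition[kept],
    trial_index = kept,
    window_ms = epoch_ms,
    baseline_ms = baseline_ms,
    rate = rec$rate,
    n_excluded = sum(!ok)
  ), class = "epoch_set")
  if (!is.null(baseline_ms)) ep <- baseline_epochs(ep) else ep
}

baseline_epochs <- function(ep) {
  off <- window_offsets(ep$window_ms, ep$rate)
  idx <- window_index(ep$baseline_ms, ep$rate, off$start, off$n)
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(bl)   # recycles over the samples dimension
  ep
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$rate))
  print(table(x$condition))
  invisible(x)
}

#' Low-pass filter every epoch
#'
#' Zero-phase 40 Hz low-pass applied per epoch and channel, after artifact
#' removal and before averaging.
#'
#' @param ep an `epoch_set`.
#' @param cutoff_hz cutoff (default 40).
#' @param order Butterworth design order.
#' @return The filtered `epoch_set`.
#' @export
lowpass_epochs <- function(ep, cutoff_hz = 40, order = 4L) {
  spec <- filter_spec("lowpass", cutoff_hz, order)
  d <- dim(ep$data)
  # one row per epoch-channel series, filtered in a single pass
  flat <- matrix(aperm(ep$data, c(3, 1, 2)), ncol = d[3], byrow = TRUE)
  flat <- zero_phase_filter(flat, spec, ep$rate)
  ep$data <- aperm(array(t(flat), c(d[3], d[1], d[2])), c(2, 3, 1))
  ep
}

#' Condition-wise ERP averaging
#'
#' Arithmetic mean across the epochs of each condition, per channel. Requested
#' conditions that are absent are omitted with a warning.
#'
#' @param ep an `epoch_set`.
#' @param conditions conditions to average (default all four).
#' @return List of class `erp_set`: `waveforms` (named list of channels x
#'   samples matrices), `n_epochs` (named), plus the epoch metadata.
#' @export
average_erp <- function(ep, conditions = ppi_conditions()) {
  present <- intersect(conditions, unique(ep$condition))
  if (!length(present)) stop("no epochs in any requested condition", call. = FALSE)
  if (length(absent <- setdiff(conditions, present))) {
    warning("condition(s) absent from the epoch set: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  wf <- lapply(present, function(k) {
    i <- which(ep$condition == k)
    m <- apply(ep$data[i, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- ep$channels$name
    m
  })
  names(wf) <- present
  structure(list(
    waveforms = wf,
    n_epochs = vapply(present, function(k) sum(ep$condition == k), 0L),
    channels = ep$channels,
    window_ms = ep$window_ms,
    rate = ep$rate
  ), class = "erp_set")
}

#' Measure N1 and P2 peaks and the P2-N1 amplitude
#'
#' N1 is the most negative sample in the 60--165 ms window and P2 the most
#' positive sample in the 165--275 ms window (window endpoints inclusive after
#' ms-to-sample rounding; ties resolve to the earliest sample). The neural
#' startle measure is the peak-to-peak amplitude `p2n1 = P2 - N1`.
#'
#' @param erp an `erp_set` from [average_erp()].
#' @param channels channel names to measure (default Fz, Cz, Pz).
#' @param n1_window_ms,p2_window_ms search windows in ms.
#' @return data.frame: `condition`, `channel`, `n1_uv`, `n1_ms`, `p2_uv`,
#'   `p2_ms`, `p2n1_uv`, `n_epochs`.
#' @export
measure_peaks <- function(erp, channels = c("Fz", "Cz", "Pz"),
                          n1_window_ms = c(60, 165),
                          p2_window_ms = c(165, 275)) {
  channels <- intersect(channels, erp$channels$name)
  if (!length(channels)) stop("no requested channel present", call. = FALSE)
  off <- window_offsets(erp$window_ms, erp$rate)
  i_n1 <- window_index_incl(n1_window_ms, erp$rate, off$start, off$n)
  i_p2 <- window_index_incl(p2_window_ms, erp$rate, off$start, off$n)
  t_ms <- (off$start + seq_len(off$n) - 1) / erp$rate * 1000
  rows <- list()
  for (cond in names(erp$waveforms)) {
    for (chn in channels) {
      w <- erp$waveforms[[cond]][chn, ]
      k1 <- i_n1[which.min(w[i_n1])]
      k2 <- i_p2[which.max(w[i_p2])]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, channel = chn,
        n1_uv = w[k1], n1_ms = t_ms[k1],
        p2_uv = w[k2], p2_ms = t_ms[k2],
        p2n1_uv = w[k2] - w[k1],
        n_epochs = erp$n_epochs[[cond]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
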