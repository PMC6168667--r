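#' Multichannel recording container
#'
#' A `ppi_recording` holds a continuous multichannel signal in microvolts plus
#' its channel table. Channels carry a role (`scalp`, `emg`, `eog`,
#' `reference`) fixed at construction; downstream stages select channels by
#' role, never by name heuristics.
#'
#' @param data numeric matrix, channels x samples, in uV.
#' @param rate sampling rate in Hz.
#' @param channels data.frame with columns `name`, `role`, `position_label`
#'   (10--20 label or ""). One row per data row.
#' @param adc_resolution uV per digital unit of the acquisition system; used by
#'   the non-responder threshold and by 16-bit file export. Default 0.0488.
#' @return An object of class `ppi_recording`.
#' @export
ppi_recording <- function(data, rate, channels, adc_resolution = 0.0488) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (!is.data.frame(channels) ||
      !all(c("name", "role") %in% names(channels))) {
    stop("channels must be a data.frame with columns name, role", call. = FALSE)
  }
  if (is.null(channels$position_label)) channels$position_label <- ""
  channels$name <- as.character(channels$name)
  channels$role <- as.character(channels$role)
  if (nrow(channels) != nrow(data)) {
    stop("channel table has ", nrow(channels), " rows but data has ",
         nrow(data), " channels", call. = FALSE)
  }
  if (anyDuplicated(channels$name)) stop("channel names must be unique", call. = FALSE)
  bad <- setdiff(unique(channels$role), c("scalp", "emg", "eog", "reference"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!any(channels$role == "scalp")) stop("at least one scalp channel required", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive", call. = FALSE)
  if (adc_resolution <= 0) stop("adc_resolution must be positive", call. = FALSE)
  rownames(data) <- channels$name
  structure(list(data = data, rate = as.numeric(rate),
                 channels = channels, adc_resolution = adc_resolution),
            class = "ppi_recording")
}

#' @export
print.ppi_recording <- function(x, ...) {
  cat(sprintf("<ppi_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  tab <- table(x$channels$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Default channel role map for the standard PPI montage
#'
#' Eleven 10--20 scalp channels, bipolar orbicularis EMG pair, one EOG channel
#' and the two earlobe references. Used by the simulator and as the default
#' role map when reading files recorded with this montage.
#'
#' @return data.frame with columns `name`, `role`, `position_label`.
#' @export
default_channels <- function() {
  scalp <- c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")
  data.frame(
    name = c(scalp, "EMG1", "EMG2", "EOG", "A1", "A2"),
    role = c(rep("scalp", 11), "emg", "emg", "eog", "reference", "reference"),
    position_label = c(scalp, "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

channels_by_role <- function(rec, role) which(rec$channels$role == role)

#' Re-reference to the earlobe average
#'
#' Subtracts the sample-wise mean of the two `reference` channels (left and
#' right earlobe) from every non-reference channel. Reference channels are kept
#' unchanged for provenance; a second call after zeroing the reference pair is
#' a no-op.
#'
#' @param rec a [ppi_recording()].
#' @return A re-referenced `ppi_recording`.
#' @export
rereference <- function(rec) {
  ref <- channels_by_role(rec, "reference")
  if (length(ref) != 2) {
    stop("re-referencing requires exactly 2 reference channels, found ",
         length(ref), call. = FALSE)
  }
  refmean <- colMeans(rec$data[ref, , drop = FALSE])
  out <- rec
  nonref <- setdiff(seq_len(nrow(rec$data)), ref)
  out$data[nonref, ] <- rec$data[nonref, , drop = FALSE] -
    rep(refmean, each = length(nonref))
  out
}

#' Event list: stimulus onsets and condition labels
#'
#' @param onsets 0-based sample indices of the pulse (P) onsets, ascending.
#' @param conditions character, one of `P`, `P30`, `P60`, `P120` per onset.
#' @param block optional integer block tag per onset.
#' @return data.frame of class `ppi_events` with columns `onset` (samples),
#'   `condition`, `block`.
#' @export
ppi_events <- function(onsets, conditions, block = NA_integer_) {
  conditions <- as.character(conditions)
  bad <- setdiff(unique(conditions), ppi_conditions())
  if (length(bad)) stop("invalid condition label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (length(onsets) != length(conditions)) {
    stop("onsets and conditions differ in length", call. = FALSE)
  }
  o <- order(onsets)
  if (is.unsorted(onsets)) {
    warning("event onsets were not ascending; sorted", call. = FALSE)
  }
  if (anyDuplicated(onsets)) stop("duplicate event onsets", call. = FALSE)
  ev <- data.frame(onset = as.integer(onsets[o]), condition = conditions[o],
                   block = rep_len(as.integer(block), length(onsets))[o],
                   stringsAsFactors = FALSE)
  class(ev) <- c("ppi_events", "data.frame")
  ev
}

#' Condition labels of the paradigm
#'
#' Pulse-alone `P` and prepulse+pulse with 30/60/120 ms lead intervals.
#' @return character vector.
#' @export
ppi_conditions <- function() c("P", "P30", "P60", "P120")

#' Read a BIDS-style events table
#'
#' Tab-separated table with columns `onset` (seconds), `duration` (seconds,
#' ignored) and `trial_type`. Rows whose `trial_type` is not a known condition
#' label are excluded with a reported count; out-of-order rows are sorted with
#' a warning.
#'
#' @param path events.tsv path.
#' @param rate sampling rate used to convert second onsets to sample indices.
#' @return A [ppi_events()] table; the number of excluded rows is attached as
#'   attribute `n_excluded`.
#' @export
read_events <- function(path, rate) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "trial_type") %in% names(tab))) {
    stop("events table needs columns onset and trial_type", call. = FALSE)
  }
  if (nrow(tab) == 0) stop("events table is empty", call. = FALSE)
  keep <- tab$trial_type %in% ppi_conditions()
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " event(s) with unknown trial_type excluded: ",
            paste(unique(tab$trial_type[!keep]), collapse = ", "))
  }
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("no events with known trial_type", call. = FALSE)
  ev <- ppi_events(onsets = round(tab$onset * rate),
                   conditions = tab$trial_type,
                   block = if (is.null(tab$block)) NA_integer_ else tab$block)
  attr(ev, "n_excluded") <- n_excluded
  ev
}

#' @rdname read_events
#' @param events a `ppi_events` table.
#' @param duration stimulus duration written to the `duration` column (s).
#' @export
write_events <- function(events, path, rate, duration = 0.04) {
  tab <- data.frame(onset = events$onset / rate,
                    duration = duration,
                    trial_type = events$condition,
                    block = events$block)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flags (not drops) events whose epoch window would leave recording bounds.
events_in_bounds <- function(events, n_samples, rate, window_ms) {
  off <- window_offsets(window_ms, rate)
  ok <- events$onset + off$start >= 0 &
    events$onset + off$start + off$n <= n_samples
  ok
}
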