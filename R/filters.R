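#' Butterworth filter specification
#'
#' @param kind one of `highpass`, `lowpass`, `bandpass`, `bandstop`.
#' @param cutoffs_hz one cutoff (high/lowpass) or an ascending pair.
#' @param order design order of a single pass; zero-phase application squares
#'   the magnitude response, so the effective roll-off is that of twice the
#'   design order.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "bandpass", "bandstop"),
                        cutoffs_hz, order = 4L) {
  kind <- match.arg(kind)
  n_cut <- if (kind %in% c("bandpass", "bandstop")) 2L else 1L
  if (length(cutoffs_hz) != n_cut) {
    stop(kind, " needs ", n_cut, " cutoff(s)", call. = FALSE)
  }
  if (any(cutoffs_hz <= 0)) stop("cutoffs must be positive", call. = FALSE)
  if (n_cut == 2L && cutoffs_hz[1] >= cutoffs_hz[2]) {
    stop("cutoff pair must ascend", call. = FALSE)
  }
  if (order < 1) stop("order must be a positive integer", call. = FALSE)
  structure(list(kind = kind, cutoffs_hz = as.numeric(cutoffs_hz),
                 order = as.integer(order)), class = "filter_spec")
}

butter_for <- function(spec, rate) {
  nyq <- rate / 2
  if (any(spec$cutoffs_hz >= nyq)) {
    stop("cutoff ", max(spec$cutoffs_hz), " Hz is at or above the Nyquist rate ",
         nyq, " Hz", call. = FALSE)
  }
  type <- switch(spec$kind, highpass = "high", lowpass = "low",
                 bandpass = "pass", bandstop = "stop")
  signal::butter(spec$order, spec$cutoffs_hz / nyq, type = type)
}

# Steady-state initial filter conditions for a unit-step input (direct-form II
# transposed), so each pass starts settled at the padded signal's first value.
butter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nz <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, nz + 1L - length(b)))
  a <- c(a, rep(0, nz + 1L - length(a)))
  comp <- rbind(-a[-1], cbind(diag(1, nz - 1L), 0))   # companion matrix of a
  solve(diag(nz) - t(comp), b[-1] - a[-1] * b[1])
}

# Reflect padding long enough to settle the filter's transient: three times the
# nominal impulse length rate/f_lo of the slowest pole, capped so very low
# cutoffs on short signals stay usable.
pad_length <- function(spec, rate, n) {
  nominal <- ceiling(3 * rate / min(spec$cutoffs_hz))
  max(3L * (2L * spec$order + 1L), min(as.integer(nominal), n - 1L))
}

#' Zero-phase Butterworth filtering
#'
#' Applies the filter forward and backward (with odd-reflection padding at both
#' ends), so the output has no phase distortion and the magnitude response is
#' the squared Butterworth magnitude of the design order.
#'
#' @param x numeric vector, or channels x samples matrix filtered row-wise.
#' @param spec a [filter_spec()].
#' @param rate sampling rate in Hz.
#' @return Filtered series, same shape as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 60 * (0:2047) / 512)
#' y <- zero_phase_filter(x, filter_spec("bandstop", c(58, 62)), 512)
#' max(abs(y[500:1500]))  # 60 Hz almost fully removed
zero_phase_filter <- function(x, spec, rate) {
  bt <- butter_for(spec, rate)
  if (is.matrix(x)) {
    n <- ncol(x)
    pad <- check_pad(spec, rate, n)
    out <- filtfilt_cascade_rows(list(bt$b), list(bt$a),
                                 list(butter_zi(bt$b, bt$a)), x, pad)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  filtfilt_padded(bt, x, spec, rate)
}

check_pad <- function(spec, rate, n) {
  pad <- pad_length(spec, rate, n)
  if (n <= pad %/% 3 + 1L || n < 3L * (2L * spec$order + 1L)) {
    stop("signal too short for zero-phase filtering; need more than ",
         3L * (2L * spec$order + 1L), " samples", call. = FALSE)
  }
  pad
}

filtfilt_padded <- function(bt, x, spec, rate) {
  pad <- check_pad(spec, rate, length(x))
  filtfilt_cascade(list(bt$b), list(bt$a), list(butter_zi(bt$b, bt$a)), x, pad)
}

#' Mains-notch cascade
#'
#' Cascaded zero-phase Butterworth band-stops at the mains base frequency and
#' every integer harmonic below Nyquist (at 512 Hz with 60 Hz mains: 60, 120,
#' 180 and 240 Hz), each `halfwidth_hz` wide on both sides.
#'
#' @inheritParams zero_phase_filter
#' @param base_hz mains base frequency (60 by default).
#' @param halfwidth_hz half-width of each stop band (default 2 Hz).
#' @param order band-stop design order per harmonic.
#' @return Filtered series, same shape as `x`.
#' @export
notch_mains <- function(x, rate, base_hz = 60, halfwidth_hz = 2, order = 4L) {
  nyq <- rate / 2
  if (base_hz >= nyq) stop("mains base frequency at or above Nyquist", call. = FALSE)
  harmonics <- seq(base_hz, nyq - 1e-9, by = base_hz)
  harmonics <- harmonics[harmonics + halfwidth_hz < nyq]
  specs <- lapply(harmonics, function(h) {
    filter_spec("bandstop", c(h - halfwidth_hz, h + halfwidth_hz), order)
  })
  bts <- lapply(specs, butter_for, rate = rate)
  bs <- lapply(bts, `[[`, "b")
  as_ <- lapply(bts, `[[`, "a")
  zis <- mapply(butter_zi, bs, as_, SIMPLIFY = FALSE)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  pad <- max(vapply(specs, pad_length, 0L, rate = rate, n = n))
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) {
      x[i, ] <- filtfilt_cascade(bs, as_, zis, x[i, ], pad)
    }
    x
  } else {
    filtfilt_cascade(bs, as_, zis, x, pad)
  }
}
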