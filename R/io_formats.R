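#' Read a multichannel recording
#'
#' Reads a BrainVision triplet (`.vhdr`/`.vmrk`/`.eeg`; binary multiplexed,
#' IEEE float32 or int16) or an EDF file into a [ppi_recording()]. Channel
#' roles come from an explicit role map, never from name heuristics; the
#' default map covers the package's standard montage (see
#' [default_channels()]).
#'
#' @param path path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"` or `"edf"`.
#' @param roles named character vector mapping channel name to role (`scalp`,
#'   `emg`, `eog`, `reference`). `NULL` uses the default montage map; channels
#'   not covered by the map raise an error.
#' @param adc_resolution uV per digital unit recorded by the amplifier.
#' @return A `ppi_recording`; channel order preserved from the file.
#' @export
read_recording <- function(path, format = c("brainvision", "edf"),
                           roles = NULL, adc_resolution = 0.0488) {
  format <- match.arg(format)
  raw <- switch(format,
                brainvision = read_brainvision_data(path),
                edf = read_edf_data(path))
  if (is.null(roles)) {
    def <- default_channels()
    roles <- stats::setNames(def$role, def$name)
  }
  missing_role <- setdiff(raw$names, names(roles))
  if (length(missing_role)) {
    stop("no role mapping for channel(s): ",
         paste(missing_role, collapse = ", "),
         "; supply a `roles` map", call. = FALSE)
  }
  def <- default_channels()
  pos <- stats::setNames(def$position_label, def$name)
  channels <- data.frame(
    name = raw$names,
    role = unname(roles[raw$names]),
    position_label = ifelse(raw$names %in% names(pos), pos[raw$names], ""),
    stringsAsFactors = FALSE
  )
  ppi_recording(raw$data, raw$rate, channels, adc_resolution)
}

known_uv_units <- function() c("µV", "uV", "μV", "")

parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][key] <- val
    }
  }
  out
}

read_brainvision_data <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path,
                                    call. = FALSE)
  hdr <- parse_ini(readLines(vhdr_path, encoding = "UTF-8", warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (is.null(ci) || is.null(bi)) stop("not a BrainVision header: ", vhdr_path,
                                       call. = FALSE)
  if (!identical(ci[["DataFormat"]], "BINARY")) {
    stop("only BINARY BrainVision data supported", call. = FALSE)
  }
  if (!identical(ci[["DataOrientation"]], "MULTIPLEXED")) {
    stop("only MULTIPLEXED BrainVision data supported", call. = FALSE)
  }
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  eeg_path <- file.path(dirname(vhdr_path), ci[["DataFile"]])
  if (!file.exists(eeg_path)) {
    stop("BrainVision data file missing: ", eeg_path, call. = FALSE)
  }
  chn <- hdr[["Channel Infos"]]
  fields <- lapply(chn[paste0("Ch", seq_len(n_ch))], function(v) {
    strsplit(v, ",", fixed = TRUE)[[1]]
  })
  names_ <- vapply(fields, function(f) gsub("\\\\1", ",", f[1]), "")
  res <- vapply(fields, function(f) {
    if (length(f) >= 3 && nzchar(f[3])) as.numeric(f[3]) else 1
  }, 0)
  unit <- vapply(fields, function(f) if (length(f) >= 4) trimws(f[4]) else "", "")
  bad_unit <- setdiff(unique(unit), known_uv_units())
  if (length(bad_unit)) {
    stop("unknown channel unit(s): ", paste(bad_unit, collapse = ", "),
         "; only microvolt data supported", call. = FALSE)
  }
  fmt <- bi[["BinaryFormat"]]
  sz <- file.info(eeg_path)$size
  if (identical(fmt, "IEEE_FLOAT_32")) {
    n <- as.integer(sz / 4)
    v <- readBin(eeg_path, "numeric", n = n, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    n <- as.integer(sz / 2)
    v <- readBin(eeg_path, "integer", n = n, size = 2, signed = TRUE,
                 endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(v) %/% n_ch
  data <- matrix(v[seq_len(n_ch * n_samp)], nrow = n_ch)  # multiplexed
  data <- data * res                                      # digital -> uV
  list(data = data, rate = rate, names = names_)
}

#' Read stimulus markers from a BrainVision marker file
#'
#' Extracts `Stimulus` markers whose description is a known condition label;
#' others are excluded with a reported count.
#'
#' @param vhdr_path path to the `.vhdr` (the `.vmrk` is resolved through it).
#' @return A [ppi_events()] table with attribute `n_excluded`.
#' @export
read_brainvision_markers <- function(vhdr_path) {
  hdr <- parse_ini(readLines(vhdr_path, encoding = "UTF-8", warn = FALSE))
  mf <- hdr[["Common Infos"]][["MarkerFile"]]
  if (is.null(mf)) stop("header declares no MarkerFile", call. = FALSE)
  vmrk_path <- file.path(dirname(vhdr_path), mf)
  if (!file.exists(vmrk_path)) stop("marker file missing: ", vmrk_path,
                                    call. = FALSE)
  mk <- parse_ini(readLines(vmrk_path, encoding = "UTF-8", warn = FALSE))
  mk <- mk[["Marker Infos"]]
  fields <- lapply(unname(mk), function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  stim <- Filter(function(f) identical(f[1], "Stimulus"), fields)
  desc <- vapply(stim, `[`, "", 2)
  pos <- vapply(stim, function(f) as.integer(f[3]), 0L)
  keep <- desc %in% ppi_conditions()
  if (any(!keep)) {
    message(sum(!keep), " marker(s) with unknown description excluded")
  }
  if (!any(keep)) stop("no stimulus markers with known condition labels",
                       call. = FALSE)
  ev <- ppi_events(pos[keep] - 1L, desc[keep])   # positions are 1-based
  attr(ev, "n_excluded") <- sum(!keep)
  ev
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `.vhdr`, `.vmrk` and `.eeg` (binary multiplexed). `"float32"` stores
#' uV values directly; `"int16"` quantizes by the recording's
#' `adc_resolution`.
#'
#' @param rec a [ppi_recording()].
#' @param vhdr_path output `.vhdr` path; companion files take the same stem.
#' @param events optional [ppi_events()] written as stimulus markers.
#' @param binary_format `"float32"` or `"int16"`.
#' @return Invisibly, `vhdr_path`.
#' @export
write_brainvision <- function(rec, vhdr_path, events = NULL,
                              binary_format = c("float32", "int16")) {
  binary_format <- match.arg(binary_format)
  stem <- sub("\\.vhdr$", "", basename(vhdr_path))
  dirn <- dirname(vhdr_path)
  eeg_name <- paste0(stem, ".eeg")
  vmrk_name <- paste0(stem, ".vmrk")
  n_ch <- nrow(rec$data)
  fmt <- if (binary_format == "float32") "IEEE_FLOAT_32" else "INT_16"
  res <- if (binary_format == "float32") 1 else rec$adc_resolution
  ch_lines <- vapply(seq_len(n_ch), function(i) {
    sprintf("Ch%d=%s,,%.6g,µV", i,
            gsub(",", "\\\\1", rec$channels$name[i]), res)
  }, "")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", eeg_name),
    paste0("MarkerFile=", vmrk_name),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$rate),
    "[Binary Infos]",
    paste0("BinaryFormat=", fmt),
    "[Channel Infos]",
    ch_lines
  )
  writeLines(hdr, vhdr_path, useBytes = TRUE)
  mk_lines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", eeg_name),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (!is.null(events)) {
    mk_lines <- c(mk_lines, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                                    seq_len(nrow(events)) + 1L,
                                    events$condition, events$onset + 1L))
  }
  writeLines(mk_lines, file.path(dirn, vmrk_name), useBytes = TRUE)
  con <- file(file.path(dirn, eeg_name), "wb")
  on.exit(close(con))
  if (binary_format == "float32") {
    writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(pmin(round(rec$data / res), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(vhdr_path)
}

pad8 <- function(x) formatC(as.character(x), width = 8, flag = "-")
padn <- function(x, w) formatC(as.character(x), width = w, flag = "-")

#' Write a recording as an EDF file
#'
#' Classic EDF, 16-bit, one-second data records, physical unit uV with a
#' per-channel physical range fitted to the data. Trailing samples that do not
#' fill a whole record are dropped with a warning.
#'
#' @param rec a [ppi_recording()].
#' @param path output `.edf` path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  spr <- as.integer(round(rec$rate))       # samples per 1 s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec * spr < ncol(rec$data)) {
    warning("dropping ", ncol(rec$data) - n_rec * spr,
            " trailing sample(s) not filling a whole EDF record", call. = FALSE)
  }
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  fmt_phys <- function(x) {
    s <- formatC(x, format = "g", digits = 7, width = 8, flag = "-")
    substr(s, 1, 8)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad8("0"))
  wr(padn("ppigate synthetic subject", 80))
  wr(padn("ppigate recording", 80))
  wr("01.01.26"); wr("00.00.00")
  wr(pad8(256 * (n_ch + 1)))
  wr(padn("", 44))
  wr(pad8(n_rec))
  wr(pad8("1"))
  wr(padn(n_ch, 4))
  for (f in list(function(i) padn(rec$channels$name[i], 16),
                 function(i) padn("", 80),
                 function(i) pad8("uV"),
                 function(i) fmt_phys(pmin_[i]),
                 function(i) fmt_phys(pmax_[i]),
                 function(i) pad8(-32768),
                 function(i) pad8(32767),
                 function(i) padn("", 80),
                 function(i) pad8(spr),
                 function(i) padn("", 32))) {
    for (i in seq_len(n_ch)) wr(f(i))
  }
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * spr + seq_len(spr)
    for (i in seq_len(n_ch)) {
      dig <- round((rec$data[i, idx] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                     65535 - 32768)
      writeBin(as.integer(pmax(pmin(dig, 32767), -32768)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf_data <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                               # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  per_ch <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- per_ch(16)
  per_ch(80)
  units <- per_ch(8)
  bad_unit <- setdiff(unique(units), known_uv_units())
  if (length(bad_unit)) {
    stop("unknown EDF physical dimension(s): ",
         paste(bad_unit, collapse = ", "), call. = FALSE)
  }
  pmin_ <- as.numeric(per_ch(8))
  pmax_ <- as.numeric(per_ch(8))
  dmin_ <- as.numeric(per_ch(8))
  dmax_ <- as.numeric(per_ch(8))
  per_ch(80)
  spr <- as.integer(per_ch(8))
  per_ch(32)
  if (length(unique(spr)) != 1) {
    stop("EDF with per-channel sampling rates not supported", call. = FALSE)
  }
  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      data[i, (r - 1) * spr[1] + seq_len(spr[1])] <-
        (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
    }
  }
  list(data = data, rate = spr[1] / dur, names = labels)
}
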