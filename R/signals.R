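#' Construct a multichannel signal recording
#'
#' Container for time-aligned EEG/EMG traces sharing one sampling rate.
#' Canonical channel names are `EEG_frontal`, `EEG_occipital`, `EMG`, but any
#' names are accepted; analysis functions select channels by name.
#'
#' @param channels Named list of numeric vectors, all the same length.
#' @param sampling_rate Sampling rate in Hz (default 256.9, typical of
#'   tethered rodent EEG acquisition systems).
#' @param start_clock_s Clock time of the first sample, seconds of day.
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(channels, sampling_rate = 256.9,
                             start_clock_s = 0) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), sampling_rate > 0)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all channels must have the same length; got ",
         paste(lens, collapse = ", "))
  }
  structure(
    list(channels = channels, sampling_rate = sampling_rate,
         start_clock_s = start_clock_s),
    class = "signal_recording"
  )
}

#' @export
print.signal_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<signal_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), n, x$sampling_rate, n / x$sampling_rate))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

rec_n_samples <- function(rec) length(rec$channels[[1]])
rec_duration_s <- function(rec) rec_n_samples(rec) / rec$sampling_rate

#' Read signals from an EDF file
#'
#' Minimal reader for the European Data Format (EDF, 16-bit) sufficient for
#' the recordings this package writes and for plain continuous EDF exports:
#' all channels must share one sampling rate. Channel names can be remapped
#' to the canonical `EEG_frontal` / `EEG_occipital` / `EMG` names through an
#' alias table (a named character vector or a YAML file of
#' `canonical: stored-label` pairs).
#'
#' @param path EDF file path.
#' @param aliases Optional alias table: `c(EMG = "EMG ch1", ...)`, or a path
#'   to a YAML file with the same structure.
#' @param require_emg If `TRUE` (default), fail unless some channel is named
#'   `EMG` after aliasing.
#' @return A [signal_recording()] (physical units, as calibrated in the file).
#' @seealso [write_edf()]
#' @export
read_edf <- function(path, aliases = NULL, require_emg = TRUE) {
  hdr <- read_edf_header(path)
  if (length(unique(hdr$samples_per_record)) != 1) {
    stop("channels disagree on samples per record (mixed sampling rates): ",
         path)
  }
  spr <- hdr$samples_per_record[1]
  ns <- hdr$n_signals
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$header_bytes)
  dig <- readBin(con, "integer", n = hdr$n_records * ns * spr, size = 2,
                 signed = TRUE, endian = "little")
  dig <- array(dig, dim = c(spr, ns, hdr$n_records))
  gain <- (hdr$phys_max - hdr$phys_min) / (hdr$dig_max - hdr$dig_min)
  channels <- lapply(seq_len(ns), function(i) {
    as.numeric(dig[, i, ]) * gain[i] + hdr$phys_min[i] - hdr$dig_min[i] * gain[i]
  })
  names(channels) <- hdr$labels
  if (!is.null(aliases)) {
    if (is.character(aliases) && length(aliases) == 1 && file.exists(aliases)) {
      aliases <- unlist(yaml::read_yaml(aliases))
    }
    for (canon in names(aliases)) {
      j <- match(aliases[[canon]], names(channels))
      if (!is.na(j)) names(channels)[j] <- canon
    }
  }
  if (require_emg && !("EMG" %in% names(channels))) {
    stop("no EMG channel found in ", path,
         " (channels: ", paste(names(channels), collapse = ", "),
         "); provide an alias table mapping EMG to a stored label")
  }
  fs <- spr / hdr$record_duration_s
  signal_recording(channels, sampling_rate = fs,
                   start_clock_s = hdr$start_clock_s)
}

#' Write signals to an EDF file
#'
#' 16-bit EDF writer. The record duration is chosen as the smallest value in
#' `1:30` seconds for which `sampling_rate * duration` is an integer (10 s for
#' the 256.9 Hz default); the recording is zero-padded to a whole number of
#' records.
#'
#' @param rec A [signal_recording()].
#' @param path Output path.
#' @param physical_range Symmetric physical range per channel in signal units
#'   (default 1000, i.e. +/-1 mV for microvolt signals). Samples outside the
#'   range are clipped. Quantisation step is `2 * physical_range / 65534`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = 1000) {
  stopifnot(inherits(rec, "signal_recording"))
  fs <- rec$sampling_rate
  rd <- NA
  for (d in 1:30) {
    if (abs(fs * d - round(fs * d)) < 1e-6) { rd <- d; break }
  }
  if (is.na(rd)) stop("sampling rate ", fs, " has no integer samples-per-record <= 30 s")
  spr <- as.integer(round(fs * rd))
  ns <- length(rec$channels)
  n <- rec_n_samples(rec)
  n_rec <- ceiling(n / spr)
  pad <- n_rec * spr - n

  pmin_ <- -physical_range; pmax_ <- physical_range
  dmin <- -32767L; dmax <- 32767L
  gain <- (pmax_ - pmin_) / (dmax - dmin)

  fmt <- function(x, w) {
    s <- substr(format(x, width = w, justify = "left"), 1, w)
    formatC(s, width = w, flag = "-")
  }
  start_s <- round(rec$start_clock_s %% 86400)
  hh <- start_s %/% 3600; mm <- (start_s %% 3600) %/% 60; ss <- start_s %% 60
  header <- paste0(
    fmt("0", 8), fmt("vigilarch synthetic", 80), fmt("vigilarch", 80),
    fmt("01.01.26", 8),
    fmt(sprintf("%02d.%02d.%02d", hh, mm, ss), 8),
    fmt(as.character(256 * (ns + 1)), 8), fmt("", 44),
    fmt(as.character(n_rec), 8), fmt(as.character(rd), 8),
    fmt(as.character(ns), 4)
  )
  field <- function(vals, w) paste0(vapply(vals, fmt, "", w = w), collapse = "")
  header <- paste0(
    header,
    field(names(rec$channels), 16),
    field(rep("", ns), 80),                      # transducer
    field(rep("uV", ns), 8),                     # physical dimension
    field(rep(format(pmin_), ns), 8),
    field(rep(format(pmax_), ns), 8),
    field(rep(format(dmin), ns), 8),
    field(rep(format(dmax), ns), 8),
    field(rep("", ns), 80),                      # prefiltering
    field(rep(as.character(spr), ns), 8),
    field(rep("", ns), 32)                       # reserved
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  digitize <- function(x) {
    x <- c(x, numeric(pad))
    x <- pmin(pmax(x, pmin_), pmax_)
    as.integer(round((x - pmin_) / gain) + dmin)
  }
  dig <- vapply(rec$channels, digitize, integer(n_rec * spr))
  # interleave: per record, all samples of ch1, then ch2, ...
  dim(dig) <- c(spr, n_rec, ns)
  out <- aperm(dig, c(1, 3, 2))
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw256 <- readBin(con, "raw", 256)
  txt <- rawToChar(raw256)
  gfx <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  start_time <- gfx(txt, 177, 8)
  tparts <- as.numeric(strsplit(start_time, "\\.")[[1]])
  start_clock_s <- if (length(tparts) == 3 && !anyNA(tparts)) {
    tparts[1] * 3600 + tparts[2] * 60 + tparts[3]
  } else 0
  header_bytes <- as.integer(gfx(txt, 185, 8))
  n_records <- as.integer(gfx(txt, 237, 8))
  record_duration_s <- as.numeric(gfx(txt, 245, 8))
  ns <- as.integer(gfx(txt, 253, 4))
  sig <- rawToChar(readBin(con, "raw", header_bytes - 256))
  take <- function(offset, w) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig, offset + (i - 1) * w + 1, offset + i * w))
    }, "")
  }
  o <- 0
  labels <- take(o, 16); o <- o + ns * 16
  o <- o + ns * 80 + ns * 8                      # transducer, dimension
  phys_min <- as.numeric(take(o, 8)); o <- o + ns * 8
  phys_max <- as.numeric(take(o, 8)); o <- o + ns * 8
  dig_min <- as.numeric(take(o, 8)); o <- o + ns * 8
  dig_max <- as.numeric(take(o, 8)); o <- o + ns * 8
  o <- o + ns * 80                               # prefiltering
  spr <- as.integer(take(o, 8))
  list(
    labels = labels, n_signals = ns, n_records = n_records,
    record_duration_s = record_duration_s, samples_per_record = spr,
    phys_min = phys_min, phys_max = phys_max, dig_min = dig_min,
    dig_max = dig_max, header_bytes = header_bytes,
    start_clock_s = start_clock_s
  )
}
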