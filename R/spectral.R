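#' Frequency band definition
#'
#' @param name Band name (e.g. `"SWA"`, `"theta"`).
#' @param lo_hz,hi_hz Band edges in Hz, `0 <= lo < hi`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  stopifnot(lo_hz >= 0, hi_hz > lo_hz)
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
band_swa <- function() band_definition("SWA", 0.5, 4)

#' @rdname band_definition
#' @details The theta band default is 5-10 Hz; REM theta in mice peaks
#'   around 6-8 Hz.
#' @export
band_theta <- function() band_definition("theta", 5, 10)

#' Per-epoch EEG power spectra
#'
#' Computes one power spectrum per hypnogram epoch by FFT with a Hanning
#' window at (nominally) 0.25-Hz resolution. Because the sampling rate need
#' not make `epoch_s * fs` an integer, the window is sized as
#' `m = min(floor(epoch_s * fs), n_fft)` samples starting at
#' `floor((k-1) * epoch_s * fs)`, demeaned, Hanning-tapered and zero-padded
#' to `n_fft = round(fs / 0.25)` points; bin spacing is then `fs / n_fft`
#' (0.2499 Hz at 256.9 Hz), stored exactly in `freq_hz`. Power is scaled so
#' that the sum over one-sided bins equals the mean square of the windowed
#' epoch (a discrete Parseval identity).
#'
#' Epochs scored `ARTIFACT` get `NA` spectra.
#'
#' @param rec A [signal_recording()].
#' @param hyp A [hypnogram()] time-aligned with `rec` (same start; durations
#'   may differ by at most one epoch).
#' @param channel Channel name in `rec` (default `"EEG_frontal"`).
#' @param freq_resolution_hz Nominal resolution, default 0.25.
#' @return An object of class `epoch_spectra`: list with `power` (matrix
#'   epochs x bins), `freq_hz` (exact bin centres, 0..Nyquist),
#'   `freq_resolution_hz` (exact spacing), `window = "hanning"`, `epoch_s`,
#'   `channel`.
#' @export
epoch_spectra <- function(rec, hyp, channel = "EEG_frontal",
                          freq_resolution_hz = 0.25) {
  stopifnot(inherits(rec, "signal_recording"), inherits(hyp, "hypnogram"))
  if (!channel %in% names(rec$channels)) {
    stop("channel not found: ", channel)
  }
  if (abs(rec_duration_s(rec) - duration_s(hyp)) > hyp$epoch_s) {
    stop(sprintf(
      "recording (%.1f s) and hypnogram (%.1f s) misaligned by more than one epoch",
      rec_duration_s(rec), duration_s(hyp)
    ))
  }
  fs <- rec$sampling_rate
  x <- rec$channels[[channel]]
  n_fft <- round(fs / freq_resolution_hz)
  m <- min(floor(hyp$epoch_s * fs), n_fft)
  w <- hanning_window(m)
  nb <- n_fft %/% 2 + 1
  scale <- c(1, rep(2, nb - 2), if (n_fft %% 2 == 0) 1 else 2)

  ne <- n_epochs(hyp)
  power <- matrix(NA_real_, nrow = ne, ncol = nb)
  art <- as.character(hyp$labels) == "ARTIFACT"
  for (k in seq_len(ne)) {
    if (art[k]) next
    s0 <- floor((k - 1) * hyp$epoch_s * fs)
    if (s0 + m > length(x)) break
    seg <- x[(s0 + 1):(s0 + m)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(n_fft - m)))
    power[k, ] <- scale * Mod(X[seq_len(nb)])^2 / (n_fft * m)
  }
  structure(
    list(
      power = power,
      freq_hz = (seq_len(nb) - 1) * fs / n_fft,
      freq_resolution_hz = fs / n_fft,
      window = "hanning", epoch_s = hyp$epoch_s, channel = channel
    ),
    class = "epoch_spectra"
  )
}

hanning_window <- function(m) {
  if (m == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
}

#' Band power per epoch
#'
#' Sums spectral bins whose centre frequency lies in `[lo_hz, hi_hz]` (both
#' edges inclusive).
#'
#' @param spec An [epoch_spectra()].
#' @param band A [band_definition()].
#' @return Numeric vector, one value per epoch (`NA` for artifact epochs).
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "epoch_spectra"), inherits(band, "band_definition"))
  sel <- spec$freq_hz >= band$lo_hz & spec$freq_hz <= band$hi_hz
  if (!any(sel)) stop("band [", band$lo_hz, ", ", band$hi_hz,
                      "] Hz contains no spectral bins")
  rowSums(spec$power[, sel, drop = FALSE])
}

#' Slow-wave-activity time course normalised to the baseline mean
#'
#' SWA (0.5-4 Hz power) per epoch expressed as a percentage of the mean over
#' all artifact-free epochs of the baseline day (the first 24 h, or the whole
#' record when shorter). All states enter the normalisation denominator, so
#' the mean of the output over baseline epochs is exactly 100.
#'
#' @param spec An [epoch_spectra()].
#' @param hyp The aligned [hypnogram()].
#' @param band Band, default [band_swa()].
#' @return A data frame of class `swa_course`: `epoch`, `time_s`, `state`,
#'   `phase`, `swa_pct`.
#' @export
swa_timecourse <- function(spec, hyp, band = band_swa()) {
  swa <- band_power(spec, band)
  baseline <- seq_len(min(n_epochs(hyp), floor(86400 / hyp$epoch_s)))
  denom <- mean(swa[baseline], na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) {
    stop("cannot normalise: no artifact-free baseline epochs with power")
  }
  out <- data.frame(
    epoch = seq_len(n_epochs(hyp)),
    time_s = (seq_len(n_epochs(hyp)) - 1) * hyp$epoch_s,
    state = as.character(hyp$labels),
    phase = phase_of_epoch(hyp),
    swa_pct = 100 * swa / denom
  )
  class(out) <- c("swa_course", "data.frame")
  out
}

#' Mean spectrum over epochs of one state
#'
#' @param spec An [epoch_spectra()].
#' @param hyp The aligned [hypnogram()].
#' @param state Vigilance label.
#' @return Numeric vector (one value per frequency bin); all-`NA` with a
#'   warning when the state has no artifact-free epochs.
#' @export
state_mean_spectrum <- function(spec, hyp, state) {
  state <- as.character(as_vigilance(state))
  rows <- which(as.character(hyp$labels) == state &
                  !is.na(spec$power[, 1]))
  if (!length(rows)) {
    warning("no artifact-free epochs of state ", state)
    return(rep(NA_real_, ncol(spec$power)))
  }
  colMeans(spec$power[rows, , drop = FALSE])
}

#' Peak frequency within a band
#'
#' Frequency of the maximal bin inside the band; ties broken toward the
#' lowest frequency. A flat spectrum is reported with attribute
#' `tie = TRUE`.
#'
#' @param spectrum Numeric vector of per-bin power.
#' @param freq_hz Bin centre frequencies matching `spectrum`.
#' @param band A [band_definition()], default [band_theta()].
#' @return Peak frequency in Hz (attribute `tie` flags a tie/flat band).
#' @export
theta_peak <- function(spectrum, freq_hz, band = band_theta()) {
  sel <- which(freq_hz >= band$lo_hz & freq_hz <= band$hi_hz)
  if (!length(sel)) stop("band contains no bins")
  p <- spectrum[sel]
  i <- which.max(p)  # first maximum = lowest frequency on ties
  out <- freq_hz[sel[i]]
  attr(out, "tie") <- sum(p == p[i]) > 1
  out
}
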