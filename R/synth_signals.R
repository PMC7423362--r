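#' Signal-synthesis configuration
#'
#' Parameters for state-conditional EEG/EMG synthesis. EEG is 1/f^alpha
#' background noise per state plus a state signature: a band-limited 0.5-4 Hz
#' (delta) component in NREM and a theta sinusoid with small frequency jitter
#' in REM. EMG is white noise whose standard deviation drops from wake
#' through NREM to REM (muscle atonia). The whole EEG trace is band-passed
#' 0.1-100 Hz in the frequency domain, emulating the acquisition hardware
#' filter. Amplitudes are in arbitrary microvolt-scaled units; all analyses
#' downstream are ratio- or normalisation-based.
#'
#' @param sampling_rate Hz, default 256.9.
#' @param alpha Named spectral exponents per state (background 1/f^alpha).
#' @param base_amp_uV Named background amplitudes (SD) per state.
#' @param delta_mult NREM delta component amplitude as a multiple of the
#'   NREM background amplitude, default 1.5.
#' @param theta_hz REM theta frequency, default 7 (must lie in the theta
#'   band).
#' @param theta_amp_uV REM theta sinusoid amplitude, default 30.
#' @param theta_jitter_hz SD of per-run theta frequency jitter, default 0.05.
#' @param emg_sd_uV Named EMG noise SD per state (wake >> NREM > REM).
#' @param bandpass_hz Length-2 passband, default `c(0.1, 100)`.
#' @param crossfade_s Linear crossfade at state changes, default 0.5.
#' @return An object of class `signal_synth_config`.
#' @export
signal_synth_config <- function(
    sampling_rate = 256.9,
    alpha = c(WAKE = 1, NREM = 1.5, REM = 1),
    base_amp_uV = c(WAKE = 20, NREM = 25, REM = 20),
    delta_mult = 1.5,
    theta_hz = 7, theta_amp_uV = 30, theta_jitter_hz = 0.05,
    emg_sd_uV = c(WAKE = 30, NREM = 8, REM = 3),
    bandpass_hz = c(0.1, 100), crossfade_s = 0.5) {
  stopifnot(sampling_rate > 0, theta_amp_uV >= 0, delta_mult >= 0,
            theta_hz >= band_theta()$lo_hz, theta_hz <= band_theta()$hi_hz,
            all(emg_sd_uV >= 0), all(base_amp_uV >= 0))
  structure(
    list(sampling_rate = sampling_rate, alpha = alpha,
         base_amp_uV = base_amp_uV, delta_mult = delta_mult,
         theta_hz = theta_hz, theta_amp_uV = theta_amp_uV,
         theta_jitter_hz = theta_jitter_hz, emg_sd_uV = emg_sd_uV,
         bandpass_hz = bandpass_hz, crossfade_s = crossfade_s),
    class = "signal_synth_config"
  )
}

# unit-variance 1/f^alpha noise of length n (FFT shaping of white noise)
onef_noise <- function(n, alpha, fs) {
  if (n < 4) return(rnorm(n))
  X <- fft(rnorm(n))
  k <- 0:(n - 1)
  fsym <- pmin(k, n - k) * fs / n
  fsym[1] <- fsym[2]                      # avoid the DC singularity
  X <- X / fsym^(alpha / 2)
  X[1] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

# unit-variance band-limited noise via FFT mask
band_noise <- function(n, lo, hi, fs) {
  if (n < 4) return(rnorm(n))
  X <- fft(rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < lo | f > hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

# zero-phase frequency-domain Butterworth-magnitude bandpass
fft_bandpass <- function(x, fs, lo, hi, order = 4) {
  n <- length(x)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  H <- 1 / sqrt(1 + (f / hi)^(2 * order))
  f0 <- pmax(f, 1e-12)
  H <- H / sqrt(1 + (lo / f0)^(2 * order))
  Re(fft(X * H, inverse = TRUE)) / n
}

#' Synthesise EEG/EMG signals from a hypnogram
#'
#' Generates the three-channel recording (`EEG_frontal`, `EEG_occipital`,
#' `EMG`) whose state-conditional spectral content matches what the analysis
#' functions assume (see [signal_synth_config()]). Signals are generated per
#' state run and joined with linear crossfades; EEG channels are independent
#' realisations with identical statistics.
#'
#' @param hyp A [hypnogram()].
#' @param cfg A [signal_synth_config()].
#' @param seed Optional integer seed.
#' @return A [signal_recording()].
#' @export
synthesize_signals <- function(hyp, cfg = signal_synth_config(), seed = NULL) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(cfg, "signal_synth_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sampling_rate
  eps <- hyp$epoch_s
  lab <- as.character(hyp$labels)
  n_samp <- round(duration_s(hyp) * fs)
  fade <- round(cfg$crossfade_s * fs)

  runs <- rle(lab)
  run_end_ep <- cumsum(runs$lengths)
  run_start_ep <- run_end_ep - runs$lengths + 1

  eeg_channel <- function() {
    sig <- numeric(n_samp)
    wsum <- numeric(n_samp)
    for (i in seq_along(runs$values)) {
      st <- runs$values[i]
      if (st == "ARTIFACT") st <- "WAKE"  # artifact epochs get wake-like noise
      a <- floor((run_start_ep[i] - 1) * eps * fs) + 1
      b <- min(floor(run_end_ep[i] * eps * fs), n_samp)
      lo <- max(1, a - fade); hi <- min(n_samp, b + fade)
      len <- hi - lo + 1
      seg <- onef_noise(len, cfg$alpha[[st]], fs) * cfg$base_amp_uV[[st]]
      if (st == "NREM" && cfg$delta_mult > 0) {
        seg <- seg + band_noise(len, 0.5, 4, fs) *
          cfg$base_amp_uV[[st]] * cfg$delta_mult
      } else if (st == "REM" && cfg$theta_amp_uV > 0) {
        fr <- cfg$theta_hz + rnorm(1, 0, cfg$theta_jitter_hz)
        ph <- runif(1, 0, 2 * pi)
        seg <- seg + cfg$theta_amp_uV *
          sin(2 * pi * fr * (0:(len - 1)) / fs + ph)
      }
      w <- rep(1, len)
      nl <- a - lo; nr <- hi - b
      if (nl > 0) w[seq_len(nl)] <- seq(0, 1, length.out = nl + 2)[2:(nl + 1)]
      if (nr > 0) w[(len - nr + 1):len] <- rev(seq(0, 1, length.out = nr + 2)[2:(nr + 1)])
      sig[lo:hi] <- sig[lo:hi] + seg * w
      wsum[lo:hi] <- wsum[lo:hi] + w
    }
    sig <- sig / pmax(wsum, 1e-9)
    fft_bandpass(sig, fs, cfg$bandpass_hz[1], cfg$bandpass_hz[2])
  }

  # EMG: white noise with a crossfaded state-dependent SD envelope
  sd_per_epoch <- cfg$emg_sd_uV[ifelse(lab == "ARTIFACT", "WAKE", lab)]
  samp_epoch <- pmin(floor((0:(n_samp - 1)) / (eps * fs)) + 1, length(lab))
  sd_env <- as.numeric(sd_per_epoch[samp_epoch])
  if (fade > 1) {
    kern <- rep(1 / fade, fade)
    sm <- stats::filter(sd_env, kern, sides = 2)
    sd_env <- ifelse(is.na(sm), sd_env, sm)   # keep raw SD at the edges
  }
  emg <- rnorm(n_samp) * as.numeric(sd_env)

  signal_recording(
    list(EEG_frontal = eeg_channel(), EEG_occipital = eeg_channel(),
         EMG = emg),
    sampling_rate = fs, start_clock_s = hyp$start_clock_s
  )
}
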