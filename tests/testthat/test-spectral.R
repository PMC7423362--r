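make_rec <- function(x, fs = 256.9) {
  signal_recording(list(EEG_frontal = x, EMG = numeric(length(x))),
                   sampling_rate = fs)
}

hyp_for <- function(x, fs = 256.9, state = "NREM", epoch_s = 4) {
  hypnogram(rep(state, floor(length(x) / (epoch_s * fs))), epoch_s = epoch_s)
}

test_that("bin spacing realises the 0.25-Hz convention at 256.9 Hz", {
  x <- rnorm(round(8 * 256.9))
  hyp <- hyp_for(x)
  sp <- epoch_spectra(make_rec(x), hyp)
  expect_equal(sp$freq_resolution_hz, 256.9 / 1028)
  expect_lt(abs(sp$freq_resolution_hz - 0.25), 0.001)
  # bin count = floor(Nyquist / resolution) + 1
  expect_equal(ncol(sp$power),
               floor((256.9 / 2) / sp$freq_resolution_hz) + 1)
  expect_equal(nrow(sp$power), n_epochs(hyp))
})

test_that("zero signal gives zero spectra; artifacts give NA rows", {
  x <- numeric(round(12 * 256.9))
  hyp <- hypnogram(c("N", "A", "N"), epoch_s = 4)
  sp <- epoch_spectra(make_rec(x), hyp)
  expect_equal(max(abs(sp$power[c(1, 3), ])), 0)
  expect_true(all(is.na(sp$power[2, ])))
  expect_true(all(is.na(band_power(sp, band_swa())[2])))
})

test_that("sinusoid power localises to its frequency and band", {
  fs <- 256.9
  t <- (0:(round(16 * fs) - 1)) / fs
  hyp <- hypnogram(rep("N", 4), epoch_s = 4)

  x2 <- sin(2 * pi * 2 * t)
  sp2 <- epoch_spectra(make_rec(x2), hyp)
  total <- rowSums(sp2$power)
  near <- rowSums(sp2$power[, abs(sp2$freq_hz - 2) <= 0.5, drop = FALSE])
  expect_true(all(near / total >= 0.95))
  expect_true(all(band_power(sp2, band_swa()) / total >= 0.95))

  x10 <- sin(2 * pi * 10 * t)
  sp10 <- epoch_spectra(make_rec(x10), hyp)
  expect_true(all(band_power(sp10, band_swa()) / rowSums(sp10$power) <= 0.05))
})

test_that("Parseval: spectra sum to the windowed time-domain variance", {
  set.seed(408)
  fs <- 256.9
  x <- rnorm(round(8 * fs))
  hyp <- hypnogram(rep("N", 2), epoch_s = 4)
  sp <- epoch_spectra(make_rec(x), hyp)
  m <- 1027
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  for (k in 1:2) {
    seg <- x[(floor((k - 1) * 4 * fs) + 1):(floor((k - 1) * 4 * fs) + m)]
    ref <- mean(((seg - mean(seg)) * w)^2)
    expect_lt(abs(sum(sp$power[k, ]) - ref) / ref, 0.01)
  }
})

test_that("band powers are additive and sum to total power", {
  set.seed(409)
  x <- rnorm(round(8 * 256.9))
  sp <- epoch_spectra(make_rec(x), hypnogram(rep("N", 2)))
  nyq <- max(sp$freq_hz)
  lowb <- band_definition("low", 0, 10)
  highb <- band_definition("high", 10 + sp$freq_resolution_hz / 2, nyq)
  expect_equal(band_power(sp, lowb) + band_power(sp, highb),
               band_power(sp, band_definition("all", 0, nyq)))
  expect_equal(band_power(sp, band_definition("all", 0, nyq)),
               rowSums(sp$power))
  expect_error(band_power(sp, band_definition("empty", 10.01, 10.02)),
               "no spectral bins")
})

test_that("SWA normalisation has mean 100 and closed-form contrasts", {
  # constructed spectra: SWA doubled in NREM at 25% NREM occupancy
  lab <- rep(c("N", "W", "W", "W"), 100)
  hyp <- hypnogram(lab)
  nb <- 20
  freq <- (0:(nb - 1)) * 0.25
  pw <- matrix(0, length(lab), nb)
  pw[, freq >= 0.5 & freq <= 4] <- 1
  pw[lab == "N", ] <- 2 * pw[lab == "N", ]
  sp <- structure(list(power = pw, freq_hz = freq, freq_resolution_hz = 0.25,
                       window = "hanning", epoch_s = 4, channel = "EEG"),
                  class = "epoch_spectra")
  course <- swa_timecourse(sp, hyp)
  expect_equal(unique(course$swa_pct[course$state == "NREM"]), 160)
  expect_equal(unique(course$swa_pct[course$state == "WAKE"]), 80)
  expect_equal(mean(course$swa_pct), 100)

  # constant SWA -> 100 everywhere, regardless of state mix
  pw2 <- matrix(1, length(lab), nb)
  sp2 <- structure(list(power = pw2, freq_hz = freq,
                        freq_resolution_hz = 0.25, window = "hanning",
                        epoch_s = 4, channel = "EEG"),
                   class = "epoch_spectra")
  expect_equal(unique(swa_timecourse(sp2, hyp)$swa_pct), 100)
})

test_that("state mean spectra are convex combinations of epoch spectra", {
  set.seed(410)
  fs <- 256.9
  x <- rnorm(round(16 * fs))
  hyp <- hypnogram(c("N", "N", "R", "W"))
  sp <- epoch_spectra(make_rec(x), hyp)
  sR <- state_mean_spectrum(sp, hyp, "REM")
  expect_equal(sR, sp$power[3, ])            # single-epoch state
  sN <- state_mean_spectrum(sp, hyp, "NREM")
  expect_true(all(sN <= pmax(sp$power[1, ], sp$power[2, ]) + 1e-12))
  expect_true(all(sN >= pmin(sp$power[1, ], sp$power[2, ]) - 1e-12))
  expect_warning(state_mean_spectrum(sp, hyp, "ARTIFACT"), "no artifact-free")
})

test_that("theta peak recovers synthetic REM theta within one bin", {
  for (f0 in c(7.0, 6.5)) {
    hyp <- hypnogram(rep("R", 15))  # 60 s of REM
    cfg <- signal_synth_config(theta_hz = f0, theta_jitter_hz = 0)
    rec <- synthesize_signals(hyp, cfg, seed = 42)
    sp <- epoch_spectra(rec, hyp)
    pk <- theta_peak(state_mean_spectrum(sp, hyp, "REM"), sp$freq_hz)
    expect_lt(abs(pk - f0), 0.25 + 1e-9)
  }
})

test_that("theta peak tie rule prefers the lowest frequency", {
  freq <- seq(0, 20, by = 0.25)
  flat <- rep(1, length(freq))
  pk <- theta_peak(flat, freq)
  expect_equal(as.numeric(pk), 5)            # lower edge of the theta band
  expect_true(attr(pk, "tie"))
})

test_that("misaligned recording and hypnogram are rejected", {
  x <- rnorm(round(20 * 256.9))
  hyp <- hypnogram(rep("N", 2))              # 8 s vs 20 s
  expect_error(epoch_spectra(make_rec(x), hyp), "misaligned")
})
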