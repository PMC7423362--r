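#' Synthesise a mobility trace coupled to a hypnogram
#'
#' Emits 1-s (by default) mobility samples conditioned on the concurrent
#' vigilance state. Immobility is generated as run-length-correlated noise:
#' within a state, the mobile/immobile indicator follows a two-state Markov
#' chain whose stationary immobility probability is
#' `p_immobile_given_sleep` (NREM/REM epochs) or `p_immobile_given_wake`
#' (wake/artifact), with mean persistence `persistence_s`; the long
#' immobile runs during sleep are what the >40-s scoring rule detects.
#' Probabilities of exactly 0 or 1 are emitted deterministically.
#'
#' @param hyp A [hypnogram()].
#' @param p_immobile_given_sleep,p_immobile_given_wake Stationary immobility
#'   probabilities; sleep must exceed wake.
#' @param persistence_s Mean run persistence in seconds, default 30.
#' @param sample_interval_s Sample spacing, default 1.
#' @param seed Optional integer seed.
#' @return A [mobility_trace()].
#' @export
synthesize_tracking <- function(hyp, p_immobile_given_sleep = 0.95,
                                p_immobile_given_wake = 0.2,
                                persistence_s = 30, sample_interval_s = 1,
                                seed = NULL) {
  stopifnot(inherits(hyp, "hypnogram"),
            p_immobile_given_sleep >= 0, p_immobile_given_sleep <= 1,
            p_immobile_given_wake >= 0, p_immobile_given_wake <= 1)
  if (p_immobile_given_sleep <= p_immobile_given_wake) {
    stop("p_immobile_given_sleep must exceed p_immobile_given_wake")
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- sample_interval_s
  n <- floor(duration_s(hyp) / dt)
  lab <- as.character(hyp$labels)
  state_at <- lab[pmin(floor((0:(n - 1)) * dt / hyp$epoch_s) + 1, length(lab))]
  p <- ifelse(state_at %in% SLEEP_STATES,
              p_immobile_given_sleep, p_immobile_given_wake)
  tau <- max(persistence_s / dt, 1)
  immobile <- logical(n)
  cur <- runif(1) < p[1]
  for (i in seq_len(n)) {
    pi_ <- p[i]
    if (pi_ <= 0) cur <- FALSE
    else if (pi_ >= 1) cur <- TRUE
    else {
      # stay/switch so that stationary P(immobile) = pi_ at persistence tau
      cur <- if (cur) runif(1) >= (1 - pi_) / tau else runif(1) < pi_ / tau
    }
    immobile[i] <- cur
  }
  mobility_trace(!immobile, sample_interval_s = dt,
                 start_clock_s = hyp$start_clock_s, schedule = hyp$schedule)
}

#' Synthesise a circadian activity-count series
#'
#' Square-wave rest/active rhythm with Poisson count noise, the canonical
#' input for periodogram validation: counts are high during the active half
#' of each cycle and low otherwise.
#'
#' @param days Record length in days.
#' @param period_h Rhythm period in hours (default 24).
#' @param bin_minutes Bin length, default 10.
#' @param active_mean,rest_mean Poisson means for the two halves.
#' @param seed Optional integer seed.
#' @return Numeric vector of counts, one per bin.
#' @export
synthesize_activity <- function(days, period_h = 24, bin_minutes = 10,
                                active_mean = 60, rest_mean = 5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(days * 24 * 60 / bin_minutes)
  t_h <- (0:(n - 1)) * bin_minutes / 60
  active <- (t_h %% period_h) < period_h / 2
  rpois(n, ifelse(active, active_mean, rest_mean))
}
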