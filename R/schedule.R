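#' Light-dark schedule
#'
#' Describes the lighting regime the animal was recorded under. The default is
#' the standard 12:12 light-dark design: lights on at clock time
#' `lights_on_s` for `light_s` seconds, then dark for `dark_s` seconds,
#' repeating every `light_s + dark_s` seconds.
#'
#' @param lights_on_s Clock time of lights-on, seconds of day (default 0).
#' @param light_s Light-phase duration, seconds (default 43200 = 12 h).
#' @param dark_s Dark-phase duration, seconds (default 43200 = 12 h).
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule(lights_on_s = 7 * 3600)
#' phase_of_time(sched, 7 * 3600)      # "LIGHT"
#' phase_of_time(sched, 19 * 3600)     # "DARK"
#' @export
light_schedule <- function(lights_on_s = 0, light_s = 43200, dark_s = 43200) {
  stopifnot(light_s > 0, dark_s > 0, lights_on_s >= 0)
  structure(
    list(lights_on_s = lights_on_s, light_s = light_s, dark_s = dark_s),
    class = "light_schedule"
  )
}

#' Phase (LIGHT/DARK) of a clock time
#'
#' @param schedule A [light_schedule()].
#' @param clock_s Clock time(s) in seconds (may exceed one day; wraps modulo
#'   the cycle length).
#' @return Character vector, `"LIGHT"` or `"DARK"`.
#' @export
phase_of_time <- function(schedule, clock_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  cycle <- schedule$light_s + schedule$dark_s
  rel <- (clock_s - schedule$lights_on_s) %% cycle
  ifelse(rel < schedule$light_s, "LIGHT", "DARK")
}

#' Phase of a hypnogram epoch
#'
#' Phase is decided by the epoch *midpoint* clock time, which makes boundary
#' epochs unambiguous: an epoch straddling lights-off belongs to the phase
#' containing more than half of it.
#'
#' @param hyp A [hypnogram()].
#' @param epoch_index 1-based epoch index (vectorised). If missing, all epochs.
#' @return Character vector of `"LIGHT"`/`"DARK"`, one per requested epoch.
#' @export
phase_of_epoch <- function(hyp, epoch_index = seq_len(n_epochs(hyp))) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- n_epochs(hyp)
  if (any(epoch_index < 1 | epoch_index > n)) {
    stop("epoch_index out of range 1..", n)
  }
  mid <- hyp$start_clock_s + (epoch_index - 0.5) * hyp$epoch_s
  phase_of_time(hyp$schedule, mid)
}
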