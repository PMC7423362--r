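#' Time-in-state accounting
#'
#' Totals per vigilance state from raw epoch labels (episode membership is
#' irrelevant here), split by light/dark phase, plus an hourly time course
#' aligned to lights-on and the standard derived ratios:
#' `rem_fraction_of_sleep = 100 * REM / (REM + NREM)` and
#' `nrem_per_wake = NREM / WAKE` (time ratios).
#'
#' @param hyp A [hypnogram()].
#' @return A list of class `state_time_summary`:
#'   `total_h` (named per-state hours, ARTIFACT its own category),
#'   `phase_h` (matrix states x LIGHT/DARK),
#'   `hourly_h` (matrix states x hour-since-lights-on, folded modulo 24 h),
#'   `rem_fraction_of_sleep`, `nrem_per_wake`, `duration_h`.
#' @examples
#' h <- hypnogram(rep(c("W", "N", "R"), c(10, 5, 5)))
#' time_in_state(h)$rem_fraction_of_sleep  # 50
#' @export
time_in_state <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  lab <- factor(as.character(hyp$labels), levels = VIGILANCE_LEVELS)
  h_per_epoch <- hyp$epoch_s / 3600
  total_h <- as.numeric(table(lab)) * h_per_epoch
  names(total_h) <- VIGILANCE_LEVELS

  phase <- factor(phase_of_epoch(hyp), levels = c("LIGHT", "DARK"))
  phase_h <- table(lab, phase) * h_per_epoch

  mid <- hyp$start_clock_s + (seq_len(n_epochs(hyp)) - 0.5) * hyp$epoch_s
  rel <- (mid - hyp$schedule$lights_on_s) %% 86400
  hour <- factor(floor(rel / 3600), levels = 0:23)
  hourly_h <- table(lab, hour) * h_per_epoch

  sleep <- total_h["NREM"] + total_h["REM"]
  structure(
    list(
      total_h = total_h,
      phase_h = unclass(phase_h),
      hourly_h = unclass(hourly_h),
      rem_fraction_of_sleep =
        if (sleep > 0) unname(100 * total_h["REM"] / sleep) else NA_real_,
      nrem_per_wake =
        if (total_h["WAKE"] > 0) unname(total_h["NREM"] / total_h["WAKE"])
        else NA_real_,
      duration_h = duration_s(hyp) / 3600
    ),
    class = "state_time_summary"
  )
}

#' @export
print.state_time_summary <- function(x, ...) {
  cat(sprintf("<state_time_summary> %.1f h record\n", x$duration_h))
  cat("  ", paste(sprintf("%s %.2f h", names(x$total_h), x$total_h),
                  collapse = " | "), "\n", sep = "")
  cat(sprintf("  REM fraction of sleep %.1f%% | NREM/wake ratio %.2f\n",
              x$rem_fraction_of_sleep, x$nrem_per_wake))
  invisible(x)
}

#' Wake-episode statistics per phase
#'
#' Wake episodes are segmented with the 1-min / 16-s rule, so brief
#' awakenings (wake runs of 16 s or less) are never wake episodes; they are
#' counted separately. Episodes truncated by the recording edge are excluded
#' from mean durations (but counted) by default. An episode's phase is the
#' phase of its first epoch.
#'
#' @param hyp A [hypnogram()].
#' @param exclude_truncated Drop edge-truncated episodes from means
#'   (default `TRUE`).
#' @param rule Segmentation rule, default [rule_wake_default()].
#' @return A list: `count`, `mean_duration_s` (named `LIGHT`/`DARK`, `NA`
#'   when a phase has no episodes), `overall_mean_s`, `n_brief_awakenings`,
#'   and the `episodes` table with a `phase` column.
#' @export
wake_episode_stats <- function(hyp, exclude_truncated = TRUE,
                               rule = rule_wake_default()) {
  eps <- segment_episodes(hyp, rule)
  eps$phase <- if (nrow(eps)) phase_of_epoch(hyp, eps$start_epoch)
               else character(0)
  use <- if (exclude_truncated) !(eps$truncated_start | eps$truncated_end)
         else rep(TRUE, nrow(eps))
  mean_by_phase <- vapply(c("LIGHT", "DARK"), function(p) {
    d <- eps$span_s[use & eps$phase == p]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  list(
    count = nrow(eps),
    mean_duration_s = mean_by_phase,
    overall_mean_s = if (any(use)) mean(eps$span_s[use]) else NA_real_,
    n_brief_awakenings = nrow(detect_brief_awakenings(hyp)),
    episodes = eps
  )
}
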