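#' Score immobility-defined sleep
#'
#' Behavioural sleep surrogate used in high-throughput screens: a sleep bout
#' is a maximal run of continuous immobility *strictly longer* than the
#' threshold (40 s by convention). Percentages are bout time over bin time.
#'
#' @param trace A [mobility_trace()].
#' @param threshold_s Immobility threshold in seconds (strict `>`), default 40.
#' @return A list of class `immobility_summary`: `bouts` (data frame
#'   `start_s`, `duration_s`), `pct_immobile_light`, `pct_immobile_dark`,
#'   `hourly_pct` (24 values, hours since lights-on), `total_sleep_s`.
#' @examples
#' tr <- mobility_trace(c(rep(1, 100), rep(0, 45), rep(1, 3455)))
#' score_immobility_sleep(tr)$hourly_pct[1]  # 1.25
#' @export
score_immobility_sleep <- function(trace, threshold_s = 40) {
  stopifnot(inherits(trace, "mobility_trace"), threshold_s > 0)
  dt <- trace$sample_interval_s
  r <- rle(!trace$mobile)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  keep <- r$values & (r$lengths * dt > threshold_s)
  bouts <- data.frame(
    start_s = (run_start[keep] - 1) * dt,
    duration_s = r$lengths[keep] * dt
  )
  # per-sample sleep indicator (samples inside qualifying bouts)
  asleep <- logical(length(trace$mobile))
  for (i in which(keep)) asleep[run_start[i]:run_end[i]] <- TRUE

  mid <- trace$start_clock_s + (seq_along(asleep) - 0.5) * dt
  phase <- phase_of_time(trace$schedule, mid)
  pct <- function(sel) if (any(sel)) 100 * sum(asleep[sel]) / sum(sel) else NA_real_
  rel <- (mid - trace$schedule$lights_on_s) %% 86400
  hour <- floor(rel / 3600)
  hourly <- vapply(0:23, function(h) pct(hour == h), numeric(1))
  structure(
    list(
      bouts = bouts,
      pct_immobile_light = pct(phase == "LIGHT"),
      pct_immobile_dark = pct(phase == "DARK"),
      hourly_pct = hourly,
      total_sleep_s = sum(asleep) * dt
    ),
    class = "immobility_summary"
  )
}

#' Screen band and phenodeviant flagging
#'
#' Constructs the "normal immobility range" of a screening cohort as
#' mean +/- k standard deviations per phase and flags individuals outside
#' the band in either phase.
#'
#' @param cohort List of `immobility_summary` objects (length at least 3).
#' @param k Band half-width in SD units, default 2.
#' @return A list of class `screen_band`: `band` (matrix phases x
#'   `c(mean, sd, lo, hi)`), `flags` (data frame with per-phase values and
#'   logical `deviant_light`, `deviant_dark`, `deviant`).
#' @export
screen_band <- function(cohort, k = 2) {
  stopifnot(length(cohort) >= 3)
  light <- vapply(cohort, function(s) s$pct_immobile_light, numeric(1))
  dark <- vapply(cohort, function(s) s$pct_immobile_dark, numeric(1))
  mk <- function(v) {
    m <- mean(v); s <- sd(v)
    c(mean = m, sd = s, lo = m - k * s, hi = m + k * s)
  }
  band <- rbind(LIGHT = mk(light), DARK = mk(dark))
  flags <- data.frame(
    individual = seq_along(cohort),
    pct_light = light, pct_dark = dark,
    deviant_light = light < band["LIGHT", "lo"] | light > band["LIGHT", "hi"],
    deviant_dark = dark < band["DARK", "lo"] | dark > band["DARK", "hi"]
  )
  flags$deviant <- flags$deviant_light | flags$deviant_dark
  structure(list(band = band, flags = flags, k = k), class = "screen_band")
}

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' Estimates circadian period from binned activity counts. For each candidate
#' period of `P` bins the data (truncated to `K = floor(N/P)` complete
#' cycles) are folded into a `K x P` matrix; the statistic is
#' `Qp = K * N' * sum((col_means - mean)^2) / sum((x - mean)^2)` with
#' `N' = K * P`, distributed approximately chi-square with `P - 1` degrees of
#' freedom under no rhythm. The period estimate is the Qp peak; amplitude is
#' peak Qp minus the pointwise alpha = 0.05 significance line.
#'
#' @param activity Numeric vector of activity counts per bin.
#' @param bin_minutes Bin length in minutes (default 10).
#' @param search_hours Period search range, default `c(20, 28)`; candidates
#'   step by one bin.
#' @param alpha Significance level for the chi-square line, default 0.05.
#' @return A list of class `periodogram_result`: `period_estimate_h`,
#'   `amplitude`, `significant` (peak above the line), and `table`
#'   (data frame `period_h`, `Qp`, `sig_line`).
#' @export
chi_square_periodogram <- function(activity, bin_minutes = 10,
                                   search_hours = c(20, 28), alpha = 0.05) {
  stopifnot(length(search_hours) == 2, search_hours[1] < search_hours[2])
  bins_per_hour <- 60 / bin_minutes
  p_lo <- ceiling(search_hours[1] * bins_per_hour)
  p_hi <- floor(search_hours[2] * bins_per_hour)
  N <- length(activity)
  if (N < 2 * p_hi) {
    stop(sprintf(
      "record too short: need >= 2 full cycles of the longest searched period (%d bins), have %d",
      2 * p_hi, N
    ))
  }
  res <- vapply(p_lo:p_hi, function(P) {
    K <- N %/% P
    x <- activity[seq_len(K * P)]
    m <- matrix(x, nrow = P)  # column h of the folded cycle = row h here
    col_means <- rowMeans(m)
    gm <- mean(x)
    denom <- sum((x - gm)^2)
    qp <- if (denom > 0) K * (K * P) * sum((col_means - gm)^2) / denom else 0
    c(qp, qchisq(1 - alpha, df = P - 1))
  }, numeric(2))
  tab <- data.frame(
    period_h = (p_lo:p_hi) / bins_per_hour,
    Qp = res[1, ], sig_line = res[2, ]
  )
  i <- which.max(tab$Qp)
  structure(
    list(
      period_estimate_h = tab$period_h[i],
      amplitude = tab$Qp[i] - tab$sig_line[i],
      significant = tab$Qp[i] > tab$sig_line[i],
      table = tab
    ),
    class = "periodogram_result"
  )
}
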