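#' Episode segmentation rules
#'
#' An episode of a vigilance state is a maximal run of that state in which
#' brief interruptions by other states are tolerated: runs separated by a gap
#' no longer than `max_gap_s` are merged, and the merged span must reach
#' `min_duration_s` to count. The conventional rodent rules are:
#'
#' * NREM and wake episodes: at least 1 min, interruptions up to 16 s
#'   (`rule_nrem_default()`, `rule_wake_default()`);
#' * REM episodes: as short as 4 s, interruptions up to 4 s
#'   (`rule_rem_default()`);
#' * the episode-duration-distribution variant in which all NREM episodes
#'   *longer than* 16 s are included (`rule_nrem_distribution()`,
#'   `min_inclusive = FALSE`).
#'
#' @param target_state Vigilance label the rule segments (`"NREM"` etc.).
#' @param min_duration_s Minimum episode span in seconds.
#' @param max_gap_s Maximum tolerated interruption in seconds (`>= 0`).
#' @param min_inclusive If `TRUE` (default) an episode qualifies when
#'   `span >= min_duration_s`; if `FALSE` the comparison is strict (`>`).
#' @return An object of class `segmentation_rule`.
#' @export
segmentation_rule <- function(target_state, min_duration_s, max_gap_s,
                              min_inclusive = TRUE) {
  target_state <- as.character(as_vigilance(target_state))
  if (max_gap_s < 0) stop("max_gap_s must be >= 0")
  if (min_duration_s < 0) stop("min_duration_s must be >= 0")
  structure(
    list(target_state = target_state, min_duration_s = min_duration_s,
         max_gap_s = max_gap_s, min_inclusive = min_inclusive),
    class = "segmentation_rule"
  )
}

#' @rdname segmentation_rule
#' @export
rule_nrem_default <- function() segmentation_rule("NREM", 60, 16)

#' @rdname segmentation_rule
#' @export
rule_wake_default <- function() segmentation_rule("WAKE", 60, 16)

#' @rdname segmentation_rule
#' @export
rule_rem_default <- function() segmentation_rule("REM", 4, 4)

#' @rdname segmentation_rule
#' @export
rule_nrem_distribution <- function() {
  segmentation_rule("NREM", 16, 16, min_inclusive = FALSE)
}

#' Segment state episodes with interruption tolerance
#'
#' Finds maximal runs of `rule$target_state`, merges runs separated by
#' non-target gaps of duration `<= max_gap_s` (a gap only merges when target
#' epochs flank it on both sides; leading/trailing non-target content never
#' joins an episode), and keeps merged spans satisfying the minimum-duration
#' condition. `ARTIFACT` epochs count as gap content.
#'
#' Durations follow the span convention: `span_s` runs from the first to the
#' last target-state epoch of the episode, interruptions included;
#' `within_s` counts target-state epochs only, so
#' `interruptions == 0` iff `span_s == within_s`.
#'
#' @param hyp A [hypnogram()].
#' @param rule A [segmentation_rule()].
#' @return A data frame of class `episode_table`, one row per episode, in
#'   temporal order, with columns `state`, `start_epoch`, `end_epoch`
#'   (1-based, inclusive), `span_s`, `within_s`, `interruptions`,
#'   `truncated_start`, `truncated_end` (episode touches the recording edge).
#' @examples
#' h <- hypnogram(rep(c("W", "N"), c(30, 40)))
#' segment_episodes(h, rule_nrem_default())
#' @export
segment_episodes <- function(hyp, rule) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(rule, "segmentation_rule"))
  eps <- hyp$epoch_s
  lab <- as.character(hyp$labels)
  n <- length(lab)
  is_t <- lab == rule$target_state

  empty <- episode_table(character(0), integer(0), integer(0), numeric(0),
                         numeric(0), integer(0), logical(0), logical(0))
  if (!any(is_t)) return(empty)

  r <- rle(is_t)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  t_idx <- which(r$values)
  # merge consecutive target runs when the single intervening gap fits;
  # gaps between target runs are exactly the non-target runs between them
  starts <- run_start[t_idx]
  ends <- run_end[t_idx]
  if (length(t_idx) > 1) {
    gap_epochs <- starts[-1] - ends[-length(ends)] - 1
    new_group <- c(TRUE, gap_epochs * eps > rule$max_gap_s)
  } else {
    new_group <- TRUE
  }
  grp <- cumsum(new_group)
  g_start <- tapply(starts, grp, min)
  g_end <- tapply(ends, grp, max)
  g_within <- tapply(ends - starts + 1, grp, sum)
  g_runs <- tapply(grp, grp, length)

  span_s <- (g_end - g_start + 1) * eps
  within_s <- g_within * eps
  keep <- if (rule$min_inclusive) span_s >= rule$min_duration_s
          else span_s > rule$min_duration_s
  episode_table(
    state = rep(rule$target_state, sum(keep)),
    start_epoch = as.integer(g_start[keep]),
    end_epoch = as.integer(g_end[keep]),
    span_s = as.numeric(span_s[keep]),
    within_s = as.numeric(within_s[keep]),
    interruptions = as.integer(g_runs[keep] - 1),
    truncated_start = as.integer(g_start[keep]) == 1L,
    truncated_end = as.integer(g_end[keep]) == n
  )
}

episode_table <- function(state, start_epoch, end_epoch, span_s, within_s,
                          interruptions, truncated_start, truncated_end) {
  df <- data.frame(
    state = state, start_epoch = start_epoch, end_epoch = end_epoch,
    span_s = span_s, within_s = within_s, interruptions = interruptions,
    truncated_start = truncated_start, truncated_end = truncated_end,
    stringsAsFactors = FALSE
  )
  class(df) <- c("episode_table", "data.frame")
  df
}

#' Detect brief awakenings
#'
#' Brief awakenings are short arousals during sleep: maximal WAKE runs of
#' duration at most `max_duration_s` (16 s by convention) whose immediately
#' adjacent epochs on both sides are sleep (NREM or REM). Runs touching the
#' recording boundary are excluded, as are runs that merge into a wake
#' *episode* (a short wake run sandwiched between two sub-16-s sleep
#' intrusions of a long wake period is part of that wake episode, not an
#' arousal during sleep). Brief awakenings are therefore disjoint from wake
#' episodes and always lie within or between sleep episodes.
#'
#' @param hyp A [hypnogram()].
#' @param max_duration_s Upper bound (inclusive) in seconds, default 16.
#' @param wake_rule Rule defining the wake episodes that preempt candidate
#'   runs, default [rule_wake_default()].
#' @return An `episode_table` (state `"WAKE"`, zero interruptions).
#' @export
detect_brief_awakenings <- function(hyp, max_duration_s = 16,
                                    wake_rule = rule_wake_default()) {
  lab <- as.character(hyp$labels)
  n <- length(lab)
  in_wake_ep <- logical(n)
  weps <- segment_episodes(hyp, wake_rule)
  for (i in seq_len(nrow(weps))) {
    in_wake_ep[weps$start_epoch[i]:weps$end_epoch[i]] <- TRUE
  }
  r <- rle(lab == "WAKE")
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  w <- which(r$values)
  keep <- vapply(w, function(i) {
    s <- run_start[i]; e <- run_end[i]
    if (s == 1 || e == n) return(FALSE)
    if ((e - s + 1) * hyp$epoch_s > max_duration_s) return(FALSE)
    if (any(in_wake_ep[s:e])) return(FALSE)
    lab[s - 1] %in% SLEEP_STATES && lab[e + 1] %in% SLEEP_STATES
  }, logical(1))
  w <- w[keep]
  episode_table(
    state = rep("WAKE", length(w)),
    start_epoch = as.integer(run_start[w]),
    end_epoch = as.integer(run_end[w]),
    span_s = (run_end[w] - run_start[w] + 1) * hyp$epoch_s,
    within_s = (run_end[w] - run_start[w] + 1) * hyp$epoch_s,
    interruptions = rep(0L, length(w)),
    truncated_start = rep(FALSE, length(w)),
    truncated_end = rep(FALSE, length(w))
  )
}

#' Histogram of episode durations
#'
#' Bins episode spans into half-open bins `[lo, hi)` defined by `bin_edges`,
#' with an overflow bin for spans at or beyond the last edge and an underflow
#' count for spans below the first edge (reported separately).
#'
#' @param episodes An `episode_table` from [segment_episodes()].
#' @param bin_edges Strictly increasing numeric vector of edges, seconds.
#' @return A data frame with columns `bin_lo`, `bin_hi` (last bin `Inf`),
#'   `count`; attribute `underflow` holds the below-first-edge count.
#' @export
episode_duration_distribution <- function(episodes, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  lo <- bin_edges
  hi <- c(bin_edges[-1], Inf)
  d <- episodes$span_s
  count <- vapply(seq_along(lo), function(i) sum(d >= lo[i] & d < hi[i]),
                  numeric(1))
  out <- data.frame(bin_lo = lo, bin_hi = hi, count = as.integer(count))
  attr(out, "underflow") <- sum(d < lo[1])
  out
}
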