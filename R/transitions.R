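#' Episode-level state-transition summary
#'
#' Counts transitions between *episodes* over the record. Wake and NREM
#' episodes are segmented with the at-least-1-min / interruptions-up-to-16-s
#' rule; REM episodes with the 4 s / 4 s rule (no practical minimum duration).
#' A wake-to-NREM transition is counted when the first epoch after a wake
#' episode's end that belongs to any episode belongs to an NREM episode;
#' NREM-to-REM transitions are counted symmetrically. Epochs belonging to no
#' episode (e.g. a 30-s wake run, too short to be an episode and too long to
#' merge) are skipped when deciding what follows an episode.
#'
#' The termination percentage is
#' `100 * n_nrem_to_rem / n_nrem_episodes` and is reported `NA` when there
#' are no NREM episodes.
#'
#' @param hyp A [hypnogram()].
#' @param wake_rule,nrem_rule,rem_rule Segmentation rules; defaults as above.
#' @return A list of class `transition_summary` with counts over the record
#'   (`n_wake_to_nrem`, `n_nrem_to_rem`, `n_nrem_episodes`,
#'   `n_wake_episodes`, `n_rem_episodes`, `n_brief_awakenings`),
#'   `pct_nrem_terminating_in_rem`, and `duration_h`. For a 24-h record the
#'   counts are per-24-h figures.
#' @export
transition_summary <- function(hyp,
                               wake_rule = rule_wake_default(),
                               nrem_rule = rule_nrem_default(),
                               rem_rule = rule_rem_default()) {
  stopifnot(inherits(hyp, "hypnogram"))
  wake_eps <- segment_episodes(hyp, wake_rule)
  nrem_eps <- segment_episodes(hyp, nrem_rule)
  rem_eps <- segment_episodes(hyp, rem_rule)

  n <- n_epochs(hyp)
  lab <- as.character(hyp$labels)
  all_eps <- rbind(wake_eps, nrem_eps, rem_eps)
  # ownership map: which episode's span covers each epoch. Spans of different
  # states can nest (short foreign runs inside a span); the label-matching
  # episode wins on overlap so "belongs to a REM episode" means a REM epoch.
  own_state <- character(n)
  if (nrow(all_eps)) {
    ord <- order(all_eps$start_epoch)
    all_eps <- all_eps[ord, ]
    for (i in seq_len(nrow(all_eps))) {
      idx <- all_eps$start_epoch[i]:all_eps$end_epoch[i]
      claim <- own_state[idx] == "" | lab[idx] == all_eps$state[i]
      own_state[idx[claim]] <- all_eps$state[i]
    }
  }
  next_owned <- function(end_epoch) {
    j <- end_epoch + 1
    while (j <= n && own_state[j] == "") j <- j + 1
    if (j > n) NA_character_ else own_state[j]
  }
  count_into <- function(eps, to_state) {
    if (!nrow(eps)) return(0L)
    sum(vapply(eps$end_epoch, next_owned, "") == to_state, na.rm = TRUE)
  }
  n_w2n <- count_into(wake_eps, "NREM")
  n_n2r <- count_into(nrem_eps, "REM")
  n_nrem <- nrow(nrem_eps)
  structure(
    list(
      n_wake_to_nrem = n_w2n,
      n_nrem_to_rem = n_n2r,
      n_nrem_episodes = n_nrem,
      n_wake_episodes = nrow(wake_eps),
      n_rem_episodes = nrow(rem_eps),
      n_brief_awakenings = nrow(detect_brief_awakenings(hyp)),
      pct_nrem_terminating_in_rem =
        if (n_nrem > 0) 100 * n_n2r / n_nrem else NA_real_,
      duration_h = duration_s(hyp) / 3600
    ),
    class = "transition_summary"
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<transition_summary> %.1f h record\n",
           "  wake->NREM %d | NREM->REM %d | NREM episodes %d",
           " | brief awakenings %d\n",
           "  %% NREM episodes terminating in REM: %s\n"),
    x$duration_h, x$n_wake_to_nrem, x$n_nrem_to_rem, x$n_nrem_episodes,
    x$n_brief_awakenings,
    if (is.na(x$pct_nrem_terminating_in_rem)) "NA"
    else sprintf("%.1f", x$pct_nrem_terminating_in_rem)
  ))
  invisible(x)
}
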