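# Independent oracles and fixture builders. The segmentation oracle walks
# epochs one by one with an explicit state machine -- no rle(), no sharing of
# code with the implementation.

brute_segment <- function(labels, epoch_s, target, min_s, gap_s,
                          min_inclusive = TRUE) {
  n <- length(labels)
  hits <- which(labels == target)
  out <- list()
  used <- logical(n)
  i <- 1
  while (i <= length(hits)) {
    start <- hits[i]
    end <- start
    # greedily absorb later target epochs while every intervening stretch of
    # non-target epochs is short enough
    j <- i + 1
    while (j <= length(hits)) {
      gap_epochs <- hits[j] - end - 1
      if (gap_epochs * epoch_s <= gap_s) {
        end <- hits[j]
        j <- j + 1
      } else break
    }
    within <- sum(labels[start:end] == target)
    # count maximal non-target stretches strictly inside [start, end]
    interruptions <- 0
    k <- start
    while (k <= end) {
      if (labels[k] != target) {
        interruptions <- interruptions + 1
        while (k <= end && labels[k] != target) k <- k + 1
      } else k <- k + 1
    }
    span_s <- (end - start + 1) * epoch_s
    ok <- if (min_inclusive) span_s >= min_s else span_s > min_s
    if (ok) {
      out[[length(out) + 1]] <- data.frame(
        state = target, start_epoch = start, end_epoch = end,
        span_s = span_s, within_s = within * epoch_s,
        interruptions = interruptions,
        truncated_start = start == 1, truncated_end = end == n,
        stringsAsFactors = FALSE
      )
    }
    i <- j
  }
  if (!length(out)) {
    return(data.frame(
      state = character(0), start_epoch = integer(0), end_epoch = integer(0),
      span_s = numeric(0), within_s = numeric(0), interruptions = integer(0),
      truncated_start = logical(0), truncated_end = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

random_labels <- function(n, p = c(0.4, 0.35, 0.15, 0.1)) {
  sample(c("WAKE", "NREM", "REM", "ARTIFACT"), n, replace = TRUE, prob = p)
}

random_hypnogram <- function(n, p = c(0.4, 0.35, 0.15, 0.1), epoch_s = 4) {
  hypnogram(random_labels(n, p), epoch_s = epoch_s)
}

expect_episodes_equal <- function(got, want) {
  got <- as.data.frame(got)[, names(want)]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

# Wilson 95% binomial confidence interval
wilson_ci <- function(x, n, z = 1.96) {
  if (n == 0) return(c(0, 1))
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

acceptance_rules <- function() {
  list(
    nrem = rule_nrem_default(),
    rem = rule_rem_default(),
    fig_dist = rule_nrem_distribution()
  )
}
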