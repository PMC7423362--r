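test_that("interruption merging follows the hand-enumerated example", {
  # 20 N, 4 W (16 s), 20 N, flanked by long wake
  lab <- c(rep("W", 30), rep("N", 20), rep("W", 4), rep("N", 20), rep("W", 30))
  h <- hypnogram(lab, epoch_s = 4)
  eps <- segment_episodes(h, rule_nrem_default())
  expect_equal(nrow(eps), 1)
  expect_equal(eps$span_s, 176)
  expect_equal(eps$within_s, 160)
  expect_equal(eps$interruptions, 1)
  expect_false(eps$truncated_start || eps$truncated_end)
})

test_that("minimum-duration conventions separate the default and distribution rules", {
  lab <- c(rep("W", 30), rep("N", 10), rep("W", 30))  # isolated 40-s NREM
  h <- hypnogram(lab, epoch_s = 4)
  expect_equal(nrow(segment_episodes(h, rule_nrem_default())), 0)
  d <- segment_episodes(h, rule_nrem_distribution())
  expect_equal(nrow(d), 1)
  expect_equal(d$span_s, 40)

  # "longer than 16 s" is strict: a 16-s run does not qualify
  lab2 <- c(rep("W", 30), rep("N", 4), rep("W", 30))
  expect_equal(
    nrow(segment_episodes(hypnogram(lab2), rule_nrem_distribution())), 0)
})

test_that("a single 4-s REM epoch is a REM episode", {
  h <- hypnogram(c(rep("N", 20), "R", rep("N", 20)))
  eps <- segment_episodes(h, rule_rem_default())
  expect_equal(nrow(eps), 1)
  expect_equal(eps$span_s, 4)
})

test_that("degenerate inputs behave", {
  h <- hypnogram(rep("N", 21600))
  eps <- segment_episodes(h, rule_nrem_default())
  expect_equal(nrow(eps), 1)
  expect_equal(eps$span_s, 86400)
  expect_true(eps$truncated_start && eps$truncated_end)

  expect_equal(nrow(segment_episodes(hypnogram(rep("W", 100)),
                                     rule_nrem_default())), 0)
  expect_error(segmentation_rule("NREM", 60, -1), "max_gap_s")
})

test_that("segmentation matches the brute-force oracle on random hypnograms", {
  set.seed(402)
  rules <- acceptance_rules()
  for (i in 1:200) {
    n <- sample(5:500, 1)
    lab <- random_labels(n)
    h <- hypnogram(lab, epoch_s = 4)
    for (r in rules) {
      got <- segment_episodes(h, r)
      want <- brute_segment(lab, 4, r$target_state, r$min_duration_s,
                            r$max_gap_s, r$min_inclusive)
      expect_episodes_equal(got, want)
    }
  }
})

test_that("episode counts/durations are monotone in the rule parameters", {
  set.seed(403)
  for (i in 1:40) {
    lab <- random_labels(sample(50:400, 1))
    h <- hypnogram(lab)
    # gap monotonicity holds for the raw merged groups (min duration 0);
    # a minimum-duration filter can promote newly merged groups, so counts
    # are only monotone pre-filter
    base0 <- segment_episodes(h, segmentation_rule("NREM", 0, 8))
    wider0 <- segment_episodes(h, segmentation_rule("NREM", 0, 20))
    expect_lte(nrow(wider0), nrow(base0))
    expect_gte(sum(wider0$span_s), sum(base0$span_s))
    # span totals of filtered episodes still never shrink (merging only
    # grows spans, so qualification is never lost)
    base <- segment_episodes(h, segmentation_rule("NREM", 40, 8))
    wider <- segment_episodes(h, segmentation_rule("NREM", 40, 20))
    expect_gte(sum(wider$span_s), sum(base$span_s))
    stricter <- segment_episodes(h, segmentation_rule("NREM", 80, 8))
    expect_lte(nrow(stricter), nrow(base))    # higher minimum, fewer episodes
  }
})

test_that("brief awakenings obey the 16-s bound and sleep flanking", {
  expect_equal(nrow(detect_brief_awakenings(
    hypnogram(c("N", "N", "W", "W", "W", "W", "N")))), 1)   # 16 s wake
  expect_equal(nrow(detect_brief_awakenings(
    hypnogram(c("N", "N", "W", "W", "W", "W", "W", "N")))), 0)  # 20 s
  expect_equal(nrow(detect_brief_awakenings(
    hypnogram(c("W", "W", "N", "N")))), 0)    # touches recording start
  expect_equal(nrow(detect_brief_awakenings(
    hypnogram(c("N", "W", "A", "N")))), 0)    # artifact flank is not sleep
  ba <- detect_brief_awakenings(hypnogram(c("N", "W", "R", "N")))
  expect_equal(ba$span_s, 4)                  # REM flank counts as sleep
})

test_that("brief awakenings never coincide with wake episodes", {
  set.seed(404)
  for (i in 1:30) {
    h <- random_hypnogram(sample(100:500, 1), p = c(0.3, 0.5, 0.15, 0.05))
    ba <- detect_brief_awakenings(h)
    weps <- segment_episodes(h, rule_wake_default())
    if (nrow(ba) && nrow(weps)) {
      for (k in seq_len(nrow(ba))) {
        # a brief awakening's epochs are wake epochs, hence can only fall in
        # a wake episode's span if that episode swallowed them as its own
        # run -- impossible since the run is <= 16 s and flanked by sleep
        inside <- weps$start_epoch <= ba$start_epoch[k] &
          weps$end_epoch >= ba$end_epoch[k]
        expect_false(any(inside))
      }
    }
  }
})

test_that("duration histograms bin and conserve counts", {
  eps <- episode_table(rep("NREM", 3), c(1, 50, 200), c(10, 93, 374),
                       c(40, 176, 700), c(40, 176, 700), rep(0L, 3),
                       rep(FALSE, 3), rep(FALSE, 3))
  hgram <- episode_duration_distribution(eps, c(16, 64, 256, 1024))
  expect_equal(hgram$count, c(1L, 1L, 1L, 0L))
  expect_equal(attr(hgram, "underflow"), 0)

  empty <- episode_duration_distribution(eps[0, ], c(16, 64))
  expect_equal(empty$count, c(0L, 0L))
  expect_error(episode_duration_distribution(eps, c(10, 10)), "increasing")

  set.seed(405)
  for (i in 1:20) {
    h <- random_hypnogram(sample(100:400, 1))
    e <- segment_episodes(h, rule_nrem_distribution())
    hist_e <- episode_duration_distribution(e, c(16, 64, 256, 1024))
    expect_equal(sum(hist_e$count) + attr(hist_e, "underflow"), nrow(e))
  }
})
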