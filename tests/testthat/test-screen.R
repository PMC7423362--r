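test_that("immobility scoring arithmetic and strict threshold", {
  # one 45-s immobile run inside 1 h of mobility
  tr <- mobility_trace(c(rep(1, 100), rep(0, 45), rep(1, 3455)))
  s <- score_immobility_sleep(tr)
  expect_equal(nrow(s$bouts), 1)
  expect_equal(s$bouts$duration_s, 45)
  expect_equal(s$hourly_pct[1], 100 * 45 / 3600)

  # exactly 40 s: no bout (strict >); 44 s: one bout
  t40 <- mobility_trace(c(rep(1, 10), rep(0, 40), rep(1, 10)))
  expect_equal(nrow(score_immobility_sleep(t40)$bouts), 0)
  t44 <- mobility_trace(c(rep(1, 10), rep(0, 44), rep(1, 10)))
  expect_equal(nrow(score_immobility_sleep(t44)$bouts), 1)

  # alternating 30 s immobile / 10 s mobile never crosses the threshold
  alt <- mobility_trace(rep(c(rep(0, 30), rep(1, 10)), 90))
  expect_equal(nrow(score_immobility_sleep(alt)$bouts), 0)
  expect_equal(score_immobility_sleep(alt)$total_sleep_s, 0)
})

test_that("hourly percentages duration-average to phase percentages", {
  set.seed(411)
  hyp <- simulate_hypnogram(calibrate_preset(genotype_preset("WT")), seed = 9)
  tr <- synthesize_tracking(hyp, seed = 9)
  s <- score_immobility_sleep(tr)
  expect_equal(mean(s$hourly_pct[1:12]), s$pct_immobile_light, tolerance = 1e-9)
  expect_equal(mean(s$hourly_pct[13:24]), s$pct_immobile_dark, tolerance = 1e-9)
})

test_that("immobility scoring is idempotent under trace refinement", {
  set.seed(412)
  m1 <- rep(sample(c(0, 1), 600, replace = TRUE, prob = c(0.7, 0.3)),
            times = sample(20:80, 600, replace = TRUE))[1:7200]
  tr1 <- mobility_trace(m1, sample_interval_s = 1)
  tr05 <- mobility_trace(rep(m1, each = 2), sample_interval_s = 0.5)
  s1 <- score_immobility_sleep(tr1)
  s05 <- score_immobility_sleep(tr05)
  expect_equal(nrow(s1$bouts), nrow(s05$bouts))
  expect_equal(s1$total_sleep_s, s05$total_sleep_s)
})

test_that("screen band construction and phenodeviant flagging", {
  fake <- function(l, d = 50) {
    structure(list(pct_immobile_light = l, pct_immobile_dark = d),
              class = "immobility_summary")
  }
  sb <- screen_band(list(fake(60), fake(62), fake(64)), k = 2)
  expect_equal(unname(sb$band["LIGHT", c("lo", "hi")]), c(58, 66))
  expect_lt(50, sb$band["LIGHT", "lo"])      # a 50% animal is phenodeviant

  # all-identical cohort: zero-width band, any different value outside it
  sb0 <- screen_band(list(fake(60), fake(60), fake(60)))
  expect_equal(unname(sb0$band["LIGHT", "sd"]), 0)
  expect_true(61 > sb0$band["LIGHT", "hi"])
  expect_error(screen_band(list(fake(60))), "length")
})

test_that("flag rate on a normal cohort approximates the two-sided tail", {
  set.seed(413)
  n <- 400
  cohort <- lapply(rnorm(n, 60, 5), function(l) {
    structure(list(pct_immobile_light = l,
                   pct_immobile_dark = rnorm(1, 40, 5)),
              class = "immobility_summary")
  })
  sb <- screen_band(cohort, k = 2)
  rate <- mean(sb$flags$deviant_light)
  expected <- 2 * pnorm(-2)                 # ~0.0455
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rate - expected), 4 * se)
})

test_that("chi-square periodogram recovers known periods", {
  act24 <- synthesize_activity(10, period_h = 24, seed = 21)
  p24 <- chi_square_periodogram(act24)
  expect_lt(abs(p24$period_estimate_h - 24), 1 / 6 + 1e-9)
  expect_true(p24$significant)

  act235 <- synthesize_activity(10, period_h = 23.5, seed = 22)
  p235 <- chi_square_periodogram(act235)
  expect_lt(abs(p235$period_estimate_h - 23.5), 1 / 6 + 1e-9)

  # constant activity: flat Qp, nothing significant
  flat <- chi_square_periodogram(rep(5, 1440))
  expect_false(flat$significant)

  # scaling invariance of the peak
  p24b <- chi_square_periodogram(act24 * 7.3)
  expect_equal(p24b$period_estimate_h, p24$period_estimate_h)
  expect_equal(p24b$table$Qp, p24$table$Qp, tolerance = 1e-12)

  expect_error(chi_square_periodogram(rep(1, 100)), "too short")
})
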