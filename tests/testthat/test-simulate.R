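test_that("calibration hits preset occupancy targets within 2%", {
  for (g in c("WT", "RLSS")) {
    preset <- genotype_preset(g)
    cfg <- calibrate_preset(preset)
    occ <- stationary_occupancy(cfg)$overall_h
    expect_true(all(abs(occ - preset$target_occupancy_h) <= 0.02 * 24))
  }
})

test_that("semi-Markov occupancy agrees with the per-epoch chain stationary", {
  # independent route: the per-epoch transition matrix's stationary vector
  # is the occupancy, computed here by power iteration
  cfg <- calibrate_preset(genotype_preset("WT"))
  for (ph in c("LIGHT", "DARK")) {
    P <- epoch_transition_matrix(cfg, ph)
    v <- c(1, 1, 1) / 3
    for (i in 1:20000) v <- as.numeric(v %*% P)
    occ <- stationary_occupancy(cfg, adjust_brief_awakenings = FALSE)
    expect_equal(v, unname(occ$per_phase[, ph]), tolerance = 1e-6)
  }
})

test_that("degenerate and boundary presets behave", {
  allwake <- list(name = "degenerate",
                  target_occupancy_h = c(WAKE = 24, NREM = 0, REM = 0),
                  rem_entry_p = 0.9)
  cfg <- calibrate_preset(allwake)
  h <- simulate_hypnogram(cfg, seed = 1)
  expect_true(all(as.character(h$labels) == "WAKE"))

  infeasible <- list(name = "bad",
                     target_occupancy_h = c(WAKE = 10, NREM = 4, REM = 10),
                     rem_entry_p = 0.9)
  expect_error(calibrate_preset(infeasible), "infeasible")
})

test_that("zero REM entry produces a REM-free hypnogram", {
  p <- genotype_preset("WT")
  p$rem_entry_p <- 0
  p$target_occupancy_h <- c(WAKE = 12, NREM = 12, REM = 0)
  cfg <- calibrate_preset(p)
  h <- simulate_hypnogram(cfg, seed = 3)
  expect_equal(sum(as.character(h$labels) == "REM"), 0)
})

test_that("simulated occupancy matches printed-value arithmetic across seeds", {
  cfgW <- calibrate_preset(genotype_preset("WT"))
  cfgR <- calibrate_preset(genotype_preset("RLSS"))
  occW <- t(vapply(1:20, function(s) {
    time_in_state(simulate_hypnogram(cfgW, seed = 700 + s))$total_h
  }, numeric(4)))
  occR <- t(vapply(1:20, function(s) {
    time_in_state(simulate_hypnogram(cfgR, seed = 700 + s))$total_h
  }, numeric(4)))
  expect_lt(abs(mean(occW[, "NREM"]) - 10.0), 0.5)   # 1.4 h / 0.14
  expect_lt(abs(mean(occW[, "REM"]) - 2.1), 0.2)     # 1.2 h / 0.57
  expect_lt(abs(mean(occR[, "NREM"]) - 8.6), 0.5)
  expect_lt(abs(mean(occR[, "REM"]) - 0.9), 0.2)
})

test_that("identical config and seed reproduce the hypnogram bit for bit", {
  cfg <- calibrate_preset(genotype_preset("RLSS"))
  h1 <- simulate_hypnogram(cfg, seed = 77)
  h2 <- simulate_hypnogram(cfg, seed = 77)
  expect_identical(as.character(h1$labels), as.character(h2$labels))

  coh1 <- simulate_cohort("WT", n = 3, base_seed = 5)
  coh2 <- simulate_cohort("WT", n = 3, base_seed = 5)
  for (i in 1:3) {
    expect_identical(as.character(coh1$hypnograms[[i]]$labels),
                     as.character(coh2$hypnograms[[i]]$labels))
  }
  expect_equal(coh1$manifest$seed, 5:7)
})

test_that("long-run empirical occupancy converges to the chain occupancy", {
  p <- genotype_preset("WT")
  p$brief_awakening_rate_per_h <- 0
  cfg <- calibrate_preset(p, hours = 240)
  h <- simulate_hypnogram(cfg, seed = 31)
  emp <- time_in_state(h)$total_h / 240
  theo <- stationary_occupancy(cfg)$overall_h / cfg$hours
  expect_true(all(abs(emp[names(theo)] - theo) < 0.03))
})

test_that("brief awakenings are inserted at roughly the configured rate", {
  cfg <- calibrate_preset(genotype_preset("WT"))
  n_ba <- vapply(1:10, function(s) {
    h <- simulate_hypnogram(cfg, seed = 800 + s)
    nrem_h <- time_in_state(h)$total_h[["NREM"]]
    nrow(detect_brief_awakenings(h)) / nrem_h
  }, numeric(1))
  # insertion can fail near run edges, so the realised rate is a bit below 8
  expect_gt(mean(n_ba), 5.5)
  expect_lt(mean(n_ba), 8.5)
})

test_that("mutant wake-episode frequency is roughly halved", {
  count24 <- function(preset, seeds) {
    cfg <- calibrate_preset(genotype_preset(preset))
    mean(vapply(seeds, function(s) {
      wake_episode_stats(simulate_hypnogram(cfg, seed = s))$count
    }, numeric(1)))
  }
  ratio <- count24("RLSS", 900 + 1:8) / count24("WT", 900 + 1:8)
  expect_lt(ratio, 0.75)
  expect_gt(ratio, 0.3)
})
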