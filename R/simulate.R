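#' Simulator configuration
#'
#' Parameters of the semi-Markov hypnogram generator. States are
#' wake (W), NREM (N), REM (R); dwell times are geometric at epoch scale
#' with phase-specific means, and on leaving a state the next state follows
#' the embedded transition matrix. REM is entered only from NREM (the
#' wake -> NREM -> REM continuum), with probability `rem_entry_p` at each
#' NREM exit; REM exits to wake with probability `rem_to_wake_p`, otherwise
#' back to NREM. Brief awakenings (wake runs of 1-4 epochs) are inserted
#' post hoc into NREM at `brief_awakening_rate_per_h` expected insertions per
#' hour of NREM, overwriting NREM epochs while keeping sleep on both flanks.
#'
#' @param mean_dwell_s 3 x 2 numeric matrix of mean dwell times in seconds,
#'   rows `WAKE,NREM,REM`, columns `LIGHT,DARK`. `Inf` means an absorbing
#'   state. All finite entries must be `>= epoch_s`.
#' @param rem_entry_p Probability an ending NREM dwell transitions to REM.
#' @param rem_to_wake_p Probability an ending REM dwell transitions to WAKE
#'   (else back to NREM), default 0.7.
#' @param brief_awakening_rate_per_h Expected brief-awakening insertions per
#'   hour of NREM, default 8.
#' @param epoch_s Epoch length, seconds (default 4).
#' @param hours Recording duration, hours (default 24).
#' @param schedule A [light_schedule()]; the simulated record starts at
#'   lights-on.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mean_dwell_s, rem_entry_p, rem_to_wake_p = 0.7,
                       brief_awakening_rate_per_h = 8, epoch_s = 4,
                       hours = 24, schedule = light_schedule()) {
  mean_dwell_s <- as.matrix(mean_dwell_s)
  stopifnot(nrow(mean_dwell_s) == 3, ncol(mean_dwell_s) == 2,
            rem_entry_p >= 0, rem_entry_p <= 1,
            rem_to_wake_p >= 0, rem_to_wake_p <= 1,
            brief_awakening_rate_per_h >= 0, epoch_s > 0, hours > 0)
  dimnames(mean_dwell_s) <- list(c("WAKE", "NREM", "REM"), c("LIGHT", "DARK"))
  fin <- is.finite(mean_dwell_s)
  if (any(mean_dwell_s[fin] < epoch_s)) {
    stop("all finite mean dwell times must be >= epoch_s")
  }
  cfg <- structure(
    list(mean_dwell_s = mean_dwell_s, rem_entry_p = rem_entry_p,
         rem_to_wake_p = rem_to_wake_p,
         brief_awakening_rate_per_h = brief_awakening_rate_per_h,
         epoch_s = epoch_s, hours = hours, schedule = schedule),
    class = "sim_config"
  )
  e <- embedded_matrix(cfg)
  if (any(abs(rowSums(e) - 1) > 1e-9) || e["WAKE", "REM"] != 0) {
    stop("invalid embedded transition matrix")  # structural guard
  }
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config`.
#' @return `embedded_matrix()`: the 3x3 row-stochastic embedded transition
#'   matrix (rows/cols `WAKE,NREM,REM`; `WAKE -> REM` is structurally zero).
#' @export
embedded_matrix <- function(cfg) {
  q <- cfg$rem_entry_p; r <- cfg$rem_to_wake_p
  m <- matrix(c(
    0,     1,     0,
    1 - q, 0,     q,
    r,     1 - r, 0
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("WAKE", "NREM", "REM"), c("WAKE", "NREM", "REM")))
  m
}

#' Long-run state occupancy of a configured chain
#'
#' The numeric stationary occupancy of the semi-Markov chain: within one
#' phase, occupancy of state i is proportional to `pi_i * m_i` where `pi` is
#' the stationary distribution of the embedded chain and `m_i` the mean
#' dwell; the 24-h occupancy weights the two phases by their durations.
#' Brief-awakening insertion is accounted for by moving the expected
#' overwritten NREM time to wake.
#'
#' @param cfg A [sim_config()].
#' @param adjust_brief_awakenings Apply the insertion correction
#'   (default `TRUE`).
#' @return A list with `per_phase` (3 x 2 matrix of occupancy fractions) and
#'   `overall_h` (named hours per state over `cfg$hours`).
#' @export
stationary_occupancy <- function(cfg, adjust_brief_awakenings = TRUE) {
  e <- embedded_matrix(cfg)
  # embedded stationary distribution via the null space of (P' - I)
  a <- rbind(t(e) - diag(3), rep(1, 3))
  pi_e <- solve(crossprod(a), crossprod(a, c(0, 0, 0, 1)))[, 1]
  per_phase <- apply(cfg$mean_dwell_s, 2, function(m) {
    w <- pi_e * m
    if (any(is.infinite(w))) {
      out <- as.numeric(is.infinite(w) & pi_e > 0)
      return(out / sum(out))
    }
    w / sum(w)
  })
  rownames(per_phase) <- c("WAKE", "NREM", "REM")
  if (adjust_brief_awakenings && cfg$brief_awakening_rate_per_h > 0) {
    steal <- cfg$brief_awakening_rate_per_h * (2.5 * cfg$epoch_s) / 3600
    per_phase["WAKE", ] <- per_phase["WAKE", ] + per_phase["NREM", ] * steal
    per_phase["NREM", ] <- per_phase["NREM", ] * (1 - steal)
  }
  sched <- cfg$schedule
  wts <- c(LIGHT = sched$light_s, DARK = sched$dark_s)
  wts <- wts / sum(wts)
  overall <- per_phase %*% wts * cfg$hours
  list(per_phase = per_phase, overall_h = setNames(overall[, 1],
                                                   rownames(per_phase)))
}

#' Genotype presets
#'
#' Stated-world presets reproducing the headline wild-type versus mutant
#' contrasts: the mutant accumulates 1.4 h (14%) less NREM and 1.2 h (57%)
#' less REM sleep over 24 h, and its NREM episodes terminate in REM less
#' often (entry probability 0.65 versus 0.90). Wild-type absolute times are
#' derived from the printed deltas (NREM 10.0 h = 1.4/0.14,
#' REM 2.1 h = 1.2/0.57, wake the remainder); mutant times are wild type
#' minus the deltas.
#'
#' @param name `"WT"` or `"RLSS"` (the mutant line).
#' @return A list of class `genotype_preset`: `name`,
#'   `target_occupancy_h` (named W/N/R hours summing to 24),
#'   `rem_entry_p`, `rem_to_wake_p`, `mean_rem_dwell_s` (base, phase factor
#'   applied at calibration), `brief_awakening_rate_per_h`, `phase_factor`,
#'   `relative_wake_episode_count` (informational; mutant wake-episode
#'   frequency is roughly half the wild type's).
#' @export
genotype_preset <- function(name = c("WT", "RLSS")) {
  name <- match.arg(toupper(name), c("WT", "RLSS"))
  if (name == "WT") {
    p <- list(
      name = "WT",
      target_occupancy_h = c(WAKE = 11.9, NREM = 10.0, REM = 2.1),
      rem_entry_p = 0.90, rem_to_wake_p = 0.7,
      mean_rem_dwell_s = 60, brief_awakening_rate_per_h = 8,
      phase_factor = 1.5, relative_wake_episode_count = 1
    )
  } else {
    p <- list(
      name = "RLSS",
      target_occupancy_h = c(WAKE = 14.5, NREM = 8.6, REM = 0.9),
      rem_entry_p = 0.65, rem_to_wake_p = 0.7,
      mean_rem_dwell_s = 70, brief_awakening_rate_per_h = 4,
      phase_factor = 1.5, relative_wake_episode_count = 0.5
    )
  }
  structure(p, class = "genotype_preset")
}

#' Calibrate a preset into a simulator configuration
#'
#' Solves for the base wake and NREM mean dwells such that the chain's
#' numeric long-run occupancy (including the light/dark dwell modulation and
#' the brief-awakening correction) matches the preset's 24-h targets. The
#' REM mean dwell is fixed by the preset (occupancy constraints leave one
#' dwell free; REM bout duration is the natural quantity to pin). Sleep
#' dwells are multiplied by `phase_factor` in the light phase and divided by
#' it in the dark; wake dwells the other way around.
#'
#' Deterministic: no randomness is involved.
#'
#' @param preset A [genotype_preset()] (or compatible list).
#' @param epoch_s,hours,schedule Passed to [sim_config()].
#' @param tol_frac Required relative occupancy accuracy (default 0.02).
#' @return A [sim_config()] whose [stationary_occupancy()] matches the
#'   targets within `tol_frac` of 24 h per state.
#' @export
calibrate_preset <- function(preset, epoch_s = 4, hours = 24,
                             schedule = light_schedule(), tol_frac = 0.02) {
  tgt <- preset$target_occupancy_h
  if (abs(sum(tgt) - 24) > 1e-6) stop("target occupancies must sum to 24 h")
  if (any(tgt < 0)) stop("negative target occupancy")
  if (tgt["REM"] > tgt["NREM"]) {
    stop("infeasible target: REM occupancy exceeds NREM")
  }
  f <- preset$phase_factor %||% 1.5
  q <- preset$rem_entry_p
  r <- preset$rem_to_wake_p %||% 0.7
  ba <- preset$brief_awakening_rate_per_h %||% 0
  m_r <- preset$mean_rem_dwell_s

  # calibration always targets the 24-h design; `hours` only sets the
  # simulated record length
  mk_cfg <- function(m_w, m_n, hrs = 24) {
    md <- cbind(
      LIGHT = c(m_w / f, m_n * f, m_r * f),
      DARK = c(m_w * f, m_n / f, m_r / f)
    )
    rownames(md) <- c("WAKE", "NREM", "REM")
    sim_config(md, rem_entry_p = q, rem_to_wake_p = r,
               brief_awakening_rate_per_h = ba, epoch_s = epoch_s,
               hours = hrs, schedule = schedule)
  }

  # degenerate all-wake target: chain never leaves wake
  if (tgt["NREM"] < 1e-9 && tgt["REM"] < 1e-9) {
    md <- cbind(LIGHT = c(Inf, epoch_s, epoch_s),
                DARK = c(Inf, epoch_s, epoch_s))
    rownames(md) <- c("WAKE", "NREM", "REM")
    return(sim_config(md, rem_entry_p = 0, rem_to_wake_p = r,
                      brief_awakening_rate_per_h = 0, epoch_s = epoch_s,
                      hours = hours, schedule = schedule))
  }
  if (tgt["REM"] < 1e-9) q <- 0

  # closed-form single-phase start values, then numeric refinement over the
  # phase-modulated two-phase chain
  e <- embedded_matrix(mk_cfg(300, 300))
  a <- rbind(t(e) - diag(3), rep(1, 3))
  pi_e <- solve(crossprod(a), crossprod(a, c(0, 0, 0, 1)))[, 1]
  m_n0 <- if (q > 0) q * m_r * tgt["NREM"] / max(tgt["REM"], 1e-6) else 240
  m_n0 <- max(m_n0, epoch_s * f)
  m_w0 <- max((tgt["WAKE"] / tgt["NREM"]) * pi_e[2] * m_n0 / pi_e[1],
              epoch_s * f)
  obj <- function(par) {
    cfg <- mk_cfg(exp(par[1]), exp(par[2]))
    occ <- stationary_occupancy(cfg)$overall_h
    sum((occ - tgt)^2)
  }
  fit <- optim(log(c(m_w0, m_n0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  cfg <- mk_cfg(exp(fit$par[1]), exp(fit$par[2]))
  occ <- stationary_occupancy(cfg)$overall_h
  cfg <- mk_cfg(exp(fit$par[1]), exp(fit$par[2]), hrs = hours)
  if (any(abs(occ - tgt) > tol_frac * 24)) {
    stop("calibration failed: occupancy ",
         paste(sprintf("%s=%.2f", names(occ), occ), collapse = " "),
         " vs targets ",
         paste(sprintf("%s=%.2f", names(tgt), tgt), collapse = " "))
  }
  attr(cfg, "preset") <- preset$name %||% "custom"
  cfg
}

#' Simulate a hypnogram
#'
#' Semi-Markov generation at epoch resolution: dwell times are geometric
#' with the phase-specific mean; at a light/dark boundary the running dwell
#' is truncated and re-drawn under the new phase's parameters (the geometric
#' law is memoryless, so this equals switching the per-epoch hazard). Brief
#' awakenings are then inserted into NREM (see [sim_config()]). The record
#' starts at lights-on.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (optional; the caller's RNG stream is used when
#'   `NULL`).
#' @param subject_id,group_tag Passed to [hypnogram()].
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(cfg, seed = NULL, subject_id = "sim",
                               group_tag = attr(cfg, "preset") %||% "") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  eps <- cfg$epoch_s
  n <- round(cfg$hours * 3600 / eps)
  sched <- cfg$schedule
  start_clock <- sched$lights_on_s

  mid <- start_clock + (seq_len(n) - 0.5) * eps
  phase <- phase_of_time(sched, mid)
  r <- rle(phase)
  block_end_idx <- cumsum(r$lengths)
  block_end <- rep(block_end_idx, r$lengths)  # last epoch of current block

  e <- embedded_matrix(cfg)
  ecum <- t(apply(e, 1, cumsum))
  states <- c("WAKE", "NREM", "REM")
  occ0 <- stationary_occupancy(cfg, adjust_brief_awakenings = FALSE)
  s <- sample(3, 1, prob = pmax(occ0$per_phase[, phase[1]], 0))
  labels <- integer(n)
  t <- 1L
  # Uniform draws are pre-allocated in per-state substreams and consumed by
  # visit index (k-th dwell of state s uses u_dwell[s, k]); dwells use the
  # inverse-CDF geometric transform. Within one run the draws are iid, so
  # the generated law is untouched, but two configurations simulated from
  # the same seed share draws bout for bout: common random numbers, which
  # stabilises between-genotype contrasts at fixed cohort size.
  cap <- n + 2L
  u_dwell <- matrix(runif(3L * cap), nrow = 3)
  u_trans <- matrix(runif(3L * cap), nrow = 3)
  k_d <- c(1L, 1L, 1L); k_t <- c(1L, 1L, 1L)
  while (t <= n) {
    m <- cfg$mean_dwell_s[s, phase[t]]
    h <- if (is.finite(m)) min(eps / m, 1) else 0
    u <- u_dwell[s, k_d[s]]; k_d[s] <- k_d[s] + 1L
    dwell <- if (h <= 0) Inf
             else 1 + floor(log(u) / log1p(-min(h, 1 - 1e-16)))
    stop_at <- block_end[t]
    if (t + dwell - 1 >= stop_at + 1 || !is.finite(dwell)) {
      labels[t:stop_at] <- s           # truncated at phase boundary: stay
      t <- stop_at + 1L
    } else {
      labels[t:(t + dwell - 1)] <- s
      t <- t + as.integer(dwell)
      v <- u_trans[s, k_t[s]]; k_t[s] <- k_t[s] + 1L
      s <- which(v <= ecum[s, ])[1]
    }
  }
  lab <- states[labels]
  lab <- insert_brief_awakenings(lab, cfg)
  hypnogram(lab, epoch_s = eps, start_clock_s = start_clock,
            schedule = sched, subject_id = subject_id, group_tag = group_tag)
}

insert_brief_awakenings <- function(lab, cfg) {
  rate <- cfg$brief_awakening_rate_per_h
  if (rate <= 0) return(lab)
  n <- length(lab)
  nrem_h <- sum(lab == "NREM") * cfg$epoch_s / 3600
  k <- rpois(1, rate * nrem_h)
  if (k == 0) return(lab)
  cand <- which(lab == "NREM")
  starts <- sample(cand, min(k, length(cand)))
  lens <- sample.int(4, length(starts), replace = TRUE)
  for (i in seq_along(starts)) {
    s0 <- starts[i]; e0 <- s0 + lens[i] - 1L
    if (s0 <= 1 || e0 >= n) next
    if (!all(lab[s0:e0] == "NREM")) next
    if (!(lab[s0 - 1] %in% SLEEP_STATES && lab[e0 + 1] %in% SLEEP_STATES)) next
    lab[s0:e0] <- "WAKE"
  }
  lab
}

#' Theoretical and empirical per-epoch transition matrices
#'
#' `epoch_transition_matrix()` gives the per-epoch Markov matrix implied by a
#' configuration for one phase (`P[i,i] = 1 - h_i`,
#' `P[i,j] = h_i * E[i,j]` with hazard `h_i = epoch_s / mean_dwell`).
#' `estimate_transition_matrix()` is its maximum-likelihood estimate from a
#' hypnogram: per-phase counts of consecutive-epoch transitions (pairs
#' spanning a phase boundary, or involving ARTIFACT, are dropped).
#'
#' @param cfg A [sim_config()].
#' @param phase `"LIGHT"` or `"DARK"`.
#' @return A 3x3 matrix (`epoch_transition_matrix`), or for
#'   `estimate_transition_matrix` a list per phase with `counts`, `probs`,
#'   and row totals `n`.
#' @export
epoch_transition_matrix <- function(cfg, phase = c("LIGHT", "DARK")) {
  phase <- match.arg(phase)
  e <- embedded_matrix(cfg)
  m <- cfg$mean_dwell_s[, phase]
  h <- ifelse(is.finite(m), pmin(cfg$epoch_s / m, 1), 0)
  p <- h * e
  diag(p) <- 1 - h
  dimnames(p) <- dimnames(e)
  p
}

#' @rdname epoch_transition_matrix
#' @param hyp A [hypnogram()].
#' @export
estimate_transition_matrix <- function(hyp) {
  lab <- as.character(hyp$labels)
  n <- length(lab)
  ph <- phase_of_epoch(hyp)
  from <- lab[-n]; to <- lab[-1]
  same <- ph[-n] == ph[-1] & from != "ARTIFACT" & to != "ARTIFACT"
  states <- c("WAKE", "NREM", "REM")
  out <- lapply(c(LIGHT = "LIGHT", DARK = "DARK"), function(p) {
    sel <- same & ph[-n] == p
    counts <- table(factor(from[sel], states), factor(to[sel], states))
    nrow_ <- rowSums(counts)
    probs <- sweep(counts, 1, pmax(nrow_, 1), "/")
    list(counts = unclass(counts), probs = unclass(probs), n = nrow_)
  })
  out
}
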