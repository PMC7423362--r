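#' Per-subject sleep-architecture metrics
#'
#' Runs the standard 24-h analysis battery on one hypnogram and returns a
#' one-row data frame: time in state, the REM-to-total-sleep and
#' NREM-per-wake ratios, episode-level transition counts, the NREM-to-REM
#' termination percentage, brief-awakening count, and wake-episode
#' statistics per phase.
#'
#' @param hyp A [hypnogram()].
#' @return A one-row data frame.
#' @export
subject_metrics <- function(hyp) {
  tis <- time_in_state(hyp)
  tr <- transition_summary(hyp)
  ws <- wake_episode_stats(hyp)
  data.frame(
    subject_id = hyp$subject_id,
    group = hyp$group_tag,
    wake_h = unname(tis$total_h["WAKE"]),
    nrem_h = unname(tis$total_h["NREM"]),
    rem_h = unname(tis$total_h["REM"]),
    artifact_h = unname(tis$total_h["ARTIFACT"]),
    rem_fraction_of_sleep = tis$rem_fraction_of_sleep,
    nrem_per_wake = tis$nrem_per_wake,
    n_wake_to_nrem = tr$n_wake_to_nrem,
    n_nrem_to_rem = tr$n_nrem_to_rem,
    n_nrem_episodes = tr$n_nrem_episodes,
    pct_nrem_terminating_in_rem = tr$pct_nrem_terminating_in_rem,
    n_brief_awakenings = tr$n_brief_awakenings,
    n_wake_episodes = ws$count,
    wake_mean_light_s = unname(ws$mean_duration_s["LIGHT"]),
    wake_mean_dark_s = unname(ws$mean_duration_s["DARK"]),
    stringsAsFactors = FALSE
  )
}

#' Two-group comparison of a metric
#'
#' Welch two-sample t-test with the descriptive statistics figure panels
#' report: per-group mean and SEM, difference of means, and percent change
#' `100 * (mean_a - mean_b) / mean_a`.
#'
#' @param a,b Numeric vectors of per-subject values (length at least 2).
#' @param metric Metric name carried into the output.
#' @param group_names Length-2 character, default `c("A", "B")`.
#' @return A one-row data frame of class `group_comparison`: means, SEMs,
#'   ns, `difference`, `pct_change`, `t_stat`, `df`, `p_value` (`NA` with a
#'   `degenerate` flag when both groups have zero variance).
#' @export
compare_groups <- function(a, b, metric = "metric",
                           group_names = c("A", "B")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  sem <- function(x) sd(x) / sqrt(length(x))
  degenerate <- var(a) == 0 && var(b) == 0
  tt <- if (!degenerate) t.test(a, b, var.equal = FALSE) else NULL
  out <- data.frame(
    metric = metric,
    group_a = group_names[1], group_b = group_names[2],
    mean_a = mean(a), sem_a = sem(a), n_a = length(a),
    mean_b = mean(b), sem_b = sem(b), n_b = length(b),
    difference = mean(a) - mean(b),
    pct_change = if (mean(a) != 0) 100 * (mean(a) - mean(b)) / mean(a)
                 else NA_real_,
    t_stat = if (degenerate) NA_real_ else unname(tt$statistic),
    df = if (degenerate) NA_real_ else unname(tt$parameter),
    p_value = if (degenerate) NA_real_ else tt$p.value,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Run the simulate-analyse-compare pipeline
#'
#' Orchestrates cohort simulation (or reading of existing hypnogram CSVs),
#' per-subject metric computation, and group comparison, writing TSV tables
#' and a parameter log to `out_dir`. The configuration is a YAML file (or an
#' equivalent list) of the form:
#'
#' ```yaml
#' groups:
#'   - name: WT
#'     simulate: {preset: WT, n: 8, seed: 1, hours: 24}
#'   - name: RLSS
#'     simulate: {preset: RLSS, n: 8, seed: 101, hours: 24}
#' ```
#'
#' A group may instead list `hypnograms: [path1.csv, ...]` (with optional
#' `epoch_s`). With two or more groups, every numeric metric is compared
#' between the first group and each other group (Welch t-test, no
#' multiple-testing correction; the metric count is logged).
#'
#' @param config Path to a YAML config or a list with the same structure.
#' @param out_dir Output directory (created if needed); default a tempdir.
#' @return Invisibly, a list with `metrics` (data frame), `comparisons`
#'   (data frame or `NULL`), `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("vigilarch_report_")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$groups) || !length(config$groups)) {
    stop("config must define at least one group")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  metrics <- list()
  for (g in config$groups) {
    if (!is.null(g$simulate)) {
      s <- g$simulate
      coh <- simulate_cohort(s$preset %||% g$name, n = s$n %||% 8,
                             base_seed = s$seed %||% 1,
                             hours = s$hours %||% 24)
      hyps <- coh$hypnograms
      for (h in seq_along(hyps)) hyps[[h]]$group_tag <- g$name
    } else if (!is.null(g$hypnograms)) {
      g$hypnograms <- unlist(g$hypnograms)
      missing_files <- g$hypnograms[!file.exists(g$hypnograms)]
      if (length(missing_files)) {
        stop("missing input file(s): ", paste(missing_files, collapse = ", "))
      }
      hyps <- lapply(g$hypnograms, read_hypnogram,
                     epoch_s = g$epoch_s %||% 4, group_tag = g$name)
    } else {
      stop("group '", g$name, "' needs a `simulate` block or `hypnograms`")
    }
    metrics[[g$name]] <- do.call(rbind, lapply(hyps, subject_metrics))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  comparisons <- NULL
  grp_names <- vapply(config$groups, function(g) g$name, "")
  if (length(grp_names) >= 2) {
    num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
    comparisons <- do.call(rbind, lapply(grp_names[-1], function(gb) {
      do.call(rbind, lapply(num_cols, function(m) {
        compare_groups(metrics[[m]][metrics$group == grp_names[1]],
                       metrics[[m]][metrics$group == gb],
                       metric = m, group_names = c(grp_names[1], gb))
      }))
    }))
    write.table(comparisons, file.path(out_dir, "comparisons.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(
    list(package = "vigilarch",
         version = as.character(utils::packageVersion("vigilarch")),
         config = config,
         n_metrics_tested = if (is.null(comparisons)) 0L
                            else length(unique(comparisons$metric))),
    file.path(out_dir, "log.yaml")
  )
  invisible(list(metrics = metrics, comparisons = comparisons,
                 out_dir = out_dir))
}
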