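#' Simulate a cohort of animals
#'
#' Generates `n` independent 24-h (by default) hypnograms from a genotype
#' preset, with deterministic per-animal seeds `base_seed + index - 1`, and
#' optionally the coupled signal recordings and mobility traces. Identical
#' `base_seed` reproduces the cohort bit for bit.
#'
#' @param preset A [genotype_preset()] or preset name (`"WT"`, `"RLSS"`).
#' @param n Number of animals.
#' @param base_seed Integer base seed.
#' @param hours Hours per recording, default 24.
#' @param signals,tracking Also synthesise EEG/EMG and mobility (default
#'   `FALSE`; signals are large).
#' @param dir Optional output directory: writes per-animal hypnogram CSVs
#'   (`<id>.csv`), tracking CSVs, EDFs, and a `manifest.yaml`.
#' @param signal_cfg A [signal_synth_config()] used when `signals = TRUE`.
#' @return A list of class `sim_cohort`: `hypnograms` (list), `manifest`
#'   (data frame `subject_id`, `group`, `seed`), and optional `recordings`,
#'   `traces`.
#' @export
simulate_cohort <- function(preset, n = 8, base_seed = 1, hours = 24,
                            signals = FALSE, tracking = FALSE, dir = NULL,
                            signal_cfg = signal_synth_config()) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(n >= 1)
  cfg <- calibrate_preset(preset, hours = hours)
  seeds <- base_seed + seq_len(n) - 1
  ids <- sprintf("%s_%02d", tolower(preset$name), seq_len(n))
  hyps <- lapply(seq_len(n), function(i) {
    simulate_hypnogram(cfg, seed = seeds[i], subject_id = ids[i],
                       group_tag = preset$name)
  })
  out <- list(
    hypnograms = hyps,
    manifest = data.frame(subject_id = ids, group = preset$name,
                          seed = seeds, stringsAsFactors = FALSE),
    config = cfg
  )
  if (signals) {
    out$recordings <- lapply(seq_len(n), function(i) {
      synthesize_signals(hyps[[i]], signal_cfg, seed = seeds[i] + 500000L)
    })
  }
  if (tracking) {
    out$traces <- lapply(seq_len(n), function(i) {
      synthesize_tracking(hyps[[i]], seed = seeds[i] + 900000L)
    })
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(n)
    for (i in seq_len(n)) {
      files[i] <- file.path(dir, paste0(ids[i], ".csv"))
      write_hypnogram(hyps[[i]], files[i])
      if (signals) write_edf(out$recordings[[i]],
                             file.path(dir, paste0(ids[i], ".edf")))
      if (tracking) write_mobility(out$traces[[i]],
                                   file.path(dir, paste0(ids[i], "_mobility.csv")))
    }
    yaml::write_yaml(
      list(group = preset$name, n = n, base_seed = base_seed, hours = hours,
           subjects = ids, hypnogram_files = basename(files)),
      file.path(dir, "manifest.yaml")
    )
  }
  class(out) <- "sim_cohort"
  out
}
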