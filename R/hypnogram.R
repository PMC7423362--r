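#' Construct a hypnogram
#'
#' A hypnogram is the epoch-resolution sequence of vigilance-state labels
#' (`WAKE`, `NREM`, `REM`, `ARTIFACT`) on which all architecture statistics
#' are computed. Epochs are half-open intervals `[t, t + epoch_s)` counted
#' from `start_clock_s`.
#'
#' @param labels Character vector (long names or the tokens `W,N,R,A`) or a
#'   factor of vigilance labels, one per epoch.
#' @param epoch_s Epoch length in seconds (default 4).
#' @param start_clock_s Clock time of the first epoch start, seconds of day.
#' @param schedule A [light_schedule()].
#' @param subject_id,group_tag Optional identifiers (e.g. `"WT"` / `"rlss"`).
#' @return An object of class `hypnogram`: a list with `labels` (factor with
#'   levels WAKE/NREM/REM/ARTIFACT), `epoch_s`, `start_clock_s`, `schedule`,
#'   `subject_id`, `group_tag`.
#' @examples
#' h <- hypnogram(c("W", "N", "N", "R"), epoch_s = 4)
#' n_epochs(h)
#' duration_s(h)
#' @export
hypnogram <- function(labels, epoch_s = 4, start_clock_s = 0,
                      schedule = light_schedule(), subject_id = "subject",
                      group_tag = "") {
  stopifnot(epoch_s > 0, length(labels) >= 1)
  labels <- as_vigilance(labels)
  structure(
    list(
      labels = labels, epoch_s = epoch_s, start_clock_s = start_clock_s,
      schedule = schedule, subject_id = subject_id, group_tag = group_tag
    ),
    class = "hypnogram"
  )
}

# normalise label input to a factor on the canonical levels
as_vigilance <- function(x) {
  x <- as.character(x)
  short <- x %in% names(LABEL_TOKENS)
  x[short] <- LABEL_TOKENS[x[short]]
  bad <- !(x %in% VIGILANCE_LEVELS)
  if (any(bad)) {
    stop("unknown vigilance label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (first at position ", which(bad)[1], ")")
  }
  factor(x, levels = VIGILANCE_LEVELS)
}

#' @rdname hypnogram
#' @param hyp A hypnogram.
#' @export
n_epochs <- function(hyp) length(hyp$labels)

#' @rdname hypnogram
#' @export
duration_s <- function(hyp) n_epochs(hyp) * hyp$epoch_s

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<hypnogram> %s%s: %d epochs x %g s (%.2f h)\n",
    x$subject_id, if (nzchar(x$group_tag)) paste0(" [", x$group_tag, "]") else "",
    n_epochs(x), x$epoch_s, duration_s(x) / 3600
  ))
  cat("  ", paste(sprintf("%s %.2f h", names(tab), tab * x$epoch_s / 3600),
                  collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Read a hypnogram from CSV
#'
#' Expects a header row and columns `epoch_start_s,label`, one row per epoch,
#' labels in `{W,N,R,A}` (long names accepted). Epochs must tile the record
#' contiguously: row `k` must start at `(k-1) * epoch_s`.
#'
#' @param path CSV file path.
#' @param epoch_s Epoch length, seconds. If `NULL`, inferred from the spacing
#'   of the first two rows.
#' @param schedule A [light_schedule()].
#' @inheritParams hypnogram
#' @return A [hypnogram()].
#' @seealso [write_hypnogram()]
#' @export
read_hypnogram <- function(path, epoch_s = NULL, schedule = light_schedule(),
                           start_clock_s = 0, subject_id = NULL,
                           group_tag = "") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_start_s", "label")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_start_s,label: ", path)
  }
  if (nrow(df) < 1) stop("empty hypnogram CSV: ", path)
  if (is.null(epoch_s)) {
    if (nrow(df) < 2) stop("cannot infer epoch length from a single row")
    epoch_s <- df$epoch_start_s[2] - df$epoch_start_s[1]
  }
  expected <- (seq_len(nrow(df)) - 1) * epoch_s
  off <- which(abs(df$epoch_start_s - expected) > 1e-9)
  if (length(off)) {
    stop(sprintf(
      "non-contiguous epochs: row %d starts at %g s, expected %g s",
      off[1], df$epoch_start_s[off[1]], expected[off[1]]
    ))
  }
  labels <- tryCatch(as_vigilance(df$label), error = function(e) {
    stop("while parsing ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  hypnogram(labels, epoch_s = epoch_s, start_clock_s = start_clock_s,
            schedule = schedule,
            subject_id = subject_id %||% sub("\\.csv$", "", basename(path)),
            group_tag = group_tag)
}

#' Write a hypnogram to CSV
#'
#' Inverse of [read_hypnogram()]; the round trip is lossless for the label
#' sequence and epoch grid.
#'
#' @param hyp A [hypnogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  tok <- names(LABEL_TOKENS)[match(as.character(hyp$labels), LABEL_TOKENS)]
  df <- data.frame(
    epoch_start_s = (seq_len(n_epochs(hyp)) - 1) * hyp$epoch_s,
    label = tok
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
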