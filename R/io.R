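#' Write a synthetic cohort to disk
#'
#' Serialises every modality in plain-text formats: one wide CSV per
#' recording (`time_ms` plus one column per channel) with its events as a
#' JSON list of `{label, onset_ms}`, one pupil CSV per trace (`time_ms`,
#' `left_mm`, `right_mm`, `validity`), a single behaviour CSV, and a JSON
#' manifest mapping participant/condition to file paths and ground-truth
#' values.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  manifest <- list(seed = spec$seed, n_participants = spec$n_participants,
                   conditions = spec$conditions, recordings = list())
  for (cond in spec$conditions) {
    for (p in seq_len(spec$n_participants)) {
      key <- sprintf("p%02d_%s", p, cond)
      entry <- list(participant = p, condition = cond)
      if (!is.null(cohort$signals)) {
        rec <- cohort$signals[[cond]][[p]]
        sig_path <- file.path(dir, paste0(key, "_signals.csv"))
        ev_path <- file.path(dir, paste0(key, "_events.json"))
        write.csv(cbind(data.frame(time_ms = rec$time_ms),
                        as.data.frame(t(rec$samples))),
                  sig_path, row.names = FALSE)
        jsonlite::write_json(rec$events, ev_path, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA)
        entry$signals <- basename(sig_path)
        entry$events <- basename(ev_path)
      }
      if (!is.null(cohort$pupil)) {
        tr <- cohort$pupil[[cond]][[p]]
        pup_path <- file.path(dir, paste0(key, "_pupil.csv"))
        write.csv(as.data.frame(tr), pup_path, row.names = FALSE)
        entry$pupil <- basename(pup_path)
        entry$pupil_truth <- list(
          true_change = attr(tr, "true_change"),
          outlier_idx = attr(tr, "outlier_idx"),
          blink_idx = attr(tr, "blink_idx"))
      }
      tru <- cohort$truth[cohort$truth$participant == p &
                            cohort$truth$condition == cond, ]
      entry$truth <- as.list(tru[c("faa", "paa", "pupil_change")])
      manifest$recordings[[key]] <- entry
    }
  }
  beh_path <- file.path(dir, "behavior.csv")
  write.csv(cohort$behavior, beh_path, row.names = FALSE)
  manifest$behavior <- basename(beh_path)
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(man_path)
}

#' Read a signal recording from CSV + events JSON
#'
#' Inverse of the signal serialisation in [write_cohort()].
#'
#' @param signals_csv Wide CSV path (`time_ms`, one column per channel).
#' @param events_json JSON path with a list of `{label, onset_ms}`.
#' @param rate Sampling rate in samples/s; inferred from the timestamps
#'   when `NULL`.
#' @return A `signal_recording`.
#' @export
read_signal_csv <- function(signals_csv, events_json, rate = NULL) {
  df <- read.csv(signals_csv, check.names = FALSE)
  if (names(df)[1] != "time_ms")
    stop("first column must be `time_ms`", call. = FALSE)
  events <- as.data.frame(jsonlite::fromJSON(events_json))
  if (is.unsorted(events$onset_ms))
    stop("events must be ordered in time", call. = FALSE)
  t_ms <- df$time_ms
  if (is.null(rate)) rate <- 1000 / stats::median(diff(t_ms))
  structure(list(
    channels = names(df)[-1],
    rate = rate,
    samples = t(as.matrix(df[-1])),
    time_ms = t_ms,
    events = events[c("label", "onset_ms")],
    participant = NA, condition = NA
  ), class = "signal_recording")
}

#' Read a pupil trace from CSV
#'
#' @param path CSV with columns `time_ms`, `left_mm`, `right_mm`,
#'   `validity` (one of `valid`, `blink`, `missing`).
#' @return A `pupil_trace` data frame.
#' @export
read_pupil_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "left_mm", "right_mm", "validity")
  if (!all(need %in% names(df)))
    stop("pupil CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$validity %in% c("valid", "blink", "missing")))
    stop("validity must be one of valid/blink/missing", call. = FALSE)
  if (is.unsorted(df$time_ms, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  class(df) <- c("pupil_trace", "data.frame")
  df
}
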