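#' Merge the two eyes of a pupil trace
#'
#' Per-sample mean of the valid eyes. A sample contributes one eye when the
#' other is lost (unilateral `NA`); it becomes missing only when both eyes
#' are non-valid (the `validity` flag is not `"valid"`, or both diameters
#' are `NA`).
#'
#' @param trace A `pupil_trace` data frame with columns `time_ms`,
#'   `left_mm`, `right_mm`, `validity`.
#' @return Numeric mm series with `NA` at missing samples.
#' @export
#' @examples
#' tr <- data.frame(time_ms = 0:2 * 10, left_mm = c(3.0, NA, NA),
#'                  right_mm = c(3.2, 3.2, NA),
#'                  validity = c("valid", "valid", "blink"))
#' merge_eyes(tr)  # 3.1, 3.2, NA
merge_eyes <- function(trace) {
  need <- c("time_ms", "left_mm", "right_mm", "validity")
  if (!all(need %in% names(trace)))
    stop("trace must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- trace$validity != "valid"
  left <- ifelse(bad, NA_real_, trace$left_mm)
  right <- ifelse(bad, NA_real_, trace$right_mm)
  merged <- rowMeans(cbind(left, right), na.rm = TRUE)
  merged[is.na(left) & is.na(right)] <- NA_real_
  if (all(is.na(merged)))
    stop("both eyes are entirely non-valid", call. = FALSE)
  merged
}

#' Split a merged pupil series into baseline/task half epochs
#'
#' The baseline and task windows are each split at their midpoint into an
#' initial and a final half (an odd sample count puts the extra sample in
#' the initial half), giving four epochs that are preprocessed separately.
#'
#' @param merged Merged mm series (see [merge_eyes()]).
#' @param time_ms Sample timestamps in ms relative to script onset.
#' @param baseline_window,task_window `c(start, end)` ms intervals;
#'   samples with `start <= t < end` are included.
#' @return List of four `pupil_epoch` objects (`baseline`/`task` x
#'   `initial`/`final`), each with `samples`, `segment`, `half`.
#' @export
split_pupil_epochs <- function(merged, time_ms, baseline_window,
                               task_window) {
  if (length(merged) != length(time_ms))
    stop("`merged` and `time_ms` lengths differ", call. = FALSE)
  ep <- pupil_epoch_indices(time_ms, baseline_window, task_window)
  mk <- function(segment, half) {
    idx <- ep[[segment]][[half]]
    if (!length(idx))
      stop("window too short to split into halves", call. = FALSE)
    structure(list(samples = merged[idx], segment = segment, half = half),
              class = "pupil_epoch")
  }
  list(baseline_initial = mk("baseline", "initial"),
       baseline_final   = mk("baseline", "final"),
       task_initial     = mk("task", "initial"),
       task_final       = mk("task", "final"))
}

#' Reject within-epoch z-score outliers
#'
#' Standardises the epoch by the mean and SD of its own valid samples and
#' marks samples with `|z| > threshold_sd` as missing. The statistics are
#' computed once, before any rejection (no iteration); a constant epoch
#' (zero SD) yields no rejections.
#'
#' @param epoch A `pupil_epoch`.
#' @param threshold_sd Rejection threshold in z units (default 3).
#' @return The epoch with outliers set to `NA` and a `z` element recording
#'   the standardised values used.
#' @export
reject_outliers <- function(epoch, threshold_sd = 3) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  x <- epoch$samples
  valid <- !is.na(x)
  if (sum(valid) < 2)
    stop("epoch needs at least 2 valid samples", call. = FALSE)
  m <- mean(x[valid])
  s <- sd(x[valid])
  z <- rep(NA_real_, length(x))
  if (s > 0) {
    z[valid] <- (x[valid] - m) / s
    x[!is.na(z) & abs(z) > threshold_sd] <- NA_real_
  } else {
    z[valid] <- 0
  }
  epoch$samples <- x
  epoch$z <- z
  epoch
}

#' Reconstruct missing pupil samples by linear interpolation
#'
#' Replaces every missing run (blinks, rejected outliers, other gaps) with
#' the straight line between the nearest valid neighbours; leading and
#' trailing missing runs, where interpolation is undefined, take the
#' nearest valid value.
#'
#' @param epoch A `pupil_epoch`.
#' @return The epoch with no missing samples and `mean_mm` set.
#' @export
#' @examples
#' ep <- structure(list(samples = c(2, NA, 4), segment = "task",
#'                      half = "initial"), class = "pupil_epoch")
#' interpolate_missing(ep)$samples  # 2, 3, 4
interpolate_missing <- function(epoch) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  x <- epoch$samples
  valid <- which(!is.na(x))
  if (!length(valid))
    stop("epoch has no valid samples to interpolate from", call. = FALSE)
  if (length(valid) == 1) {
    x[] <- x[valid]
  } else if (length(valid) < length(x)) {
    x <- approx(valid, x[valid], xout = seq_along(x), rule = 2)$y
  }
  epoch$samples <- x
  epoch$mean_mm <- mean(x)
  epoch
}

#' Baseline-relative pupil change from four reconstructed epochs
#'
#' The baseline mean is the unweighted mean of the two baseline epoch
#' means; likewise for the task. The change is `task_mean -
#' baseline_mean`, in mm: positive values indicate dilation relative to
#' baseline, negative values constriction.
#'
#' @param epochs List of four reconstructed `pupil_epoch` objects as
#'   returned by [split_pupil_epochs()] after [interpolate_missing()].
#' @return List with `baseline_mean`, `task_mean`, `change`.
#' @export
pupil_change <- function(epochs) {
  stopifnot(length(epochs) == 4)
  m <- vapply(epochs, function(e) {
    if (anyNA(e$samples))
      stop("epochs must be reconstructed before averaging", call. = FALSE)
    mean(e$samples)
  }, 0)
  segs <- vapply(epochs, function(e) e$segment, "")
  baseline_mean <- mean(m[segs == "baseline"])
  task_mean <- mean(m[segs == "task"])
  list(baseline_mean = baseline_mean, task_mean = task_mean,
       change = task_mean - baseline_mean)
}

#' Full pupillometry stage for one trace
#'
#' Merges the eyes, splits baseline and task into half epochs, rejects
#' within-epoch 3-SD outliers, reconstructs missing samples by linear
#' interpolation, and computes the baseline-relative mean diameter change.
#'
#' @param trace A `pupil_trace` data frame.
#' @param baseline_window Baseline ms interval (default `c(-5000, -200)`).
#' @param task_window Task ms interval; default from 0 to just past the
#'   last sample.
#' @param outlier_sd Outlier threshold in z units (default 3).
#' @param scale `"mm"` (default) computes the means on the millimetre
#'   scale; `"z"` re-standardises each reconstructed epoch by its own mean
#'   and SD first, so the change is expressed in within-epoch z units.
#'   The mm scale is the supported reading; the z alternative is exposed
#'   for sensitivity checks only.
#' @return One-row data frame: `participant`, `condition`,
#'   `baseline_mean`, `task_mean`, `change`.
#' @export
process_pupil <- function(trace, baseline_window = c(-5000, -200),
                          task_window = NULL, outlier_sd = 3,
                          scale = c("mm", "z")) {
  scale <- match.arg(scale)
  if (is.null(task_window)) {
    dt <- if (nrow(trace) > 1) diff(trace$time_ms[1:2]) else 1
    task_window <- c(0, max(trace$time_ms) + dt)
  }
  merged <- merge_eyes(trace)
  epochs <- split_pupil_epochs(merged, trace$time_ms, baseline_window,
                               task_window)
  epochs <- lapply(epochs, function(e)
    interpolate_missing(reject_outliers(e, outlier_sd)))
  if (scale == "z") {
    epochs <- lapply(epochs, function(e) {
      s <- sd(e$samples)
      e$samples <- if (s > 0) (e$samples - mean(e$samples)) / s
                   else e$samples * 0
      e
    })
  }
  ch <- pupil_change(epochs)
  data.frame(
    participant = if (is.null(attr(trace, "participant"))) NA
                  else attr(trace, "participant"),
    condition = if (is.null(attr(trace, "condition"))) NA
                else attr(trace, "condition"),
    baseline_mean = ch$baseline_mean, task_mean = ch$task_mean,
    change = ch$change, stringsAsFactors = FALSE)
}
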