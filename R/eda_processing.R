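#' Construct an electrodermal-activity time series
#'
#' One annotator's EDA recording: strictly increasing timestamps (seconds)
#' with nonnegative values in microsiemens, plus explicit experiment start
#' and end markers (the markers were set manually in the lab protocol and
#' are therefore inputs, not inferred).
#'
#' @param annotator_id identifier.
#' @param time_s numeric vector of sample timestamps in seconds.
#' @param eda_us numeric vector of EDA values in microsiemens.
#' @param start,end experiment start/end timestamps; default to the first
#'   and last sample.
#' @return object of class `eda_timeseries`.
#' @export
eda_timeseries <- function(annotator_id, time_s, eda_us,
                           start = NULL, end = NULL) {
  if (length(time_s) != length(eda_us) || length(time_s) == 0) {
    stop("time_s and eda_us must be equal-length, non-empty", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(eda_us < 0)) stop("EDA values must be >= 0", call. = FALSE)
  structure(
    list(annotator_id = as.character(annotator_id),
         time_s = as.numeric(time_s), eda_us = as.numeric(eda_us),
         start = if (is.null(start)) time_s[1] else as.numeric(start),
         end = if (is.null(end)) time_s[length(time_s)] else as.numeric(end)),
    class = "eda_timeseries"
  )
}

#' @export
print.eda_timeseries <- function(x, ...) {
  cat(sprintf("<eda_timeseries> annotator %s: %d samples over [%.1f, %.1f] s\n",
              x$annotator_id, length(x$time_s), x$start, x$end))
  invisible(x)
}

#' Read per-annotator EDA recordings
#'
#' Reads a CSV with columns `annotator_id`, `time_s`, `eda_us` (long
#' format, one row per sample) and splits it into one time series per
#' annotator.
#'
#' @param path CSV path.
#' @return named list of [eda_timeseries()] objects.
#' @export
read_eda <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("annotator_id", "time_s", "eda_us")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    stop("EDA table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  by_ann <- split(raw, raw$annotator_id)
  lapply(by_ann, function(d) {
    d <- d[order(d$time_s), ]
    eda_timeseries(d$annotator_id[1], d$time_s, d$eda_us)
  })
}

#' Write EDA series to a long-format CSV
#'
#' @param series list of [eda_timeseries()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eda <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(annotator_id = s$annotator_id, time_s = s$time_s,
               eda_us = s$eda_us, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Segment an EDA series by recorded task durations
#'
#' Cuts one annotator's recording into consecutive half-open windows
#' `[t_i, t_i + d_i)` starting at the experiment start, one window per
#' annotation task in presentation order, so each sample belongs to
#' exactly one segment. The durations may not overrun the recording
#' (beyond one sample period of tolerance).
#'
#' @param series an [eda_timeseries()].
#' @param durations numeric vector of task durations in seconds, in
#'   presentation order.
#' @param tolerance_s allowed overrun beyond the experiment end, default
#'   the median sampling period.
#' @return list of segments, each a list with `annotator_id`,
#'   `triplet_id` (ordinal), `start`, `end`, `time_s`, `eda_us`.
#' @export
segment_series <- function(series, durations, tolerance_s = NULL) {
  stopifnot(inherits(series, "eda_timeseries"))
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  if (is.null(tolerance_s)) {
    tolerance_s <- if (length(series$time_s) > 1) {
      stats::median(diff(series$time_s))
    } else 0
  }
  total <- sum(durations)
  avail <- series$end - series$start
  if (total > avail + tolerance_s) {
    stop(sprintf("durations overrun the recording by %.2f s",
                 total - avail), call. = FALSE)
  }
  starts <- series$start + c(0, cumsum(durations))[seq_along(durations)]
  ends <- starts + durations
  lapply(seq_along(durations), function(i) {
    sel <- series$time_s >= starts[i] & series$time_s < ends[i]
    # the last sample before the window start is the value "held" at the
    # window boundary; kept so offset readings can look back to it
    before <- which(series$time_s < starts[i])
    list(annotator_id = series$annotator_id, triplet_id = i,
         start = starts[i], end = ends[i],
         time_s = series$time_s[sel], eda_us = series$eda_us[sel],
         pre_time = if (length(before)) series$time_s[max(before)] else NULL,
         pre_value = if (length(before)) series$eda_us[max(before)] else NULL)
  })
}

#' Mean EDA of a segment at 10-second sampling
#'
#' Reads the series at offsets 0, 10, 20, ... seconds from the segment
#' start (taking, at each offset, the last recorded sample at or before
#' it — sample-and-hold) and returns the mean of those readings. A segment
#' shorter than 10 s yields a single reading at offset 0.
#'
#' @param segment one segment from [segment_series()].
#' @param interval_s sampling interval in seconds (default 10).
#' @return mean EDA in microsiemens.
#' @export
eda_mean <- function(segment, interval_s = 10) {
  if (length(segment$time_s) == 0 && is.null(segment$pre_value)) {
    stop("empty segment: no EDA samples in window", call. = FALSE)
  }
  duration <- segment$end - segment$start
  offsets <- seq(0, max(duration - 1e-9, 0), by = interval_s)
  if (length(offsets) == 0) offsets <- 0
  readings <- vapply(offsets, function(o) {
    at <- segment$start + o
    idx <- which(segment$time_s <= at)
    if (length(idx) > 0) return(segment$eda_us[max(idx)])
    # no in-window sample at or before the offset: the recording holds
    # the last sample before the window (or, failing that, the next one)
    if (!is.null(segment$pre_value)) segment$pre_value
    else segment$eda_us[1]
  }, numeric(1))
  mean(readings)
}

#' Per-task mean EDA for one annotator
#'
#' Convenience wrapper: segments the series by the task durations and
#' computes the 10-second-sampled mean per segment.
#'
#' @inheritParams segment_series
#' @param interval_s sampling interval passed to [eda_mean()].
#' @return numeric vector, one mean per task.
#' @export
eda_means <- function(series, durations, interval_s = 10) {
  vapply(segment_series(series, durations), eda_mean, numeric(1),
         interval_s = interval_s)
}
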