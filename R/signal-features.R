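#' Per-axis mean absolute consecutive difference
#'
#' The smartwatch's per-minute activity statistic for one accelerometer axis:
#' the mean of the 119 absolute differences between consecutive samples of a
#' 120-sample (2 Hz, one minute) window. Absolute differences are used so the
#' statistic measures the average magnitude of acceleration change rather than
#' the net drift over the minute (a signed sum telescopes to
#' `(x[120] - x[1]) / 119`, which is degenerate for periodic movement).
#'
#' @param axis_samples Numeric vector of exactly 120 finite acceleration
#'   values for one axis (units are arbitrary but must be consistent).
#' @return A single non-negative number.
#' @export
#' @examples
#' axis_mean_abs_diff(rep(1, 120))              # constant signal -> 0
#' axis_mean_abs_diff(seq(0, by = 0.1, length.out = 120)) # ramp -> 0.1
axis_mean_abs_diff <- function(axis_samples) {
  if (length(axis_samples) != samples_per_minute()) {
    stop("`axis_samples` must contain exactly ", samples_per_minute(),
         " values (got ", length(axis_samples), ").", call. = FALSE)
  }
  if (!is.numeric(axis_samples) || !all(is.finite(axis_samples))) {
    stop("`axis_samples` must be finite numeric values.", call. = FALSE)
  }
  mean(abs(diff(axis_samples)))
}

# 2 Hz for 60 s
samples_per_minute <- function() 120L

validate_window <- function(window) {
  if (!is.data.frame(window)) {
    stop("`window` must be a data frame with columns t, ax, ay, az.",
         call. = FALSE)
  }
  missing <- setdiff(c("t", "ax", "ay", "az"), names(window))
  if (length(missing) > 0) {
    stop("`window` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(window) != samples_per_minute()) {
    stop("`window` must have exactly ", samples_per_minute(),
         " rows (got ", nrow(window), "); partial minutes are rejected, not padded.",
         call. = FALSE)
  }
  if (is.unsorted(window$t, strictly = TRUE)) {
    stop("`window$t` must be strictly increasing.", call. = FALSE)
  }
  vals <- c(window$ax, window$ay, window$az)
  if (!all(is.finite(vals))) {
    stop("Accelerometer samples must be finite.", call. = FALSE)
  }
  invisible(window)
}

#' Per-minute average of PA and dominant axis
#'
#' Computes the watch's "average of PA" feature: the per-axis mean absolute
#' consecutive difference is computed for x, y and z, and the maximum of the
#' three is returned together with the axis achieving it (the dominant axis).
#' Ties are broken by the fixed priority x > y > z so the result is
#' deterministic.
#'
#' @param window A minute window: data frame with columns `t` (seconds within
#'   the minute, strictly increasing), `ax`, `ay`, `az`; exactly 120 rows.
#' @return A list with elements `pa_avg` (non-negative number) and
#'   `dominant_axis` (one of `"x"`, `"y"`, `"z"`).
#' @export
compute_pa_avg <- function(window) {
  validate_window(window)
  per_axis <- c(
    x = axis_mean_abs_diff(window$ax),
    y = axis_mean_abs_diff(window$ay),
    z = axis_mean_abs_diff(window$az)
  )
  # which.max() already keeps the first maximum, i.e. priority x > y > z
  axis <- names(per_axis)[which.max(per_axis)]
  list(pa_avg = unname(max(per_axis)), dominant_axis = axis)
}

#' Per-minute variance of PA on the dominant axis
#'
#' Computes the watch's "variance of PA" feature: the mean (divisor 119) of
#' the squared deviations of the dominant axis's 119 absolute consecutive
#' differences from `pa_avg`.
#'
#' @inheritParams compute_pa_avg
#' @param pa_avg,dominant_axis The values returned by [compute_pa_avg()] on
#'   the same window.
#' @return A single non-negative number.
#' @export
compute_pa_var <- function(window, pa_avg, dominant_axis) {
  validate_window(window)
  if (!dominant_axis %in% c("x", "y", "z")) {
    stop("`dominant_axis` must be one of \"x\", \"y\", \"z\".", call. = FALSE)
  }
  samples <- window[[paste0("a", dominant_axis)]]
  own <- axis_mean_abs_diff(samples)
  for (ax in setdiff(c("x", "y", "z"), dominant_axis)) {
    other <- axis_mean_abs_diff(window[[paste0("a", ax)]])
    if (other > own) {
      stop("`dominant_axis` (\"", dominant_axis, "\") is not the arg-max axis ",
           "of this window; pass the values returned by compute_pa_avg().",
           call. = FALSE)
    }
  }
  diffs <- abs(diff(samples))
  mean((diffs - pa_avg)^2)
}

#' Count steps in a one-minute accelerometer window
#'
#' A deterministic peak-counting step detector on the vector-magnitude
#' signal: the magnitude is smoothed with a centered moving average, then
#' local maxima exceeding the smoothed signal's median by at least
#' `threshold` and separated by at least `min_spacing` samples are counted.
#' Constant offsets (gravity) do not affect the count because the threshold
#' is relative to the median.
#'
#' @inheritParams compute_pa_avg
#' @param threshold Minimum peak height above the median of the smoothed
#'   magnitude, in signal units. Default 0.15.
#' @param min_spacing Minimum number of samples between counted peaks
#'   (default 2, i.e. 1 s at 2 Hz, capping the detector at 60 steps/min).
#' @param smooth_width Width of the centered moving-average filter in
#'   samples (odd; default 3). Edge samples use the partial window.
#' @return A non-negative integer step count.
#' @export
count_steps <- function(window, threshold = 0.15, min_spacing = 2L,
                        smooth_width = 3L) {
  validate_window(window)
  stopifnot(threshold > 0, min_spacing >= 1, smooth_width >= 1,
            smooth_width %% 2 == 1)
  magnitude <- sqrt(window$ax^2 + window$ay^2 + window$az^2)
  smoothed <- moving_average(magnitude, smooth_width)
  cutoff <- stats::median(smoothed) + threshold
  n <- length(smoothed)
  is_peak <- c(FALSE,
               smoothed[2:(n - 1)] > smoothed[1:(n - 2)] &
                 smoothed[2:(n - 1)] >= smoothed[3:n],
               FALSE) & smoothed > cutoff
  idx <- which(is_peak)
  count <- 0L
  last <- -Inf
  for (i in idx) {
    if (i - last >= min_spacing) {
      count <- count + 1L
      last <- i
    }
  }
  count
}

moving_average <- function(x, width) {
  if (width == 1) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract all per-minute features from one window
#'
#' Composes [compute_pa_avg()], [compute_pa_var()] and [count_steps()] into
#' the watch's per-minute feature record.
#'
#' @inheritParams compute_pa_avg
#' @param step_args Optional named list of overrides passed to
#'   [count_steps()] (`threshold`, `min_spacing`, `smooth_width`).
#' @return A one-row tibble with columns `pa_avg`, `pa_var`, `steps`,
#'   `dominant_axis`.
#' @export
extract_minute_features <- function(window, step_args = list()) {
  avg <- compute_pa_avg(window)
  pa_var <- compute_pa_var(window, avg$pa_avg, avg$dominant_axis)
  steps <- do.call(count_steps, c(list(window), step_args))
  tibble::tibble(
    pa_avg = avg$pa_avg,
    pa_var = pa_var,
    steps = as.integer(steps),
    dominant_axis = avg$dominant_axis
  )
}

#' Extract per-minute features from a raw accelerometer stream
#'
#' Groups a long-format 2 Hz triaxial stream into one-minute windows and
#' extracts the smartwatch features for each. Windows are half-open
#' `[minute_start, minute_start + 60 s)`; partial windows (fewer than 120
#' samples) raise an error rather than being padded.
#'
#' @param accel A data frame with columns `participant_id`, `minute_start`
#'   (anything groupable: timestamp or label), `t` (seconds within the
#'   minute), `ax`, `ay`, `az`.
#' @param step_args Passed to [extract_minute_features()].
#' @return A tibble with one row per participant-minute: `participant_id`,
#'   `minute_start`, `pa_avg`, `pa_var`, `steps`, `dominant_axis`.
#' @export
extract_features <- function(accel, step_args = list()) {
  missing <- setdiff(c("participant_id", "minute_start", "t", "ax", "ay", "az"),
                     names(accel))
  if (length(missing) > 0) {
    stop("`accel` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  accel |>
    dplyr::group_by(.data$participant_id, .data$minute_start) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(win, key) {
      extract_minute_features(win[c("t", "ax", "ay", "az")], step_args)
    }) |>
    dplyr::ungroup()
}
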