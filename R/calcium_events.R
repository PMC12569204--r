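#' One ROI's raw fluorescence time series
#'
#' @param roi_id Character scalar identifying the ROI/cell.
#' @param intensities Numeric vector of fluorescence values, finite and
#'   positive, length >= 4 (the minimum admitting one difference triple).
#' @param sampling_interval Seconds per sample (> 0).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(roi_id, intensities, sampling_interval) {
  stopifnot(is.character(roi_id), length(roi_id) == 1, nzchar(roi_id),
            is.numeric(sampling_interval), sampling_interval > 0)
  intensities <- as.numeric(intensities)
  if (length(intensities) < 4) {
    stop("trace '", roi_id, "' has fewer than 4 samples", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("trace '", roi_id, "' contains non-finite or non-positive values",
         call. = FALSE)
  }
  structure(
    list(roi_id = roi_id, intensities = intensities,
         sampling_interval = sampling_interval),
    class = "raw_trace"
  )
}

#' Detection parameters of the transient detector
#'
#' Defaults are the algorithm's stated constants: baseline F0 is the lower
#' fifth percentile of the session, and the dynamic threshold is the
#' greater of 2 x MAD of the dF/F0 trace and a fixed minimum of 0.1.
#'
#' @param mad_multiplier Multiplier on the (unscaled) MAD. Default 2.
#' @param threshold_floor Fixed minimum threshold, dF/F0 units. Default 0.1.
#' @param f0_percentile Baseline percentile of the session, percent.
#'   Default 5.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(mad_multiplier = 2,
                             threshold_floor = 0.1,
                             f0_percentile = 5) {
  stopifnot(mad_multiplier > 0, threshold_floor >= 0,
            f0_percentile > 0, f0_percentile < 100)
  structure(
    list(mad_multiplier = mad_multiplier,
         threshold_floor = threshold_floor,
         f0_percentile = f0_percentile),
    class = "detection_params"
  )
}

#' dF/F0 normalization against a low-percentile baseline
#'
#' `dff = (F - F0) / F0` where `F0` is the `f0_percentile`-th percentile of
#' the session (linear interpolation between order statistics). The result
#' is invariant under multiplicative rescaling of the raw trace.
#'
#' @param trace A [raw_trace()].
#' @param params A [detection_params()].
#' @return An object of class `normalized_trace` with fields `roi_id`,
#'   `dff`, `f0`, `sampling_interval`.
#' @export
normalize_dff <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(params, "detection_params"))
  f0 <- unname(quantile(trace$intensities, params$f0_percentile / 100,
                        type = 7))
  if (f0 <= 0) {
    stop("baseline F0 <= 0 for ROI '", trace$roi_id,
         "'; dF/F0 undefined", call. = FALSE)
  }
  structure(
    list(roi_id = trace$roi_id,
         dff = (trace$intensities - f0) / f0,
         f0 = f0,
         sampling_interval = trace$sampling_interval),
    class = "normalized_trace"
  )
}

#' MAD-based dynamic detection threshold
#'
#' `max(mad_multiplier * MAD(dff), threshold_floor)` with the unscaled MAD,
#' `median(|dff - median(dff)|)` (no 1.4826 normal-consistency factor).
#' For a quiet trace the MAD reflects noise and the fixed floor dominates;
#' for a noisy trace the MAD term raises the bar.
#'
#' @param norm A [normalize_dff()] result.
#' @param params A [detection_params()].
#' @return Threshold in dF/F0 units.
#' @export
compute_threshold <- function(norm, params = detection_params()) {
  stopifnot(inherits(norm, "normalized_trace"),
            inherits(params, "detection_params"))
  mad_unscaled <- median(abs(norm$dff - median(norm$dff)))
  max(params$mad_multiplier * mad_unscaled, params$threshold_floor)
}

#' Difference-pattern candidate detection
#'
#' A candidate activity event is a local peak/plateau start found from
#' three consecutive time-point differences: a positive slope into the
#' sample, followed by a non-positive change, then a negative slope. With
#' `d[i] = dff[i+1] - dff[i]`, sample `t` (1-based) is a candidate iff
#' `d[t-1] > 0`, `d[t] <= 0` and `d[t+1] < 0`. The first sample and the
#' last two samples can never be candidates; no padding is applied.
#'
#' @param norm A [normalize_dff()] result (length >= 4).
#' @return Sorted integer vector of candidate sample indices (1-based).
#' @export
detect_candidates <- function(norm) {
  stopifnot(inherits(norm, "normalized_trace"))
  x <- norm$dff
  n <- length(x)
  if (n < 4) return(integer(0))
  d <- diff(x)
  t <- 2:(n - 2)
  t[d[t - 1] > 0 & d[t] <= 0 & d[t + 1] < 0]
}

#' Dynamic-threshold filtering of candidates
#'
#' A candidate is retained only if the dF/F0 signal at that sample strictly
#' exceeds the threshold; a candidate exactly at threshold is rejected.
#'
#' @param candidates Sorted integer vector of candidate indices.
#' @param norm A [normalize_dff()] result.
#' @param threshold Threshold in dF/F0 units.
#' @return The retained subset of `candidates`.
#' @export
filter_by_threshold <- function(candidates, norm, threshold) {
  stopifnot(inherits(norm, "normalized_trace"))
  candidates <- as.integer(candidates)
  candidates[norm$dff[candidates] > threshold]
}

#' Interval-based de-duplication of threshold-crossing events
#'
#' Closely spaced events are retained as distinct only if the signal
#' between them drops below the threshold, so each retained event is a
#' distinct peak. Scanning left to right, consecutive events join the same
#' group unless the minimum dF/F0 strictly between them (excluding the
#' event samples themselves) falls below the threshold; each group
#' contributes its maximum-amplitude member (earliest index on ties).
#'
#' @param events Sorted integer indices, all strictly above `threshold`.
#' @param norm A [normalize_dff()] result.
#' @param threshold Threshold in dF/F0 units.
#' @return An object of class `event_set` with fields `roi_id`,
#'   `event_indices` (1-based), `amplitudes`, `threshold`.
#' @export
deduplicate_events <- function(events, norm, threshold) {
  stopifnot(inherits(norm, "normalized_trace"))
  events <- as.integer(events)
  x <- norm$dff
  groups <- list()
  for (e in events) {
    if (length(groups)) {
      prev <- groups[[length(groups)]]
      last_event <- prev[length(prev)]
      between <- if (e - last_event > 1) x[(last_event + 1):(e - 1)]
                 else numeric(0)
      dips <- length(between) > 0 && min(between) < threshold
      if (dips) {
        groups[[length(groups) + 1]] <- e
      } else {
        groups[[length(groups)]] <- c(prev, e)
      }
    } else {
      groups[[1]] <- e
    }
  }
  kept <- vapply(groups, function(g) g[which.max(x[g])], integer(1))
  structure(
    list(roi_id = norm$roi_id,
         event_indices = kept,
         amplitudes = x[kept],
         threshold = threshold),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %s: %d events above threshold %.3f\n",
              x$roi_id, length(x$event_indices), x$threshold))
  invisible(x)
}

#' Per-cell activity rate
#'
#' Number of detected activity events divided by the imaging-session
#' duration, in events per minute. Cells with no detectable activity are
#' flagged for exclusion (`included = FALSE`).
#'
#' @param events An [deduplicate_events()] result (`event_set`).
#' @param duration Session duration in seconds (> 0).
#' @return An object of class `activity_summary` with fields `roi_id`,
#'   `n_events`, `duration`, `rate` (events/min), `included`.
#' @export
activity_rate <- function(events, duration) {
  stopifnot(inherits(events, "event_set"))
  if (!is.finite(duration) || duration <= 0) {
    stop("session duration must be positive", call. = FALSE)
  }
  n <- length(events$event_indices)
  structure(
    list(roi_id = events$roi_id,
         n_events = n,
         duration = duration,
         rate = n / (duration / 60),
         included = n > 0),
    class = "activity_summary"
  )
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> %s: %d events in %.0f s = %.2f/min%s\n",
              x$roi_id, x$n_events, x$duration, x$rate,
              if (x$included) "" else " [excluded]"))
  invisible(x)
}

#' Full transient-detection pipeline for one trace
#'
#' Composition of the detection stages in order: dF/F0 normalization,
#' dynamic-threshold computation, difference-pattern candidate detection,
#' threshold filtering, interval-based de-duplication, activity rate.
#'
#' @param trace A [raw_trace()].
#' @param params A [detection_params()].
#' @return List with components `events` (an `event_set`) and `summary`
#'   (an `activity_summary`).
#' @examples
#' tr <- raw_trace("roi1", 100 * (1 + c(0, 0, .05, .6, .6, .2, .05, 0, 0, 0)), 1)
#' detect_events(tr)$events$event_indices  # single event at the peak
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "raw_trace"))
  norm <- normalize_dff(trace, params)
  threshold <- compute_threshold(norm, params)
  candidates <- detect_candidates(norm)
  above <- filter_by_threshold(candidates, norm, threshold)
  events <- deduplicate_events(above, norm, threshold)
  duration <- length(trace$intensities) * trace$sampling_interval
  list(events = events, summary = activity_rate(events, duration))
}

#' Precision/recall of detected events against ground truth
#'
#' Greedy earliest-first one-to-one matching: detected indices are scanned
#' in increasing order and each is matched to the earliest unmatched true
#' onset within `tolerance` samples. Precision is matched/detected (0 with
#' `precision_defined = FALSE` when nothing was detected), recall is
#' matched/true.
#'
#' @param detected An `event_set` or integer vector of detected indices.
#' @param truth Integer vector of true onset indices (same index base as
#'   `detected`).
#' @param tolerance Matching tolerance in samples (>= 0). Default 3.
#' @return List with `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_true`, `precision_defined`.
#' @export
evaluate_detection <- function(detected, truth, tolerance = 3) {
  stopifnot(tolerance >= 0)
  if (inherits(detected, "event_set")) detected <- detected$event_indices
  detected <- sort(as.integer(detected))
  truth <- sort(as.integer(truth))
  matched <- 0L
  used <- rep(FALSE, length(truth))
  for (d in detected) {
    hit <- which(!used & abs(truth - d) <= tolerance)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  n_det <- length(detected)
  n_true <- length(truth)
  list(
    precision = if (n_det > 0) matched / n_det else 0,
    recall = if (n_true > 0) matched / n_true else 1,
    n_matched = matched,
    n_detected = n_det,
    n_true = n_true,
    precision_defined = n_det > 0
  )
}
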