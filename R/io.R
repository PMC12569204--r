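#' Read a Ct table from CSV
#'
#' Required columns: `sample_id`, `condition`, `replicate`, `ct`. An empty
#' `ct` cell is the no-amplification sentinel (never 0). An optional
#' `known_fraction` column (constant within a sample) marks calibration
#' standards. Rows are grouped by (sample_id, condition) into
#' [ct_measurement()] objects.
#'
#' @param path Path to a CSV file (UTF-8, header row, "." decimal).
#' @return Named list of measurement sets, one per sample: each a list with
#'   element `measurements` (named by condition) and, when present,
#'   `known_fraction`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(ct = "character"))
  required <- c("sample_id", "condition", "replicate", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Ct table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- which(!df$condition %in% CT_CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition '", df$condition[bad_cond[1]],
         "' in row ", bad_cond[1], call. = FALSE)
  }
  key <- paste(df$sample_id, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, condition, replicate) in row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  ct_chr <- trimws(df$ct)
  is_sentinel <- is.na(ct_chr) | ct_chr == ""
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad_ct <- which(!is_sentinel & is.na(ct_num))
  if (length(bad_ct)) {
    stop("non-numeric ct value '", ct_chr[bad_ct[1]], "' in row ", bad_ct[1],
         call. = FALSE)
  }
  df$ct_parsed <- ifelse(is_sentinel, NA_real_, ct_num)

  out <- list()
  for (sid in unique(df$sample_id)) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    meas <- list()
    for (cond in unique(sub$condition)) {
      rows <- sub[sub$condition == cond, , drop = FALSE]
      rows <- rows[order(rows$replicate), , drop = FALSE]
      meas[[cond]] <- ct_measurement(sid, cond, rows$ct_parsed)
    }
    entry <- list(measurements = meas)
    if ("known_fraction" %in% names(sub)) {
      kf <- unique(as.numeric(sub$known_fraction))
      kf <- kf[!is.na(kf)]
      if (length(kf) > 1) {
        stop("sample '", sid, "' has inconsistent known_fraction values",
             call. = FALSE)
      }
      if (length(kf) == 1) entry$known_fraction <- kf
    }
    out[[sid]] <- entry
  }
  out
}

#' Write Ct measurements to CSV
#'
#' Inverse of [read_ct_table()]. The no-amplification sentinel is written
#' as an empty `ct` cell.
#'
#' @param samples Named list as returned by [read_ct_table()], or a list of
#'   sample entries each holding `measurements` and optionally
#'   `known_fraction`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(samples, path) {
  rows <- list()
  for (entry in samples) {
    for (m in entry$measurements) {
      r <- data.frame(
        sample_id = m$sample_id,
        condition = m$condition,
        replicate = seq_along(m$ct_values),
        ct = ifelse(is.na(m$ct_values), "",
                    format(m$ct_values, digits = 15, trim = TRUE)),
        stringsAsFactors = FALSE
      )
      if (!is.null(entry$known_fraction)) r$known_fraction <- entry$known_fraction
      rows[[length(rows) + 1]] <- r
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI trace matrix from CSV
#'
#' One column per ROI (header = roi_id), one row per time point. A leading
#' `time` or `index` column, if present, is dropped: timing comes from the
#' declared sampling interval. Requires at least 4 rows; all cells must be
#' finite and positive.
#'
#' @param path Path to a CSV file.
#' @param sampling_interval Seconds per sample (> 0).
#' @return Named list of [raw_trace()] objects.
#' @export
read_trace_matrix <- function(path, sampling_interval) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(sampling_interval), sampling_interval > 0)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (length(df) && tolower(names(df)[1]) %in% c("time", "index", "t")) {
    df <- df[, -1, drop = FALSE]
  }
  if (ncol(df) < 1) stop("trace matrix has no ROI columns", call. = FALSE)
  if (nrow(df) < 4) {
    stop("trace matrix has ", nrow(df), " rows; at least 4 required",
         call. = FALSE)
  }
  traces <- list()
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      stop("non-numeric value in ROI column '", names(df)[j], "'",
           call. = FALSE)
    }
    bad <- which(!is.finite(col) | col <= 0)
    if (length(bad)) {
      stop("non-finite or non-positive intensity in column '", names(df)[j],
           "', row ", bad[1], call. = FALSE)
    }
    traces[[names(df)[j]]] <- raw_trace(names(df)[j], col, sampling_interval)
  }
  traces
}

#' Write ROI traces to a CSV matrix
#'
#' First column `time` in seconds (0-based), remaining columns one ROI
#' each. All traces must share length and sampling interval.
#'
#' @param traces List of [raw_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_matrix <- function(traces, path) {
  stopifnot(length(traces) >= 1)
  n <- length(traces[[1]]$intensities)
  dt <- traces[[1]]$sampling_interval
  for (tr in traces) {
    if (length(tr$intensities) != n || tr$sampling_interval != dt) {
      stop("traces must share length and sampling interval", call. = FALSE)
    }
  }
  df <- data.frame(time = (seq_len(n) - 1) * dt)
  for (tr in traces) df[[tr$roi_id]] <- tr$intensities
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Result-table writers. Sample indices in files are 0-based (stated in the
# column names) while R objects are 1-based.

write_estimates_csv <- function(estimates, path) {
  df <- do.call(rbind, lapply(names(estimates), function(sid) {
    e <- estimates[[sid]]
    data.frame(sample_id = sid,
               fraction = e$fraction,
               raw_fraction = e$raw_fraction,
               R = e$relative_amplification,
               clamped = e$clamped,
               qc_pass = e$qc_pass,
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_events_csv <- function(event_sets, path) {
  rows <- lapply(event_sets, function(es) {
    if (!length(es$event_indices)) return(NULL)
    data.frame(roi_id = es$roi_id,
               event_index_0based = es$event_indices - 1L,
               amplitude = es$amplitudes,
               threshold = es$threshold,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(roi_id = character(0), event_index_0based = integer(0),
                     amplitude = numeric(0), threshold = numeric(0))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_activity_csv <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(roi_id = s$roi_id, n_events = s$n_events,
               duration_s = s$duration, rate_per_min = s$rate,
               included = s$included, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file mirroring the arguments of
#'   [run_workflow()].
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
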