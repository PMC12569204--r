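#' Enzyme-condition vocabulary for digestion qPCR
#'
#' The three digestion conditions of the assay: the methylation-sensitive
#' digest (HpaII-type enzyme plus the fragmenting control enzyme), the
#' methylation-insensitive isoschizomer digest (MspI-type, used as the
#' complete-digestion control), and the control digest (fragmenting enzyme
#' only, the normalization condition).
#'
#' @export
CT_CONDITIONS <- c("sensitive_digest", "insensitive_digest", "control_digest")

#' Replicate Ct values for one sample under one enzyme condition
#'
#' A qPCR threshold-cycle measurement. "No amplification" (no template
#' survived the digest, so the reaction never crosses threshold) is encoded
#' as `NA` replicate values; a measurement whose replicates are all `NA`
#' carries the no-amplification sentinel and maps to relative
#' amplification 0 downstream, never to a finite Ct.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param condition One of `r paste(CT_CONDITIONS, collapse = ", ")`.
#' @param ct_values Numeric vector of replicate Ct values (finite, > 0), or
#'   all `NA` for the no-amplification sentinel. At least one replicate.
#' @return An object of class `ct_measurement`.
#' @seealso [relative_amplification()], [read_ct_table()]
#' @export
ct_measurement <- function(sample_id, condition, ct_values) {
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id))
  condition <- match.arg(condition, CT_CONDITIONS)
  if (length(ct_values) < 1) {
    stop("ct_measurement requires at least one replicate", call. = FALSE)
  }
  ct_values <- as.numeric(ct_values)
  finite <- ct_values[!is.na(ct_values)]
  if (length(finite) && (any(!is.finite(finite)) || any(finite <= 0))) {
    stop("Ct values must be finite and positive (or NA for no amplification)",
         call. = FALSE)
  }
  if (length(finite) && anyNA(ct_values)) {
    stop("ct_measurement mixes finite Cts with the no-amplification sentinel; ",
         "a measurement is either quantifiable or not", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, condition = condition, ct_values = ct_values),
    class = "ct_measurement"
  )
}

#' @param x A `ct_measurement`.
#' @return `is_no_amplification()`: `TRUE` if the measurement carries the
#'   no-amplification sentinel (all replicates `NA`).
#' @rdname ct_measurement
#' @export
is_no_amplification <- function(x) {
  stopifnot(inherits(x, "ct_measurement"))
  all(is.na(x$ct_values))
}

#' @param measurement A `ct_measurement`.
#' @return `mean_ct()`: mean replicate Ct; errors on the sentinel.
#' @rdname ct_measurement
#' @export
mean_ct <- function(measurement) {
  if (is_no_amplification(measurement)) {
    stop("no-amplification measurement has no mean Ct (sample ",
         measurement$sample_id, ", ", measurement$condition, ")",
         call. = FALSE)
  }
  mean(measurement$ct_values)
}

#' @export
print.ct_measurement <- function(x, ...) {
  vals <- if (is_no_amplification(x)) "no amplification"
          else paste(sprintf("%.3f", x$ct_values), collapse = ", ")
  cat(sprintf("<ct_measurement> %s / %s: %s\n", x$sample_id, x$condition, vals))
  invisible(x)
}
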