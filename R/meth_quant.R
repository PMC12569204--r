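#' Relative amplification of a digest versus the control digest
#'
#' Ct differences encode template ratios logarithmically: one cycle at
#' efficiency 2 is a factor of two. The relative amplification of the
#' sensitive digest against the fragmenting-enzyme-only control digest,
#'
#'   R = E^-(mean Ct_digest - mean Ct_control),
#'
#' is the fraction of template that survived digestion and is the assay's
#' methylation readout. Replicates are summarized by mean Ct before forming
#' R (conventional delta-Ct practice; avoids log-scale bias of averaging
#' per-replicate ratios). A no-amplification digest maps to R = 0.
#'
#' @param digest [ct_measurement()] for the digested condition.
#' @param control [ct_measurement()] for the control digest of the same
#'   sample; must have finite Cts.
#' @param pcr_efficiency Amplification factor per cycle, in (1, 2\].
#'   Default 2.
#' @return Relative amplification R >= 0.
#' @examples
#' d <- ct_measurement("s1", "sensitive_digest", c(21, 21, 21))
#' c0 <- ct_measurement("s1", "control_digest", c(20, 20, 20))
#' relative_amplification(d, c0)  # 0.5: one extra cycle halves
#' @export
relative_amplification <- function(digest, control, pcr_efficiency = 2) {
  stopifnot(inherits(digest, "ct_measurement"),
            inherits(control, "ct_measurement"),
            pcr_efficiency > 1, pcr_efficiency <= 2)
  if (digest$sample_id != control$sample_id) {
    stop("sample_id mismatch: '", digest$sample_id, "' vs '",
         control$sample_id, "'", call. = FALSE)
  }
  if (is_no_amplification(control)) {
    stop("control digest of sample '", control$sample_id,
         "' did not amplify; cannot normalize", call. = FALSE)
  }
  if (is_no_amplification(digest)) return(0)
  pcr_efficiency^(-(mean_ct(digest) - mean_ct(control)))
}

#' Fit the methylation standard curve
#'
#' Ordinary least-squares line `R = slope * fraction + intercept` through
#' calibration points of known methylation fraction, as used to convert a
#' sample's relative amplification into a methylation fraction by inverse
#' prediction. The dosage model is exactly linear (R equals the methylation
#' fraction when digestion is complete), so a trend line is the natural
#' functional form.
#'
#' @param points Data frame with numeric columns `known_fraction` and `R`
#'   (at least two distinct fractions), e.g. from [calibration_points()].
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `points`, and `invertible` (`FALSE` when the
#'   fitted slope is zero, e.g. zero-variance R).
#' @examples
#' fit_standard_curve(data.frame(known_fraction = c(0, 1), R = c(0, 1)))
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("known_fraction", "R") %in% names(points)))
  if (nrow(points) < 2 || length(unique(points$known_fraction)) < 2) {
    stop("standard curve needs at least two distinct known fractions",
         call. = FALSE)
  }
  if (any(!is.finite(points$known_fraction)) || any(!is.finite(points$R))) {
    stop("standard-curve points must be finite", call. = FALSE)
  }
  fit <- lm(R ~ known_fraction, data = points)
  slope <- unname(coef(fit)[["known_fraction"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  ss_tot <- sum((points$R - mean(points$R))^2)
  r_squared <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         points = points, invertible = abs(slope) > .Machine$double.eps),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> R = %.4f * fraction + %.4f (r^2 = %.4f, %d points)%s\n",
    x$slope, x$intercept, x$r_squared, nrow(x$points),
    if (x$invertible) "" else " [NON-INVERTIBLE]"))
  invisible(x)
}

#' Estimate a methylation fraction by inverse prediction
#'
#' Inverts the standard curve at an observed relative amplification:
#' `raw_fraction = (R - intercept) / slope`, clamped to \[0, 1\]. Estimates
#' outside the unit interval are clamped and flagged rather than rejected:
#' fully methylated and fully unmethylated loci sit at the endpoints, which
#' replicate noise will overshoot.
#'
#' @param R Observed relative amplification (>= 0).
#' @param curve A [fit_standard_curve()] result; must be invertible.
#' @param qc_pass Logical digestion-QC flag to propagate (see
#'   [digestion_qc()]).
#' @return An object of class `methylation_estimate` with fields `fraction`
#'   (clamped), `raw_fraction`, `relative_amplification`, `clamped`,
#'   `qc_pass`.
#' @export
estimate_methylation <- function(R, curve, qc_pass = TRUE) {
  stopifnot(inherits(curve, "standard_curve"), is.finite(R), R >= 0,
            is.logical(qc_pass), length(qc_pass) == 1)
  if (!curve$invertible) {
    stop("standard curve has zero slope and cannot be inverted",
         call. = FALSE)
  }
  raw <- (R - curve$intercept) / curve$slope
  fraction <- min(1, max(0, raw))
  structure(
    list(fraction = fraction,
         raw_fraction = raw,
         relative_amplification = R,
         clamped = raw < 0 || raw > 1,
         qc_pass = qc_pass),
    class = "methylation_estimate"
  )
}

#' @export
print.methylation_estimate <- function(x, ...) {
  cat(sprintf(
    "<methylation_estimate> %.1f%%%s (raw %.4f, R = %.4f, QC %s)\n",
    100 * x$fraction, if (x$clamped) " [clamped]" else "",
    x$raw_fraction, x$relative_amplification,
    if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Digestion quality control via the insensitive isoschizomer
#'
#' The methylation-insensitive isoschizomer digest cuts every template copy
#' regardless of methylation, so its residual relative amplification
#' measures incomplete digestion. The check passes when that residual is at
#' most `max_residual` (boundary inclusive).
#'
#' @param insensitive_digest_R Relative amplification of the insensitive
#'   digest versus the control digest (>= 0).
#' @param max_residual Maximum tolerated residual amplification.
#'   Default 0.05.
#' @return Logical pass flag.
#' @export
digestion_qc <- function(insensitive_digest_R, max_residual = 0.05) {
  stopifnot(is.numeric(insensitive_digest_R),
            length(insensitive_digest_R) == 1,
            max_residual >= 0)
  if (!is.finite(insensitive_digest_R) || insensitive_digest_R < 0) {
    stop("insensitive-digest relative amplification must be >= 0",
         call. = FALSE)
  }
  insensitive_digest_R <= max_residual
}

#' Full estimation pipeline for one sample
#'
#' Relative amplification of the sensitive digest, digestion QC from the
#' insensitive digest (if provided), and inverse prediction through the
#' standard curve.
#'
#' @param measurements Named list of [ct_measurement()] objects with at
#'   least `sensitive_digest` and `control_digest`; `insensitive_digest`
#'   optional (QC passes vacuously when absent).
#' @param curve A [fit_standard_curve()] result.
#' @param pcr_efficiency Amplification factor per cycle, in (1, 2\].
#' @param max_residual QC threshold, see [digestion_qc()].
#' @return A `methylation_estimate`.
#' @export
estimate_sample_methylation <- function(measurements, curve,
                                        pcr_efficiency = 2,
                                        max_residual = 0.05) {
  stopifnot(is.list(measurements),
            all(c("sensitive_digest", "control_digest") %in%
                  names(measurements)))
  R <- relative_amplification(measurements$sensitive_digest,
                              measurements$control_digest, pcr_efficiency)
  qc <- TRUE
  if (!is.null(measurements$insensitive_digest)) {
    R_insens <- relative_amplification(measurements$insensitive_digest,
                                       measurements$control_digest,
                                       pcr_efficiency)
    qc <- digestion_qc(R_insens, max_residual)
  }
  estimate_methylation(R, curve, qc_pass = qc)
}

#' Comparative delta-delta-Ct relative expression
#'
#' Standard comparative quantification of RT-qPCR: the target Ct is
#' normalized to a reference gene (e.g. ACTB) within the sample
#' (`delta_ct`), then to a calibrator sample (`delta_delta_ct`); the fold
#' change is `efficiency^(-delta_delta_ct)`. The raw delta-Ct is exposed
#' for downstream statistics.
#'
#' @param target_ct Target-gene Ct, cycles (finite).
#' @param reference_ct Reference-gene Ct of the same sample, cycles.
#' @param calibrator_delta_ct Delta-Ct of the calibrator sample, cycles.
#' @param pcr_efficiency Amplification factor per cycle, in (1, 2\].
#' @return An object of class `expression_result` with fields `delta_ct`,
#'   `delta_delta_ct`, `relative_quantity`.
#' @examples
#' relative_expression_ddct(20, 15, 7)$relative_quantity  # 4
#' @export
relative_expression_ddct <- function(target_ct, reference_ct,
                                     calibrator_delta_ct,
                                     pcr_efficiency = 2) {
  stopifnot(is.finite(target_ct), is.finite(reference_ct),
            is.finite(calibrator_delta_ct),
            pcr_efficiency > 1, pcr_efficiency <= 2)
  delta_ct <- target_ct - reference_ct
  ddct <- delta_ct - calibrator_delta_ct
  structure(
    list(delta_ct = delta_ct,
         delta_delta_ct = ddct,
         relative_quantity = pcr_efficiency^(-ddct)),
    class = "expression_result"
  )
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf(
    "<expression_result> dCt = %.3f, ddCt = %.3f, RQ = %.4f\n",
    x$delta_ct, x$delta_delta_ct, x$relative_quantity))
  invisible(x)
}
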