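#' Simulation settings for the digestion-qPCR arm
#'
#' Generative model for methylation-sensitive restriction-digestion qPCR.
#' Each unmethylated template copy is cut by the methylation-sensitive
#' enzyme with probability `cut_efficiency_sensitive`; methylated copies are
#' protected. The insensitive isoschizomer cuts every copy with probability
#' `cut_efficiency_insensitive` regardless of methylation. The fragmenting
#' control enzyme (MseI-type) does not touch the amplicon. A condition whose
#' surviving template fraction is `s` amplifies `-log(s)/log(E)` cycles
#' later than the control digest (`E` = PCR efficiency per cycle), so
#'
#'   Ct = base_ct - log(s)/log(pcr_efficiency) + N(0, noise_sd)
#'
#' per replicate, and `s = 0` yields the no-amplification sentinel, never a
#' finite Ct.
#'
#' @param config An [allele_config()] giving the latent methylation
#'   fraction.
#' @param cut_efficiency_sensitive Probability in \[0, 1\] that an
#'   unmethylated copy is cut by the sensitive enzyme. Default 1 (complete
#'   digestion, as the assay's 12 h over-digestion intends).
#' @param cut_efficiency_insensitive Probability in \[0, 1\] that any copy is
#'   cut by the insensitive isoschizomer. Default 1.
#' @param pcr_efficiency Amplification factor per cycle, in (1, 2\].
#'   Default 2 (perfect doubling).
#' @param base_ct Ct of the control digest, cycles. Default 20.
#' @param noise_sd Replicate Ct noise standard deviation, cycles (>= 0).
#'   Default 0.2, a typical technical-replicate spread.
#' @param n_replicates Number of qPCR replicates per condition (>= 1).
#'   Default 3.
#' @param seed Integer RNG seed.
#' @return An object of class `digestion_sim_spec`.
#' @export
digestion_sim_spec <- function(config,
                               cut_efficiency_sensitive = 1,
                               cut_efficiency_insensitive = 1,
                               pcr_efficiency = 2,
                               base_ct = 20,
                               noise_sd = 0.2,
                               n_replicates = 3,
                               seed = 1L) {
  stopifnot(
    inherits(config, "allele_config"),
    cut_efficiency_sensitive >= 0, cut_efficiency_sensitive <= 1,
    cut_efficiency_insensitive >= 0, cut_efficiency_insensitive <= 1,
    pcr_efficiency > 1, pcr_efficiency <= 2,
    is.finite(base_ct), base_ct > 0,
    noise_sd >= 0,
    n_replicates >= 1, n_replicates == round(n_replicates)
  )
  structure(
    list(config = config,
         cut_efficiency_sensitive = cut_efficiency_sensitive,
         cut_efficiency_insensitive = cut_efficiency_insensitive,
         pcr_efficiency = pcr_efficiency,
         base_ct = base_ct,
         noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "digestion_sim_spec"
  )
}

# Ct replicates for a surviving template fraction s; s = 0 -> sentinel NAs.
ct_for_survival <- function(s, spec) {
  if (s == 0) return(rep(NA_real_, spec$n_replicates))
  spec$base_ct - log(s) / log(spec$pcr_efficiency) +
    rnorm(spec$n_replicates, 0, spec$noise_sd)
}

# Surviving fraction under the sensitive digest for methylation fraction m.
survival_sensitive <- function(m, cut_efficiency) {
  m + (1 - m) * (1 - cut_efficiency)
}

#' Simulate a digestion-qPCR measurement set with known ground truth
#'
#' Generates replicate Ct values for one sample under the three enzyme
#' conditions of the assay. With methylation fraction `m`, the surviving
#' template fractions are `m + (1-m)(1-cut_eff_sensitive)` (sensitive
#' digest), `1 - cut_eff_insensitive` (insensitive digest) and 1 (control
#' digest). Identical spec (including seed) gives bitwise-identical output.
#'
#' @param spec A [digestion_sim_spec()].
#' @param sample_id Sample identifier for the generated measurements.
#' @return A list with components
#'   \item{measurements}{named list of [ct_measurement()] objects for
#'     `sensitive_digest`, `insensitive_digest`, `control_digest`;}
#'   \item{truth}{list with `true_methylation_fraction`.}
#' @examples
#' spec <- digestion_sim_spec(allele_config(1, 1), noise_sd = 0)
#' sim <- simulate_digestion_qpcr(spec)
#' sim$measurements$sensitive_digest$ct_values  # base_ct + 1: half survives
#' @export
simulate_digestion_qpcr <- function(spec, sample_id = "sample") {
  stopifnot(inherits(spec, "digestion_sim_spec"))
  m <- methylation_fraction(spec$config)
  set.seed(spec$seed)
  s_sens <- survival_sensitive(m, spec$cut_efficiency_sensitive)
  s_insens <- 1 - spec$cut_efficiency_insensitive
  measurements <- list(
    sensitive_digest = ct_measurement(
      sample_id, "sensitive_digest", ct_for_survival(s_sens, spec)),
    insensitive_digest = ct_measurement(
      sample_id, "insensitive_digest", ct_for_survival(s_insens, spec)),
    control_digest = ct_measurement(
      sample_id, "control_digest", ct_for_survival(1, spec))
  )
  list(measurements = measurements,
       truth = list(true_methylation_fraction = m))
}

#' Simulate a calibration (standard-curve) series
#'
#' Generates one sensitive-digest/control-digest measurement pair per known
#' methylation fraction, emulating calibration standards mixed from fully
#' methylated and fully unmethylated genomic DNA at each fraction. The noise
#' model is the same as [simulate_digestion_qpcr()]: a mixture at fraction
#' `f` leaves surviving fraction `f + (1-f)(1-cut_eff)` under the sensitive
#' digest.
#'
#' @param fractions Non-empty numeric vector of known methylation fractions
#'   in \[0, 1\]. Duplicates are allowed. The default 5-point series
#'   `c(0, 0.25, 0.5, 0.75, 1)` spans the assay's dynamic range evenly.
#' @param spec A [digestion_sim_spec()]; its `config` is ignored (the known
#'   fraction replaces it), all other parameters apply.
#' @return A list of calibration points, each a list with `known_fraction`,
#'   `sensitive` and `control` ([ct_measurement()] objects). Class
#'   `calibration_series`.
#' @export
simulate_calibration_series <- function(fractions = c(0, 0.25, 0.5, 0.75, 1),
                                        spec) {
  stopifnot(inherits(spec, "digestion_sim_spec"))
  if (length(fractions) == 0) {
    stop("calibration requires at least one known fraction", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("calibration fractions must lie in [0, 1]", call. = FALSE)
  }
  set.seed(spec$seed)
  points <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    id <- sprintf("cal_%02d", i)
    s <- survival_sensitive(f, spec$cut_efficiency_sensitive)
    list(
      known_fraction = f,
      sensitive = ct_measurement(id, "sensitive_digest",
                                 ct_for_survival(s, spec)),
      control = ct_measurement(id, "control_digest",
                               ct_for_survival(1, spec))
    )
  })
  structure(points, class = "calibration_series")
}

#' Relative-amplification points of a calibration series
#'
#' @param series A `calibration_series` from [simulate_calibration_series()]
#'   or assembled from [read_ct_table()] output.
#' @param pcr_efficiency Amplification factor per cycle, in (1, 2\].
#' @return Data frame with columns `known_fraction` and `R`, ready for
#'   [fit_standard_curve()].
#' @export
calibration_points <- function(series, pcr_efficiency = 2) {
  stopifnot(inherits(series, "calibration_series"))
  data.frame(
    known_fraction = vapply(series, `[[`, numeric(1), "known_fraction"),
    R = vapply(series, function(p) {
      relative_amplification(p$sensitive, p$control, pcr_efficiency)
    }, numeric(1))
  )
}
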