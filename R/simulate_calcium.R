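#' Simulation settings for the calcium-imaging arm
#'
#' Generative model for spontaneous-activity fluorescence recordings from a
#' genetically encoded calcium indicator. Each cell's trace is
#'
#'   F(t) = baseline * (1 + drift(t) + sum of transient kernels) + N(0, noise_sd)
#'
#' with transient onsets drawn from a Poisson process at `event_rate`
#' (thinned so retained onsets are more than `refractory_samples` apart),
#' amplitudes uniform on `amplitude_range` (in dF/F0 units of the
#' baseline), a linear rise over `rise_samples` samples and a
#' single-exponential decay with time constant `decay_tau`. `drift(t)` is
#' slow monotone photobleaching: a linear decay losing `drift_amplitude` of
#' the baseline over the session (each cell's realized loss drawn uniformly
#' up to that amplitude). One global seed governs the session through an
#' independent substream per cell, so adding cells does not perturb earlier
#' cells.
#'
#' Defaults describe a typical desk-scale session: 100 cells, 10 min at
#' 1 Hz, 2 events/min, transient amplitudes 0.4-0.8 dF/F0 (well above the
#' 0.1 detection floor), ~2 s decay, and noise at 2% of baseline so
#' amplitudes are at least 20x the noise sd.
#'
#' @param n_cells Number of cells/ROIs (>= 1).
#' @param n_samples Samples per trace (>= 4).
#' @param sampling_interval Seconds per sample (> 0).
#' @param event_rate Events per minute (>= 0).
#' @param amplitude_range Length-2 numeric, min <= max, dF/F0 units.
#' @param decay_tau Exponential decay time constant, seconds (> 0).
#' @param rise_samples Samples of linear rise to peak (>= 0).
#' @param baseline Baseline fluorescence, arbitrary units (> 0).
#' @param drift_amplitude Maximum fractional baseline loss to slow
#'   photobleaching over the session (>= 0).
#' @param noise_sd Additive noise sd, fluorescence units (>= 0).
#' @param refractory_samples Minimum spacing between retained onsets,
#'   samples (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `calcium_sim_spec`.
#' @export
calcium_sim_spec <- function(n_cells = 100,
                             n_samples = 600,
                             sampling_interval = 1,
                             event_rate = 2,
                             amplitude_range = c(0.4, 0.8),
                             decay_tau = 2,
                             rise_samples = 2L,
                             baseline = 100,
                             drift_amplitude = 0.05,
                             noise_sd = 2,
                             refractory_samples = 10L,
                             seed = 1L) {
  stopifnot(
    n_cells >= 1, n_cells == round(n_cells),
    n_samples >= 4, n_samples == round(n_samples),
    sampling_interval > 0,
    event_rate >= 0,
    length(amplitude_range) == 2, amplitude_range[1] <= amplitude_range[2],
    decay_tau > 0,
    rise_samples >= 0, rise_samples == round(rise_samples),
    drift_amplitude >= 0,
    noise_sd >= 0,
    refractory_samples >= 0, refractory_samples == round(refractory_samples)
  )
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be a positive fluorescence level", call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells),
         n_samples = as.integer(n_samples),
         sampling_interval = sampling_interval,
         event_rate = event_rate,
         amplitude_range = as.numeric(amplitude_range),
         decay_tau = decay_tau,
         rise_samples = as.integer(rise_samples),
         baseline = baseline,
         drift_amplitude = drift_amplitude,
         noise_sd = noise_sd,
         refractory_samples = as.integer(refractory_samples),
         seed = as.integer(seed)),
    class = "calcium_sim_spec"
  )
}

# Per-cell substream seed derived from the global seed; kept within the
# 32-bit integer range so set.seed() accepts it.
cell_substream_seed <- function(seed, cell) {
  as.integer((as.double(seed) * 1009 + cell * 7919) %% 2147483647)
}

# Poisson-process onsets (sample indices, 1-based) thinned by a refractory
# dead time. Exponential inter-arrival times at event_rate per minute.
draw_onsets <- function(spec) {
  rate_per_s <- spec$event_rate / 60
  if (rate_per_s == 0) return(integer(0))
  duration <- spec$n_samples * spec$sampling_interval
  times <- numeric(0)
  t <- rexp(1, rate_per_s)
  while (t < duration) {
    times <- c(times, t)
    t <- t + rexp(1, rate_per_s)
  }
  onsets <- unique(floor(times / spec$sampling_interval) + 1L)
  kept <- integer(0)
  for (o in onsets) {
    if (!length(kept) || o - kept[length(kept)] > spec$refractory_samples) {
      kept <- c(kept, o)
    }
  }
  kept
}

# Additive dF/F0 signal of one transient starting at sample `onset`:
# linear rise over rise_samples to `amp`, then exponential decay.
transient_kernel <- function(onset, amp, spec) {
  n <- spec$n_samples
  idx <- onset:n
  rel <- idx - onset
  rise <- spec$rise_samples
  k <- ifelse(
    rel <= rise,
    if (rise == 0) amp else amp * rel / rise,
    amp * exp(-(rel - rise) * spec$sampling_interval / spec$decay_tau)
  )
  list(idx = idx, values = k)
}

#' Simulate a session of calcium fluorescence traces with known onsets
#'
#' @param spec A [calcium_sim_spec()].
#' @return A list with components
#'   \item{traces}{list of [raw_trace()] objects, one per cell
#'     (`roi_id` = `"cell_001"`, ...);}
#'   \item{truth}{list with `event_onsets`, a per-cell list of strictly
#'     increasing 1-based onset sample indices (transient start; the peak
#'     follows `rise_samples` later).}
#' @examples
#' sim <- simulate_calcium_traces(calcium_sim_spec(n_cells = 2, seed = 7))
#' length(sim$truth$event_onsets$cell_001)
#' @export
simulate_calcium_traces <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  n <- spec$n_samples
  duration <- n * spec$sampling_interval
  clipped_cells <- character(0)
  traces <- vector("list", spec$n_cells)
  onsets_all <- vector("list", spec$n_cells)
  ids <- sprintf("cell_%03d", seq_len(spec$n_cells))
  for (cell in seq_len(spec$n_cells)) {
    set.seed(cell_substream_seed(spec$seed, cell))
    onsets <- draw_onsets(spec)
    amps <- if (length(onsets)) {
      runif(length(onsets), spec$amplitude_range[1], spec$amplitude_range[2])
    } else numeric(0)
    bleach_loss <- runif(1, 0, spec$drift_amplitude)
    noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else numeric(n)

    signal <- numeric(n)
    for (i in seq_along(onsets)) {
      kern <- transient_kernel(onsets[i], amps[i], spec)
      signal[kern$idx] <- signal[kern$idx] + kern$values
    }
    drift <- -bleach_loss * seq_len(n) / n
    raw <- spec$baseline * (1 + drift + signal) + noise
    if (any(raw <= 0)) {
      raw[raw <= 0] <- .Machine$double.eps * spec$baseline
      clipped_cells <- c(clipped_cells, ids[cell])
    }
    traces[[cell]] <- raw_trace(ids[cell], raw, spec$sampling_interval)
    onsets_all[[cell]] <- onsets
  }
  if (length(clipped_cells)) {
    warning("clipped non-positive fluorescence values in: ",
            paste(clipped_cells, collapse = ", "), call. = FALSE)
  }
  names(traces) <- ids
  names(onsets_all) <- ids
  list(traces = traces, truth = list(event_onsets = onsets_all))
}
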