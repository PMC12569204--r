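# Generators: digestion-qPCR and calcium-trace simulation with ground truth.

test_that("allele_config validates and exposes the methylation fraction", {
  expect_equal(methylation_fraction(allele_config(1, 1)), 0.5)
  expect_equal(methylation_fraction(allele_config(1, 0)), 1)
  expect_equal(methylation_fraction(allele_config(0, 2)), 0)
  expect_error(allele_config(0, 0), "at least one copy")
  expect_error(allele_config(-1, 2))
})

test_that("noiseless digestion Cts follow the survival model", {
  # halving the template adds exactly one cycle at efficiency 2
  sim <- simulate_digestion_qpcr(
    digestion_sim_spec(allele_config(1, 1), noise_sd = 0))
  expect_equal(sim$measurements$sensitive_digest$ct_values, rep(21, 3))
  expect_equal(sim$measurements$control_digest$ct_values, rep(20, 3))
  expect_equal(sim$truth$true_methylation_fraction, 0.5)

  # fully methylated: everything survives the sensitive digest
  sim <- simulate_digestion_qpcr(
    digestion_sim_spec(allele_config(1, 0), noise_sd = 0))
  expect_equal(sim$measurements$sensitive_digest$ct_values, rep(20, 3))

  # fully unmethylated + complete digestion: the no-amplification sentinel,
  # never a finite Ct; complete insensitive digest likewise
  sim <- simulate_digestion_qpcr(
    digestion_sim_spec(allele_config(0, 1), noise_sd = 0))
  expect_true(is_no_amplification(sim$measurements$sensitive_digest))
  expect_true(is_no_amplification(sim$measurements$insensitive_digest))
})

test_that("digestion simulation is deterministic under a fixed seed", {
  spec <- digestion_sim_spec(allele_config(1, 1), noise_sd = 0.3, seed = 11L)
  a <- simulate_digestion_qpcr(spec)
  b <- simulate_digestion_qpcr(spec)
  expect_identical(a, b)
})

test_that("noiseless relative amplification equals m for any configuration", {
  # conservation of the dosage model, across genotypes incl. partial cutting
  for (cfg in list(c(1, 1), c(1, 0), c(0, 1), c(2, 0), c(1, 2), c(3, 1))) {
    allele <- allele_config(cfg[1], cfg[2])
    m <- methylation_fraction(allele)
    sim <- simulate_digestion_qpcr(digestion_sim_spec(allele, noise_sd = 0))
    R <- relative_amplification(sim$measurements$sensitive_digest,
                                sim$measurements$control_digest)
    expect_equal(R, m, tolerance = 1e-12)
    expect_equal(R, oracle_survival(m, 1), tolerance = 1e-12)
  }
  # partial sensitive cutting follows s = m + (1-m)(1-ce)
  sim <- simulate_digestion_qpcr(
    digestion_sim_spec(allele_config(1, 1), cut_efficiency_sensitive = 0.8,
                       noise_sd = 0))
  R <- relative_amplification(sim$measurements$sensitive_digest,
                              sim$measurements$control_digest)
  expect_equal(R, oracle_survival(0.5, 0.8), tolerance = 1e-12)
})

test_that("noisy generator plus estimator recovers 0.5 end to end", {
  # DERIVED example: noise_sd 0.2, 3 replicates, fixed seed; the oracle is
  # the analytic survival fraction with replicate-averaged noise
  cal <- simulate_calibration_series(
    c(0, 0.25, 0.5, 0.75, 1),
    digestion_sim_spec(allele_config(1, 0), noise_sd = 0.2, seed = 101L))
  curve <- fit_standard_curve(calibration_points(cal))
  sim <- simulate_digestion_qpcr(
    digestion_sim_spec(allele_config(1, 1), noise_sd = 0.2,
                       n_replicates = 3, seed = 202L))
  est <- estimate_sample_methylation(sim$measurements, curve)
  expect_lt(abs(est$fraction - 0.5), 0.05)
})

test_that("calibration series spans fractions with the stated noise model", {
  spec0 <- digestion_sim_spec(allele_config(1, 0), noise_sd = 0)
  series <- simulate_calibration_series(c(0, 0.5, 1), spec0)
  pts <- calibration_points(series)
  expect_equal(pts$R, c(0, 0.5, 1), tolerance = 1e-12)

  # at noise 0.2 Ct a single fitted slope has sd ~0.1, so the 0.9-1.1 band
  # is asserted on the mean over seeded repetitions of the same fit
  slopes <- vapply(seq_len(50), function(k) {
    specn <- digestion_sim_spec(allele_config(1, 0), noise_sd = 0.2,
                                seed = 700L + k)
    fit_standard_curve(
      calibration_points(simulate_calibration_series(c(0, 0.25, 0.5, 0.75, 1),
                                                     specn)))$slope
  }, numeric(1))
  expect_gt(mean(slopes), 0.9)
  expect_lt(mean(slopes), 1.1)

  expect_error(simulate_calibration_series(numeric(0), spec0),
               "at least one")
  expect_error(simulate_calibration_series(c(0, 1.2), spec0), "\\[0, 1\\]")
})

test_that("quiet calcium simulation gives constant traces and zero events", {
  spec <- calcium_sim_spec(n_cells = 3, n_samples = 50, event_rate = 0,
                           noise_sd = 0, drift_amplitude = 0)
  sim <- simulate_calcium_traces(spec)
  expect_length(sim$traces, 3)
  for (tr in sim$traces) {
    expect_true(all(tr$intensities == tr$intensities[1]))
    out <- detect_events(tr)
    expect_length(out$events$event_indices, 0)
    expect_false(out$summary$included)
  }
  expect_true(all(lengths(sim$truth$event_onsets) == 0))
})

test_that("calcium simulation is deterministic and substreamed per cell", {
  spec <- calcium_sim_spec(n_cells = 4, n_samples = 120, seed = 9L)
  a <- simulate_calcium_traces(spec)
  b <- simulate_calcium_traces(spec)
  expect_identical(a, b)

  # adding cells must not perturb earlier cells (independent substreams)
  bigger <- simulate_calcium_traces(
    calcium_sim_spec(n_cells = 6, n_samples = 120, seed = 9L))
  expect_identical(a$traces$cell_001, bigger$traces$cell_001)
  expect_identical(a$truth$event_onsets$cell_004,
                   bigger$truth$event_onsets$cell_004)
})

test_that("ground-truth onsets are sorted, in range, refractory-spaced", {
  spec <- calcium_sim_spec(n_cells = 30, n_samples = 300, seed = 5L,
                           refractory_samples = 10L)
  sim <- simulate_calcium_traces(spec)
  for (onsets in sim$truth$event_onsets) {
    if (length(onsets) < 2) next
    expect_true(all(diff(onsets) > 10))
    expect_true(all(onsets >= 1 & onsets <= 300))
  }
})

test_that("expected event count matches the Poisson rate (no refractory)", {
  # dead-time thinning lowers the realized rate, so the rate identity is
  # checked on the unthinned process
  spec <- calcium_sim_spec(n_cells = 250, n_samples = 300, event_rate = 3,
                           refractory_samples = 0L, noise_sd = 0, seed = 21L)
  sim <- simulate_calcium_traces(spec)
  counts <- lengths(sim$truth$event_onsets)
  expected <- 3 * (300 / 60)            # rate * duration(min) = 15 per cell
  se <- sqrt(expected / 250)            # Poisson SE of the mean over cells
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("dF/F0 is invariant to rescaling the simulated baseline", {
  base_spec <- function(b) calcium_sim_spec(
    n_cells = 2, n_samples = 100, baseline = b, noise_sd = 0,
    drift_amplitude = 0.05, seed = 13L)
  a <- simulate_calcium_traces(base_spec(100))
  b <- simulate_calcium_traces(base_spec(700))
  for (id in names(a$traces)) {
    expect_equal(normalize_dff(a$traces[[id]])$dff,
                 normalize_dff(b$traces[[id]])$dff, tolerance = 1e-12)
  }
})
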