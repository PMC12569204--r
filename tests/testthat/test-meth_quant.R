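# Methylation-fraction estimation: relative amplification, standard curve,
# inverse prediction, digestion QC, ddCt expression.

test_that("relative amplification converts Ct differences to ratios", {
  ctrl <- ct_measurement("s1", "control_digest", rep(20, 3))
  cases <- list(
    list(ct = 20, R = 1.0),            # identity
    list(ct = 21, R = 0.5),            # one cycle halves
    list(ct = 20 + log2(10), R = 0.1)  # log2(10) cycles = one decade
  )
  for (cs in cases) {
    dig <- ct_measurement("s1", "sensitive_digest", rep(cs$ct, 3))
    expect_equal(relative_amplification(dig, ctrl, 2), cs$R,
                 tolerance = 1e-12)
  }
  # no-amplification sentinel maps to R = 0
  dig <- ct_measurement("s1", "sensitive_digest", rep(NA_real_, 3))
  expect_equal(relative_amplification(dig, ctrl), 0)
  # contract errors
  other <- ct_measurement("s2", "sensitive_digest", rep(21, 3))
  expect_error(relative_amplification(other, ctrl), "sample_id mismatch")
  expect_error(relative_amplification(
    dig, ct_measurement("s1", "control_digest", NA_real_)), "did not amplify")
  expect_error(ct_measurement("s1", "sensitive_digest", numeric(0)),
               "at least one replicate")
})

test_that("standard-curve fit matches the closed-form least squares", {
  # identity line
  ident <- fit_standard_curve(data.frame(known_fraction = c(0, 1),
                                         R = c(0, 1)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)

  # DERIVED oracle, computed by hand: x = (0, .5, 1), y = (.02, .51, .99)
  # Sxy/Sxx = .485/.5 = .97; intercept = ybar - slope*xbar = .065/3
  curve <- fit_standard_curve(data.frame(known_fraction = c(0, 0.5, 1),
                                         R = c(0.02, 0.51, 0.99)))
  expect_equal(curve$slope, 0.97, tolerance = 1e-10)
  expect_equal(curve$intercept, 0.065 / 3, tolerance = 1e-10)
  expect_gt(curve$r_squared, 0.999)

  expect_error(fit_standard_curve(data.frame(known_fraction = c(0, 0),
                                             R = c(0.5, 0.6))),
               "distinct known fractions")
  expect_error(fit_standard_curve(data.frame(known_fraction = 0.5, R = 0.5)),
               "distinct known fractions")
  # zero-variance R: flat curve flagged non-invertible
  flat <- fit_standard_curve(data.frame(known_fraction = c(0, 0.5, 1),
                                        R = c(0.4, 0.4, 0.4)))
  expect_false(flat$invertible)
  expect_error(estimate_methylation(0.4, flat), "cannot be inverted")
})

test_that("inverse prediction clamps and flags out-of-range estimates", {
  ident <- fit_standard_curve(data.frame(known_fraction = c(0, 1),
                                         R = c(0, 1)))
  mid <- estimate_methylation(0.5, ident)
  expect_equal(mid$fraction, 0.5)
  expect_false(mid$clamped)

  high <- estimate_methylation(1.2, ident)
  expect_equal(high$fraction, 1)
  expect_equal(high$raw_fraction, 1.2)
  expect_true(high$clamped)

  # DERIVED: inverting the hand-fit curve at R = 0.507 -> ~0.500
  curve <- fit_standard_curve(data.frame(known_fraction = c(0, 0.5, 1),
                                         R = c(0.02, 0.51, 0.99)))
  est <- estimate_methylation(0.507, curve)
  expect_equal(est$fraction, (0.507 - 0.065 / 3) / 0.97, tolerance = 1e-10)
  expect_equal(est$fraction, 0.500, tolerance = 1e-3)
})

test_that("digestion QC thresholds residual amplification, inclusive", {
  expect_true(digestion_qc(0))
  expect_false(digestion_qc(0.5))
  expect_true(digestion_qc(0.05))    # boundary inclusive at the default
  expect_false(digestion_qc(0.0500001))
  expect_error(digestion_qc(-0.1), ">= 0")
})

test_that("ddCt expression follows the comparative method", {
  r <- relative_expression_ddct(20, 15, 7, 2)
  expect_equal(r$delta_ct, 5)
  expect_equal(r$delta_delta_ct, -2)
  expect_equal(r$relative_quantity, 4)

  expect_equal(relative_expression_ddct(22, 15, 7)$relative_quantity, 1)
  expect_equal(relative_expression_ddct(25, 15, 7)$relative_quantity, 0.125)
  # efficiency below doubling compresses fold changes
  expect_equal(relative_expression_ddct(25, 15, 7, 1.9)$relative_quantity,
               1.9^-3)
})

test_that("estimates are invariant to a global Ct shift", {
  curve <- fit_standard_curve(data.frame(known_fraction = c(0, 0.5, 1),
                                         R = c(0.02, 0.51, 0.99)))
  fractions <- vapply(c(-3, 0, 2.5, 10), function(shift) {
    dig <- ct_measurement("s", "sensitive_digest", c(21.1, 21.3, 20.9) + shift)
    ctrl <- ct_measurement("s", "control_digest", c(20.0, 20.2, 19.8) + shift)
    estimate_sample_methylation(
      list(sensitive_digest = dig, control_digest = ctrl), curve)$fraction
  }, numeric(1))
  expect_equal(diff(range(fractions)), 0, tolerance = 1e-12)
})

test_that("estimate is monotone in R for a positive-slope curve", {
  curve <- fit_standard_curve(data.frame(known_fraction = c(0, 0.5, 1),
                                         R = c(0.02, 0.51, 0.99)))
  Rs <- seq(0, 1.3, by = 0.05)
  fr <- vapply(Rs, function(R) estimate_methylation(R, curve)$fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("noiseless pipeline recovers any allele configuration exactly", {
  spec0 <- digestion_sim_spec(allele_config(1, 0), noise_sd = 0)
  curve <- fit_standard_curve(
    calibration_points(simulate_calibration_series(c(0, 0.25, 0.5, 0.75, 1),
                                                   spec0)))
  for (cfg in list(c(1, 1), c(1, 0), c(0, 1), c(1, 3), c(5, 2))) {
    allele <- allele_config(cfg[1], cfg[2])
    sim <- simulate_digestion_qpcr(digestion_sim_spec(allele, noise_sd = 0))
    est <- estimate_sample_methylation(sim$measurements, curve)
    expect_equal(est$fraction, methylation_fraction(allele),
                 tolerance = 1e-10)
    expect_true(est$qc_pass)
  }
})

test_that("stochastic recovery: mean absolute error <= 0.05 at the stated noise", {
  # noise_sd 0.2 Ct, 3 replicates, 5-point calibration, >= 100 repetitions
  for (truth in c(0, 0.5, 1)) {
    allele <- switch(as.character(truth),
                     "0" = allele_config(0, 1),
                     "0.5" = allele_config(1, 1),
                     "1" = allele_config(1, 0))
    errs <- vapply(seq_len(100), function(k) {
      cal <- simulate_calibration_series(
        c(0, 0.25, 0.5, 0.75, 1),
        digestion_sim_spec(allele_config(1, 0), noise_sd = 0.2,
                           seed = 5000L + k))
      curve <- fit_standard_curve(calibration_points(cal))
      sim <- simulate_digestion_qpcr(
        digestion_sim_spec(allele, noise_sd = 0.2, seed = 6000L + k))
      abs(estimate_sample_methylation(sim$measurements, curve)$fraction -
            truth)
    }, numeric(1))
    expect_lte(mean(errs), 0.05)
  }
})
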