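# Noiseless fits shared across blocks (each ~1.5 s)
clean_muscle <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 1),
                                  fix_axis, seed = 1)
clean_fit <- fit_spectrum(clean_muscle$spectrum, fix_basis)

test_that("noiseless identity: amplitudes recovered to < 1e-4 relative", {
  truth <- clean_muscle$truth$amplitudes
  est <- clean_fit$amplitudes[names(truth)]
  expect_true(all(abs(est - truth) / truth < 1e-4))
  # absent signals stay at (or extremely near) zero
  absent <- setdiff(clean_fit$labels, names(truth))
  expect_true(all(clean_fit$amplitudes[absent] < 1e-3 * max(truth)))
  # baseline collapses to ~0 relative to the tallest signal
  expect_lt(max(Mod(clean_fit$baseline)),
            1e-6 * max(Mod(clean_fit$fitted)))
  expect_true(clean_fit$diagnostics$converged)
})

test_that("relative intensities normalize to 100 over the reporting subset", {
  rel <- clean_fit$relative_intensities
  expect_equal(sum(rel), 100, tolerance = 1e-9)
  expect_setequal(names(rel), c("gATP", "aATP", "bATP", "GPC", "PCr", "Pi"))
  # uniform amplitudes split evenly
  amps <- stats::setNames(rep(2, 6), names(rel))
  expect_equal(unname(relative_intensities(amps, names(rel))),
               rep(100 / 6, 6))
  # proportionality: scaling amplitudes leaves percentages unchanged
  expect_equal(relative_intensities(amps * 7, names(rel)),
               relative_intensities(amps, names(rel)))
  expect_error(relative_intensities(amps, character(0)), "empty")
  expect_error(relative_intensities(amps, "nope"), "nope")
})

test_that("true phases are recovered and reported wrapped", {
  g <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 1),
                         fix_axis, seed = 1,
                         phase0_deg = -96, phase1_deg_ppm = 7)
  f <- fit_spectrum(g$spectrum, fix_basis)
  expect_equal(f$phase0_deg, -96, tolerance = 1)
  expect_equal(f$phase1_deg_ppm, 7, tolerance = 0.5)
  truth <- g$truth$amplitudes
  expect_true(all(abs(f$amplitudes[names(truth)] - truth) / truth < 1e-3))
  # truth shifted by +360 degrees is the same signal; report stays wrapped
  g2 <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 1),
                          fix_axis, seed = 1,
                          phase0_deg = -96 + 360, phase1_deg_ppm = 7)
  expect_equal(g2$spectrum$fid, g$spectrum$fid, tolerance = 1e-12)
  f2 <- fit_spectrum(g2$spectrum, fix_basis)
  expect_equal(f2$phase0_deg, f$phase0_deg, tolerance = 1e-3)
  expect_gt(f2$phase0_deg, -180)
  expect_lte(f2$phase0_deg, 180)
})

test_that("broadening is recovered when the data are wider than the basis", {
  g <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 5),
                         fix_axis, seed = 1)
  f <- fit_spectrum(g$spectrum, fix_basis)
  # Lorentzian widths add: 1 Hz basis + 4 Hz extra = 5 Hz data
  expect_equal(f$broadening_hz, 4, tolerance = 0.05)
  truth <- g$truth$amplitudes
  expect_true(all(abs(f$amplitudes[names(truth)] - truth) / truth < 1e-3))
})

test_that("fitted shifts stay within the prior's reach on well-posed data", {
  g <- generate_spectrum(muscle_preset(snr = 50), fix_axis, seed = 7)
  f <- fit_spectrum(g$spectrum, fix_basis)
  expect_true(all(abs(f$shifts_ppm) <= 0.05))
  expect_identical(unname(f$shifts_ppm["PCr"]), 0)  # reference pinned
})

test_that("axis mismatch is a structural error; longer basis is truncated", {
  short_axis <- make_axis(1024, 2000, 49.9)
  sp_short <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 1),
                                short_axis, seed = 1)$spectrum
  # same dwell, basis longer: truncation path works
  f <- fit_spectrum(sp_short, fix_basis)
  truth <- muscle_preset()$ground_truth
  expect_true(all(abs(f$amplitudes[names(truth)] - truth) / truth < 1e-2))
  # different dwell: hard error
  bad_axis <- make_axis(2048, 1000, 49.9)
  sp_bad <- generate_spectrum(muscle_preset(snr = Inf, linewidth_hz = 1),
                              bad_axis, seed = 1)$spectrum
  expect_error(fit_spectrum(sp_bad, fix_basis), "incompatible")
})

test_that("compare_methods computes paired CVs and grades", {
  a <- list(c(gATP = 23.3, PCr = 60)); b <- list(c(gATP = 26.0, PCr = 60))
  cmp <- compare_methods(a, b)
  # hand-evaluated: 100 * (|23.3-26.0|/sqrt(2)) / 24.65 = 7.744
  expect_equal(unname(cmp$mean_cv["gATP"]),
               100 * (2.7 / sqrt(2)) / 24.65, tolerance = 1e-10)
  expect_identical(unname(cmp$grade["gATP"]), "very good")
  expect_identical(unname(cmp$mean_cv["PCr"]), 0)
  # identical inputs: CV 0 everywhere
  same <- compare_methods(a, a)
  expect_true(all(same$mean_cv == 0))
  # grade thresholds
  expect_identical(grade_agreement(c(5, 15, 25, 37)),
                   c("very good", "good", "acceptable", "not acceptable"))
  expect_error(compare_methods(a, list(c(PCr = 1, foo = 2))), "mismatch")
})
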