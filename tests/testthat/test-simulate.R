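test_that("axis geometry: dwell, ppm span, invertible mapping", {
  ax <- make_axis(2048, 1000, 49.9)
  expect_equal(ax$dwell_s, 1e-3)
  expect_equal(diff(range(ax$ppm)), (1000 / 49.9) * (2047 / 2048))
  # ppm decreases with index (plots read high-to-low left to right)
  expect_true(all(diff(ax$ppm) < 0))
  # minimal case
  ax2 <- make_axis(2, 1000, 49.9)
  expect_identical(ax2$n_points, 2L)
  expect_equal(ax2$dwell_s, 1e-3)
  # hand-derived span for doubled bandwidth
  ax3 <- make_axis(2048, 2000, 49.9)
  expect_equal(diff(range(ax3$ppm)), (2000 / 49.9) * (2047 / 2048))
  expect_error(make_axis(0, 1000, 49.9))
  expect_error(make_axis(2048, -1, 49.9))
})

test_that("transform contract: freq is the halved-first-point DFT of fid", {
  s <- simulate_signal(registry_row("PCr"), fix_axis, fwhm_hz = 2)
  # independent brute-force DFT at a handful of bins
  n <- fix_axis$n_points
  x <- s$fid; x[1] <- x[1] / 2
  k_asc <- seq.int(-n / 2, n / 2 - 1)
  for (j in c(1L, 5L, 1024L, 1025L, 2048L)) {
    k <- k_asc[n + 1L - j]   # freq[j] corresponds to descending ppm
    brute <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    expect_lt(Mod(s$freq[j] - brute), 1e-10 * max(Mod(s$freq)))
  }
  # invertible
  expect_equal(phosfit:::spec_ifft(s$freq, fix_axis), s$fid,
               tolerance = 1e-12)
  # pure Lorentzian gives an absorption spectrum with no baseline offset:
  # real part far from the line is ~0, not a constant pedestal
  far <- abs(s$axis$ppm) > 8
  expect_lt(max(abs(Re(s$freq[far]))), 1e-3 * max(Re(s$freq)))
})

test_that("singlet peak lands within one grid step of the requested shift", {
  sigs <- basis_signals(fix_reg)
  step <- fine_axis$bandwidth_hz / fine_axis$n_points / fine_axis$larmor_mhz
  for (i in seq_len(nrow(sigs))) {
    row <- sigs[i, ]
    row$multiplicity <- "s"  # force singlet: position oracle only
    s <- simulate_signal(row, fine_axis, fwhm_hz = 1)
    pk <- fine_axis$ppm[which.max(Re(s$freq))]
    expect_lt(abs(pk - row$shift_basisp), step * 1.01)
  }
})

test_that("multiplet structure and decoupling behaviour follow the registry", {
  # triplet collapses to singlet under decoupling (P-H coupling removed)
  pe <- registry_row("PE")
  expect_identical(count_peaks(simulate_signal(pe, fine_axis)), 3L)
  expect_identical(count_peaks(simulate_signal(pe, fine_axis,
                                               decoupled = TRUE)), 1L)
  # oxidized NAD reshapes from unresolved singlet to resolved doublet
  nad <- registry_row("NAD+")
  expect_identical(count_peaks(simulate_signal(nad, fine_axis)), 1L)
  expect_identical(count_peaks(simulate_signal(nad, fine_axis,
                                               decoupled = TRUE)), 2L)
  # P-P coupled doublet unaffected by proton decoupling
  g_atp <- registry_row("gATP")
  expect_identical(count_peaks(simulate_signal(g_atp, fine_axis)), 2L)
  expect_identical(count_peaks(simulate_signal(g_atp, fine_axis,
                                               decoupled = TRUE)), 2L)
})

test_that("full decoupling truth table over the registry", {
  collapse <- c("PE", "PC", "G1P", "G6P", "GPC", "DPG2", "DPG3")
  unchanged_multiplets <- c("aATP", "bATP", "gATP", "UDPG_a", "UDPG_b")
  always_singlet <- c("PCr", "Pi", "PEP", "NADH", "MP", "GPE")
  lines_of <- function(m) switch(m, s = 1L, d = 2L, t = 3L)
  for (lab in collapse) {
    row <- registry_row(lab)
    s0 <- simulate_signal(row, fine_axis, variant = "basisp")
    s1 <- simulate_signal(row, fine_axis, variant = "basisp",
                          decoupled = TRUE)
    expect_identical(count_peaks(s0), lines_of(row$multiplicity),
                     label = paste(lab, "coupled"))
    expect_identical(count_peaks(s1), 1L, label = paste(lab, "decoupled"))
  }
  for (lab in unchanged_multiplets) {
    row <- registry_row(lab)
    expect_identical(count_peaks(simulate_signal(row, fine_axis)),
                     count_peaks(simulate_signal(row, fine_axis,
                                                 decoupled = TRUE)),
                     label = lab)
  }
  for (lab in always_singlet) {
    row <- registry_row(lab)
    expect_identical(count_peaks(simulate_signal(row, fine_axis)), 1L,
                     label = lab)
    expect_identical(count_peaks(simulate_signal(row, fine_axis,
                                                 decoupled = TRUE)), 1L,
                     label = lab)
  }
})

test_that("doublet splitting in ppm equals J / larmor", {
  g_atp <- registry_row("gATP")   # J = 19.0 Hz
  s <- simulate_signal(g_atp, fine_axis, fwhm_hz = 1)
  pks <- sort(peak_ppms(s, frac = 0.4)[1:2])
  expect_equal(diff(pks), 19.0 / 49.9, tolerance = 2e-3)
})

test_that("integrated area is amplitude-proportional, independent of
           multiplicity, J and decoupling", {
  area <- function(s) sum(Re(s$freq))
  amp <- 3.7
  ref <- area(simulate_signal(registry_row("PCr"), fix_axis, fwhm_hz = 1,
                              amplitude = amp))
  for (lab in c("PE", "gATP", "bATP", "UDPG_a", "NAD+")) {
    for (dec in c(FALSE, TRUE)) {
      a <- area(simulate_signal(registry_row(lab), fix_axis, fwhm_hz = 1,
                                amplitude = amp, decoupled = dec))
      expect_equal(a, ref, tolerance = 5e-3, label = paste(lab, dec))
    }
  }
  # proportional to amplitude
  a2 <- area(simulate_signal(registry_row("PE"), fix_axis, fwhm_hz = 1,
                             amplitude = 2 * amp))
  expect_equal(a2, 2 * ref, tolerance = 5e-3)
})

test_that("basis construction: membership, order, MP broad, determinism", {
  expect_identical(fix_basis$labels, basis_signals(fix_reg)$label)
  expect_false(any(grepl("ADP", fix_basis$labels)))
  expect_identical(sum(fix_basis$labels %in% c("aATP", "bATP", "gATP")), 3L)
  expect_identical(fix_basis$fwhm_hz[fix_basis$labels == "MP"], 5)
  b_over <- build_basis(fix_reg, fix_axis, fwhm_hz = 1,
                        overrides = list(MP = 2))
  expect_identical(b_over$fwhm_hz[b_over$labels == "MP"], 2)
  b2 <- build_basis(fix_reg, fix_axis, decoupled = FALSE, fwhm_hz = 1)
  expect_identical(b2$members$PCr$fid, fix_basis$members$PCr$fid)

  # decoupled basis keeps the UDPG doublets (P-P coupling, J = 10 Hz)
  bd <- build_basis(fix_reg, fine_axis, decoupled = TRUE, fwhm_hz = 1)
  u <- bd$members$UDPG_b
  pks <- sort(peak_ppms(u, frac = 0.4)[1:2])
  expect_equal(diff(pks), 10.0 / 49.9, tolerance = 2e-3)
})

test_that("combine_spectra: linearity, identity, seeded determinism", {
  x <- simulate_signal(registry_row("PCr"), fix_axis, fwhm_hz = 2)
  y <- simulate_signal(registry_row("Pi"), fix_axis, fwhm_hz = 2)
  lin <- combine_spectra(list(x, y), c(2, 3))
  expect_equal(lin$fid, 2 * x$fid + 3 * y$fid, tolerance = 1e-12)
  expect_equal(lin$freq, 2 * x$freq + 3 * y$freq, tolerance = 1e-12)
  ident <- combine_spectra(list(x), 1)
  expect_identical(ident$fid, x$fid)
  n1 <- combine_spectra(list(x), 1, noise_sd = 0.1, seed = 42)
  n2 <- combine_spectra(list(x), 1, noise_sd = 0.1, seed = 42)
  expect_identical(n1$fid, n2$fid)
  n3 <- combine_spectra(list(x), 1, noise_sd = 0.1, seed = 43)
  expect_false(identical(n3$fid, n1$fid))
  # axis mismatch is structural
  z <- simulate_signal(registry_row("PCr"), make_axis(1024, 2000, 49.9))
  expect_error(combine_spectra(list(x, z)), "axis mismatch")
})
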