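# Shared fixtures, built once per test run.  The wide axis spans ~40 ppm so
# the beta-ATP resonance at -16.18 ppm is on-axis.
fix_reg <- load_registry()
fix_axis <- make_axis(2048, 2000, 49.9)
fix_basis <- build_basis(fix_reg, fix_axis, decoupled = FALSE, fwhm_hz = 1)

# fine axis for peak-location oracles (0.122 Hz grid step)
fine_axis <- make_axis(16384, 2000, 49.9)

# count resolved peaks of a simulated signal: local maxima above a fraction
# of the tallest, on the real (absorption) channel
count_peaks <- function(spec, frac = 0.15) {
  y <- Re(spec$freq)
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  sum(y[idx] >= frac * max(y))
}

# ppm positions of resolved peaks (parabolic three-point refinement),
# tallest first
peak_ppms <- function(spec, frac = 0.15) {
  y <- Re(spec$freq)
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[y[idx] >= frac * max(y)]
  idx <- idx[order(-y[idx])]
  vapply(idx, function(i) phosfit:::refine_peak_ppm(y, spec$axis$ppm, i),
         numeric(1))
}

registry_row <- function(label, registry = fix_reg) {
  row <- registry$components[registry$components$label == label, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  row
}
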