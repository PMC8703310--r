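#' Construct a spectral axis
#'
#' Defines the sampling of a \eqn{^{31}}P acquisition and the affine
#' Hz-to-ppm mapping. The dwell time is `1/bandwidth_hz` and the ppm span is
#' `bandwidth_hz / larmor_mhz` (a MHz transmitter frequency gives Hz per
#' ppm). The stored ppm grid is monotone decreasing with array index, so
#' spectra plot high-to-low ppm left to right as is conventional.
#'
#' Defaults mirror a 3 T FID protocol: 2048 complex points over a 1000 Hz
#' bandwidth (about 20 ppm) at a 49.9 MHz phosphorus transmitter frequency,
#' with the reference (PCr) on-resonance at 0 ppm.
#'
#' @param n_points Number of complex points (>= 2; powers of two recommended).
#' @param bandwidth_hz Spectral bandwidth in Hz (> 0).
#' @param larmor_mhz Transmitter frequency in MHz (> 0).
#' @param reference_ppm ppm value at zero frequency offset (default 0).
#' @param acquisition_delay_ms Dead time before the first sample (default 0;
#'   kept as metadata, not applied by the simulator).
#' @return An object of class `phos_axis`.
#' @examples
#' ax <- make_axis(2048, 1000, 49.9)
#' diff(range(ax$ppm))  # ~20.03 ppm span
#' @export
make_axis <- function(n_points = 2048, bandwidth_hz = 1000,
                      larmor_mhz = 49.9, reference_ppm = 0,
                      acquisition_delay_ms = 0) {
  if (!is.numeric(n_points) || n_points < 2 || n_points != round(n_points))
    stop("n_points must be an integer >= 2")
  if (bandwidth_hz <= 0 || larmor_mhz <= 0)
    stop("bandwidth_hz and larmor_mhz must be positive")
  n <- as.integer(n_points)
  dwell <- 1 / bandwidth_hz
  # frequency grid after shifting DC to the centre; ascending in Hz
  k <- seq.int(-floor(n / 2), ceiling(n / 2) - 1)
  hz_asc <- k * bandwidth_hz / n
  ppm_asc <- reference_ppm + hz_asc / larmor_mhz
  ax <- list(n_points = n, bandwidth_hz = bandwidth_hz,
             larmor_mhz = larmor_mhz, reference_ppm = reference_ppm,
             acquisition_delay_ms = acquisition_delay_ms,
             dwell_s = dwell,
             time_s = (seq_len(n) - 1) * dwell,
             ppm = rev(ppm_asc),        # index 1 = highest ppm
             hz = rev(hz_asc))
  class(ax) <- "phos_axis"
  ax
}

#' @export
print.phos_axis <- function(x, ...) {
  cat(sprintf("<phos_axis> %d pts, %.6g Hz bandwidth, %.6g MHz (%.4g ppm span)\n",
              x$n_points, x$bandwidth_hz, x$larmor_mhz,
              x$bandwidth_hz / x$larmor_mhz))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$bandwidth_hz - b$bandwidth_hz) < tol &&
    abs(a$larmor_mhz - b$larmor_mhz) < tol &&
    abs(a$reference_ppm - b$reference_ppm) < tol
}

# Transform contract: the first time-domain point is halved before the DFT so
# a one-sided Lorentzian FID transforms to an offset-free absorption line;
# the output is reordered to match axis$ppm (monotone decreasing).
spec_fft <- function(fid, axis) {
  n <- axis$n_points
  stopifnot(length(fid) == n)
  x <- fid
  x[1] <- x[1] / 2
  f <- stats::fft(x)
  # fft bin order: 0, +1, ..., +(n-ceil(n/2)-1), then negative frequencies
  nneg <- floor(n / 2)
  asc <- c(f[(n - nneg + 1):n], f[1:(n - nneg)])  # ascending Hz
  rev(asc)
}

spec_ifft <- function(freq, axis) {
  n <- axis$n_points
  stopifnot(length(freq) == n)
  asc <- rev(freq)
  nneg <- floor(n / 2)
  f <- c(asc[(nneg + 1):n], asc[1:nneg])
  x <- stats::fft(f, inverse = TRUE) / n
  x[1] <- x[1] * 2
  x
}

#' Build a spectrum object from a time-domain FID
#'
#' @param fid Complex vector of length `axis$n_points`.
#' @param axis A `phos_axis`.
#' @param provenance Named list of free-form metadata.
#' @return An object of class `phos_spectrum` holding both domains; `freq` is
#'   the DFT of `fid` under the package transform contract.
#' @export
as_spectrum <- function(fid, axis, provenance = list()) {
  stopifnot(inherits(axis, "phos_axis"), length(fid) == axis$n_points)
  s <- list(axis = axis, fid = as.complex(fid),
            freq = spec_fft(as.complex(fid), axis),
            provenance = provenance)
  class(s) <- "phos_spectrum"
  s
}

#' @export
print.phos_spectrum <- function(x, ...) {
  cat(sprintf("<phos_spectrum> %d pts, %.6g Hz bw, %.6g MHz", x$axis$n_points,
              x$axis$bandwidth_hz, x$axis$larmor_mhz))
  if (length(x$provenance))
    cat(" [", paste(names(x$provenance), collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Weighted combination of spectra with optional seeded noise
#'
#' Forms the weighted complex sum of the member FIDs and, if requested, adds
#' i.i.d. complex Gaussian noise (`noise_sd` per real/imaginary channel per
#' time point) generated from `seed`. The seed is recorded in the result's
#' provenance, so a combination is bit-reproducible.
#'
#' @param members List of `phos_spectrum` sharing one axis.
#' @param weights Numeric weights, recycled to `length(members)`.
#' @param noise_sd Optional time-domain noise standard deviation per channel.
#' @param seed Optional integer seed used when `noise_sd` is given.
#' @return A `phos_spectrum`.
#' @export
combine_spectra <- function(members, weights = 1, noise_sd = NULL,
                            seed = NULL) {
  stopifnot(length(members) >= 1)
  axis <- members[[1]]$axis
  for (m in members)
    if (!axes_equal(axis, m$axis)) stop("combine_spectra: axis mismatch")
  weights <- rep_len(weights, length(members))
  fid <- Reduce(`+`, Map(function(m, w) w * m$fid, members, weights))
  prov <- list(combined = length(members))
  if (!is.null(noise_sd) && noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    n <- axis$n_points
    fid <- fid + complex(real = stats::rnorm(n, 0, noise_sd),
                         imaginary = stats::rnorm(n, 0, noise_sd))
    prov$noise_sd <- noise_sd
    prov$seed <- seed
  }
  as_spectrum(fid, axis, prov)
}
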