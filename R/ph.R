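#' Henderson-Hasselbalch calibration for the Pi chemical shift
#'
#' The intracellular pH probe in \eqn{^{31}}P MRS is the chemical-shift
#' difference \eqn{\delta} between inorganic phosphate and phosphocreatine,
#' governed by the HPO4(2-)/H2PO4(-) equilibrium:
#' \deqn{pH = pK_a + \log_{10}\frac{\delta - \delta_{acid}}{\delta_{base} - \delta}}
#' with defaults \eqn{pK_a = 6.75}, \eqn{\delta_{acid} = 3.27} ppm,
#' \eqn{\delta_{base} = 5.63} ppm. `log` is base 10.
#'
#' @param pka Acid dissociation constant of the probe.
#' @param delta_acid,delta_base Limiting shifts of the fully protonated /
#'   deprotonated forms, ppm.
#' @return A `phos_ph_cal` list.
#' @export
ph_calibration <- function(pka = 6.75, delta_acid = 3.27, delta_base = 5.63) {
  stopifnot(is.finite(pka), delta_acid < delta_base)
  structure(list(pka = pka, delta_acid = delta_acid, delta_base = delta_base),
            class = "phos_ph_cal")
}

#' pH from the Pi-PCr shift difference
#'
#' @param delta Shift difference in ppm; must lie strictly inside
#'   `(delta_acid, delta_base)`. A value outside signals a mis-referenced
#'   spectrum and raises an error stating the valid range.
#' @param calibration A [ph_calibration()].
#' @return pH value(s).
#' @examples
#' ph_from_shift(4.78)   # ~7.00
#' ph_from_shift(4.45)   # 6.75, the titration midpoint
#' @export
ph_from_shift <- function(delta, calibration = ph_calibration()) {
  c0 <- calibration
  if (any(delta <= c0$delta_acid | delta >= c0$delta_base))
    stop(sprintf(
      "shift difference %.4g ppm outside the calibrated open interval (%g, %g)",
      delta[which(delta <= c0$delta_acid | delta >= c0$delta_base)[1]],
      c0$delta_acid, c0$delta_base))
  c0$pka + log10((delta - c0$delta_acid) / (c0$delta_base - delta))
}

#' Pi-PCr shift difference expected at a given pH
#'
#' Closed-form inverse of [ph_from_shift()]; saturates asymptotically at the
#' calibration bounds, so any finite pH maps strictly inside them.
#'
#' @param ph pH value(s), finite.
#' @inheritParams ph_from_shift
#' @return Shift difference in ppm.
#' @examples
#' shift_from_ph(7.0)   # ~4.78
#' @export
shift_from_ph <- function(ph, calibration = ph_calibration()) {
  stopifnot(all(is.finite(ph)))
  c0 <- calibration
  r <- 10^(ph - c0$pka)
  (c0$delta_acid + c0$delta_base * r) / (1 + r)
}

# Local maxima of a numeric vector (strict neighbours), returned as indices.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Three-point parabolic refinement of a peak position on the ppm grid.
refine_peak_ppm <- function(mag, ppm, idx) {
  if (idx <= 1L || idx >= length(mag)) return(ppm[idx])
  y1 <- mag[idx - 1]; y2 <- mag[idx]; y3 <- mag[idx + 1]
  den <- y1 - 2 * y2 + y3
  d <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / den
  ppm[idx] + d * (ppm[idx + 1] - ppm[idx])  # ppm grid is uniform
}

# Largest refined peak of the magnitude spectrum inside a ppm window.
# The magnitude is first smoothed with a short running mean (about one
# typical in vivo linewidth) so that noise riding on a broad flat-topped
# line does not pull the apparent maximum sideways; symmetric smoothing
# does not shift a symmetric peak.
find_peak <- function(spectrum, window, min_prominence, label,
                      smooth_bins = NULL) {
  ppm <- spectrum$axis$ppm
  mag <- Mod(spectrum$freq)
  if (is.null(smooth_bins)) {
    # matched to the tallest peak's apparent full width at half maximum
    pk <- which.max(mag)
    half <- mag[pk] / 2
    lo <- pk; while (lo > 1 && mag[lo] > half) lo <- lo - 1
    hi <- pk; while (hi < length(mag) && mag[hi] > half) hi <- hi + 1
    smooth_bins <- max(3L, min(31L, hi - lo))
  }
  # an even-length running mean would shift the whole grid by half a bin
  if (smooth_bins %% 2L == 0L) smooth_bins <- smooth_bins + 1L
  if (smooth_bins > 1L) {
    kern <- rep(1 / smooth_bins, smooth_bins)
    mag <- stats::filter(mag, kern, sides = 2)
    mag[is.na(mag)] <- 0
    mag <- as.numeric(mag)
  }
  inside <- which(ppm >= window[1] & ppm <= window[2])
  if (!length(inside)) stop("signal '", label, "' search window off-axis")
  cand <- intersect(local_maxima(mag), inside)
  cand <- cand[mag[cand] >= min_prominence * max(mag)]
  if (!length(cand))
    stop("signal '", label, "' not detected in [", window[1], ", ",
         window[2], "] ppm")
  best <- cand[which.max(mag[cand])]
  refine_peak_ppm(mag, ppm, best)
}

#' Estimate pH from a spectrum
#'
#' Locates the reference (default PCr) and probe (default Pi) peak maxima of
#' the magnitude spectrum, refines each by three-point parabolic
#' interpolation, and applies [ph_from_shift()] to their ppm difference.
#' The probe is searched inside the calibration's open shift interval
#' (relative to the reference), the reference within 1 ppm of its registry
#' fitting-basis shift.
#'
#' @param spectrum A `phos_spectrum`.
#' @param reference_label,probe_label Registry signal labels.
#' @param calibration A [ph_calibration()].
#' @param min_prominence Minimum peak height as a fraction of the global
#'   magnitude maximum (default 0.02); an undetected peak raises an error
#'   naming the missing signal.
#' @param registry Registry used to locate the reference search window.
#' @return pH estimate (with the shift difference used as attribute
#'   `"delta_ppm"`).
#' @export
ph_from_spectrum <- function(spectrum, reference_label = "PCr",
                             probe_label = "Pi",
                             calibration = ph_calibration(),
                             min_prominence = 0.02,
                             registry = load_registry()) {
  stopifnot(inherits(spectrum, "phos_spectrum"))
  ref_shift <- shift_variant(registry, "basisp", label = reference_label)
  ref_ppm <- find_peak(spectrum, ref_shift + c(-1, 1), min_prominence,
                       reference_label)
  probe_win <- ref_ppm + c(calibration$delta_acid, calibration$delta_base)
  probe_ppm <- find_peak(spectrum, probe_win, min_prominence, probe_label)
  delta <- probe_ppm - ref_ppm
  ph <- ph_from_shift(delta, calibration)
  attr(ph, "delta_ppm") <- delta
  ph
}
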