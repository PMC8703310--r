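#' Tissue and phantom presets for the synthetic generator
#'
#' A preset is a stated ground truth: relative signal amplitudes over a set
#' of registry labels, a target pH (placing the Pi resonance via
#' [shift_from_ph()]), a linewidth, a peak signal-to-noise ratio and a
#' decoupling flag.
#'
#' `muscle_preset()` and `liver_preset()` carry the six-signal relative
#' intensities of resting calf muscle and liver as quantified by time-domain
#' fitting of the reference cohort (muscle: gamma-ATP 12.4, alpha-ATP 10.3,
#' beta-ATP 10.0, GPC 2.6, PCr 60.2, Pi 4.4 percent; liver: 23.3, 26.9,
#' 13.4, 21.6, 2.5, 12.3 percent, the small PCr being contamination from
#' overlying tissue). Default linewidths are 5 Hz (muscle) and 15 Hz
#' (liver, visibly broader in vivo); default peak SNR 50.
#'
#' @param ph Target pH controlling the Pi shift.
#' @param linewidth_hz Lorentzian FWHM applied to every signal.
#' @param snr Peak SNR of the tallest signal (see [generate_spectrum()]).
#' @param decoupled Logical; simulate under proton decoupling.
#' @return A `phos_preset` list with `name`, `ground_truth` (named numeric),
#'   `ph`, `linewidth_hz`, `snr`, `decoupled`.
#' @export
muscle_preset <- function(ph = 7.0, linewidth_hz = 5, snr = 50,
                          decoupled = FALSE) {
  new_preset("muscle",
             c(gATP = 12.4, aATP = 10.3, bATP = 10.0, GPC = 2.6,
               PCr = 60.2, Pi = 4.4),
             ph, linewidth_hz, snr, decoupled)
}

#' @rdname muscle_preset
#' @export
liver_preset <- function(ph = 7.0, linewidth_hz = 15, snr = 50,
                         decoupled = FALSE) {
  new_preset("liver",
             c(gATP = 23.3, aATP = 26.9, bATP = 13.4, GPC = 21.6,
               PCr = 2.5, Pi = 12.3),
             ph, linewidth_hz, snr, decoupled)
}

new_preset <- function(name, ground_truth, ph, linewidth_hz, snr, decoupled) {
  stopifnot(all(ground_truth >= 0), ph > 5.5, ph < 8.5, linewidth_hz > 0)
  structure(list(name = name, ground_truth = ground_truth, ph = ph,
                 linewidth_hz = linewidth_hz, snr = snr,
                 decoupled = decoupled),
            class = "phos_preset")
}

#' Single-metabolite phantom preset
#'
#' Emulates the phantom recipe: the metabolite at 10 mM (2 mM for UDPG and
#' 2,3-DPG), phosphocreatine at 5 mM as internal standard, and phosphate
#' buffer at 40 mM (reduced to 10 mM in the low-concentration phantoms).
#' Signal amplitudes are proportional to concentration times the number of
#' contributing phosphorus nuclei: each registry signal of a metabolite
#' corresponds to one \eqn{^{31}}P nucleus, so every component receives the
#' metabolite concentration.
#'
#' @param metabolite Entry abbreviation; must have a phantom concentration
#'   (the literature-only MP and GPE entries are rejected).
#' @param ph Phantom pH; sets the Pi shift.
#' @param registry A `phos_registry`.
#' @param linewidth_hz,snr,decoupled As in [muscle_preset()]; phantom lines
#'   are narrow (default 1.5 Hz).
#' @return A `phos_preset`.
#' @examples
#' phantom_preset("G6P", 7.0)$ground_truth  # G6P 10, PCr 5, Pi 40
#' @export
phantom_preset <- function(metabolite, ph = 7.0, registry = load_registry(),
                           linewidth_hz = 1.5, snr = 200, decoupled = FALSE) {
  ent <- registry$entries[[metabolite]]
  if (is.null(ent)) stop("unknown metabolite: ", metabolite)
  if (is.na(ent$phantom_mm))
    stop(metabolite, " is a literature-only entry with no phantom recipe")
  gt <- numeric()
  for (i in seq_len(nrow(ent$components)))
    gt[ent$components$label[i]] <- ent$phantom_mm
  if (!"PCr" %in% names(gt)) gt["PCr"] <- 5
  gt["Pi"] <- if (metabolite == "Pi") ent$phantom_mm else ent$buffer_mm
  new_preset(paste0("phantom:", metabolite), gt, ph, linewidth_hz, snr,
             decoupled)
}

#' Generate a synthetic spectrum with known ground truth
#'
#' Builds one simulated signal per preset label at its fitting-basis
#' chemical shift (the Pi resonance overridden by the preset pH through the
#' Henderson-Hasselbalch calibration), applies the preset linewidth,
#' optionally a zero/first-order phase, sums them, and adds seeded complex
#' Gaussian time-domain noise scaled so that the tallest peak magnitude over
#' the frequency-domain noise SD equals the preset SNR. The frequency-domain
#' per-channel noise SD of time-domain noise with per-channel SD
#' \eqn{\sigma_t} is \eqn{\sigma_t \sqrt{n}} under the package transform, so
#' \eqn{\sigma_t = peak / (SNR \sqrt{n})}.
#'
#' @param preset A `phos_preset`.
#' @param axis A `phos_axis`. The default spans about 40 ppm so that the
#'   beta-ATP resonance at -16.18 ppm is on-axis.
#' @param seed Integer seed for the noise (recorded in provenance).
#' @param registry A `phos_registry`.
#' @param phase0_deg,phase1_deg_ppm Optional phase applied to the clean
#'   signal (default 0), for exercising phase fitting.
#' @return A list with `spectrum` (`phos_spectrum`) and `truth` (list:
#'   amplitudes, ph, pi_shift_ppm, linewidth_hz, snr, noise_sd, phases,
#'   seed).
#' @export
generate_spectrum <- function(preset, axis = make_axis(2048, 2000, 49.9),
                              seed = 1, registry = load_registry(),
                              phase0_deg = 0, phase1_deg_ppm = 0) {
  stopifnot(inherits(preset, "phos_preset"), inherits(axis, "phos_axis"))
  comps <- registry$components
  pi_shift <- shift_from_ph(preset$ph)
  members <- list()
  for (lab in names(preset$ground_truth)) {
    row <- comps[comps$label == lab, , drop = FALSE]
    if (nrow(row) != 1L) stop("unknown signal label in preset: ", lab)
    # place at the fitting-basis shift, falling back to the pH-7 phantom
    # shift for signals outside the basis (e.g. ADP phantoms)
    variant <- if (!is.na(row$shift_basisp)) "basisp" else "ph70"
    if (lab == "Pi") { row$shift_basisp <- pi_shift; variant <- "basisp" }
    members[[lab]] <- simulate_signal(row, axis, variant = variant,
                                      decoupled = preset$decoupled,
                                      fwhm_hz = preset$linewidth_hz,
                                      amplitude = preset$ground_truth[[lab]])
  }
  clean <- combine_spectra(members, 1)
  if (phase0_deg != 0 || phase1_deg_ppm != 0) {
    phw <- (phase0_deg + phase1_deg_ppm * axis$ppm) * pi / 180
    clean <- as_spectrum(spec_ifft(clean$freq * exp(1i * phw), axis), axis)
  }
  peak <- max(Mod(clean$freq))
  noise_sd_t <- if (is.finite(preset$snr) && preset$snr > 0)
    peak / (preset$snr * sqrt(axis$n_points)) else 0
  sp <- if (noise_sd_t > 0)
    combine_spectra(list(clean), 1, noise_sd = noise_sd_t, seed = seed)
  else clean
  sp$provenance$preset <- preset$name
  sp$provenance$decoupled <- preset$decoupled
  list(spectrum = sp,
       truth = list(amplitudes = preset$ground_truth, ph = preset$ph,
                    pi_shift_ppm = pi_shift,
                    linewidth_hz = preset$linewidth_hz, snr = preset$snr,
                    noise_sd_time = noise_sd_t,
                    noise_sd_freq = noise_sd_t * sqrt(axis$n_points),
                    phase0_deg = phase0_deg,
                    phase1_deg_ppm = phase1_deg_ppm, seed = seed))
}
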