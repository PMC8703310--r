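# First-order multiplet line lists.  Offsets in Hz about the centre shift,
# binomial weights normalized to sum 1 so total time-zero amplitude (and hence
# integrated area) is independent of multiplicity.
multiplet_lines <- function(multiplicity, j_hz) {
  switch(multiplicity,
         s = list(off = 0, w = 1),
         d = list(off = c(-j_hz / 2, j_hz / 2), w = c(0.5, 0.5)),
         t = list(off = c(-j_hz, 0, j_hz), w = c(0.25, 0.5, 0.25)),
         stop("unsupported multiplicity: ", multiplicity))
}

#' Simulate one metabolite signal
#'
#' Produces the complex FID of a first-order multiplet as a sum of
#' exponentially damped complex sinusoids: one line per multiplet peak at the
#' centre shift plus or minus J-coupling offsets (doublet split J, weights
#' 1:1; triplet lines at -J, 0, +J, weights 1:2:1), each damped at rate
#' `pi * fwhm_hz` (pure Lorentzian lineshape). Weights are normalized so the
#' time-zero amplitude equals `amplitude` regardless of multiplicity.
#'
#' Proton decoupling collapses P-H coupled multiplets to a singlet at the
#' centre shift; P-P couplings are unaffected. The oxidized NAD resonance is
#' special-cased per its registry record: an unresolved singlet when coupled
#' that becomes a resolved doublet under decoupling.
#'
#' @param component One signal row from the registry.
#' @param axis A `phos_axis`.
#' @param variant Chemical-shift variant to place the signal at.
#' @param decoupled Logical; proton decoupling on.
#' @param fwhm_hz Lorentzian full width at half maximum in Hz (> 0).
#' @param amplitude Total time-zero amplitude.
#' @return A `phos_spectrum`.
#' @examples
#' reg <- load_registry()
#' pe <- basis_signals(reg, include = "PE")
#' s <- simulate_signal(pe, make_axis(), decoupled = TRUE)
#' @export
simulate_signal <- function(component, axis, variant = "basisp",
                            decoupled = FALSE, fwhm_hz = 1, amplitude = 1) {
  stopifnot(inherits(axis, "phos_axis"), fwhm_hz > 0)
  if (is.data.frame(component)) {
    stopifnot(nrow(component) == 1L)
    component <- as.list(component)
  }
  centre <- shift_variant(component, variant)
  mult <- effective_multiplicity(component, decoupled)
  j <- if (mult == "s") 0 else component$j_hz
  lines <- multiplet_lines(mult, j)
  t <- axis$time_s
  f0 <- (centre - axis$reference_ppm) * axis$larmor_mhz  # Hz per ppm
  fid <- complex(real = numeric(axis$n_points))
  for (k in seq_along(lines$off)) {
    fid <- fid + lines$w[k] *
      exp((2i * pi * (f0 + lines$off[k]) - pi * fwhm_hz) * t)
  }
  as_spectrum(amplitude * fid, axis,
              provenance = list(label = component$label, variant = variant,
                                decoupled = decoupled, fwhm_hz = fwhm_hz,
                                amplitude = amplitude))
}

#' Build a fitting basis set
#'
#' Simulates one model spectrum per basis-eligible signal at its
#' fitting-basis chemical shift on a common axis. The three ATP resonances
#' enter as three independent members. Membrane phospholipids (MP) are
#' modeled as a broad singlet, by default five times the basis linewidth.
#'
#' @param registry A `phos_registry`.
#' @param axis A `phos_axis`.
#' @param decoupled Logical; simulate under proton decoupling.
#' @param fwhm_hz Basis linewidth in Hz (default 1, narrow phantom lines).
#' @param overrides Named list `label -> fwhm_hz` of per-signal linewidth
#'   overrides.
#' @param include,exclude Passed to [basis_signals()].
#' @return An object of class `phos_basis`: list with `axis`, `members`
#'   (list of `phos_spectrum`), `labels`, `shifts_ppm`, `fwhm_hz`,
#'   `decoupled`, `registry_version`.
#' @examples
#' b <- build_basis(load_registry(), make_axis(2048, 2000, 49.9))
#' b$labels
#' @export
build_basis <- function(registry, axis, decoupled = FALSE, fwhm_hz = 1,
                        overrides = list(), include = NULL, exclude = NULL) {
  sigs <- basis_signals(registry, include = include, exclude = exclude)
  mp_factor <- 5
  members <- vector("list", nrow(sigs))
  widths <- numeric(nrow(sigs))
  for (i in seq_len(nrow(sigs))) {
    lab <- sigs$label[i]
    w <- if (!is.null(overrides[[lab]])) overrides[[lab]]
         else if (identical(lab, "MP")) mp_factor * fwhm_hz
         else fwhm_hz
    widths[i] <- w
    members[[i]] <- simulate_signal(sigs[i, ], axis, variant = "basisp",
                                    decoupled = decoupled, fwhm_hz = w,
                                    amplitude = 1)
  }
  names(members) <- sigs$label
  b <- list(axis = axis, members = members, labels = sigs$label,
            shifts_ppm = sigs$shift_basisp, fwhm_hz = widths,
            decoupled = decoupled, registry_version = registry$version,
            signals = sigs)
  class(b) <- "phos_basis"
  b
}

#' @export
print.phos_basis <- function(x, ...) {
  cat(sprintf("<phos_basis> %d members, %s, fwhm %s Hz\n", length(x$members),
              if (x$decoupled) "1H-decoupled" else "coupled",
              paste(unique(x$fwhm_hz), collapse = "/")))
  print(data.frame(label = x$labels, shift_ppm = x$shifts_ppm,
                   fwhm_hz = x$fwhm_hz))
  invisible(x)
}
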