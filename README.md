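# phosfit

Quantification toolkit for in vivo phosphorus-31 magnetic resonance
spectroscopy (³¹P MRS) at clinical field strength, for spectroscopists and
methods developers who need a complete, testable chain from prior knowledge
to fitted metabolite intensities without any scanner data.

³¹P spectra of muscle and liver contain, besides the prominent PCr, ATP and
Pi resonances, a crowded 2–8 ppm region of phosphomonoesters and
phosphodiesters (PE, PC, G1P, G6P, GPC, GPE, PEP, PtdC, NAD⁺/NADH, UDPG,
membrane phospholipids). Quantifying them requires a basis of model spectra
built from phantom-measured chemical shifts, multiplicities and J-couplings.
phosfit provides:

* **Registry** — 17 metabolite entries / 22 signals with shifts at pH 7.0
  and 7.5 (37 °C, PCr = 0 ppm), J-couplings, assigned coupling partners,
  and the fitting-basis shifts; 20 signals are basis-eligible (ADP is
  excluded: fully overlapped by α/γ-ATP in vivo).
* **Simulator** — first-order multiplets as damped complex exponentials
  (Lorentzian lines, binomial weights), with a proton-decoupling flag: P–H
  multiplets collapse to singlets, P–P multiplets (ATP, UDPG) persist, and
  NAD⁺ reshapes from an unresolved singlet to a doublet.
* **Linear-combination fit** — frequency-domain model
  `e^{i(φ0+φ1·ppm)} [ Σ a_m B_m(δ_m, γ) + spline baseline ]` with
  nonnegative amplitudes, Gaussian priors on shifts (0.01 ppm) and phases
  (−96° ± 10°, 7 ± 4 °/ppm), exact active-set inner solve and analytic
  envelope gradients; relative intensities and relative Cramér–Rao lower
  bounds per signal.
* **pH** — Henderson–Hasselbalch calibration
  `pH = 6.75 + log10((δ − 3.27)/(5.63 − δ))` for the Pi–PCr shift
  difference, its closed-form inverse, and a peak-picking estimator for
  whole spectra.
* **Synthetic data** — seeded phantom-like and tissue-like generators with
  known ground truth (muscle/liver six-signal presets, phantom recipes),
  so every stage is validated end to end.

## Worked example

```r
library(phosfit)

reg   <- load_registry()
axis  <- make_axis(2048, 2000, 49.9)           # 2048 pts, ~40 ppm at 3 T
basis <- build_basis(reg, axis, fwhm_hz = 1)   # 20 members, ADP excluded

g   <- generate_spectrum(muscle_preset(snr = 50), axis, seed = 42)
fit <- fit_spectrum(g$spectrum, basis)
round(fit$relative_intensities, 1)
#> gATP aATP bATP  GPC  PCr   Pi
#> 11.8 10.1  8.4  3.5 61.6  4.5

ph <- ph_from_spectrum(g$spectrum)
sprintf("pH %.2f (delta %.3f ppm)", ph, attr(ph, "delta_ppm"))
#> "pH 7.06 (delta 4.850 ppm)"
```

(The ~0.06 pH overshoot is a documented property of magnitude-spectrum peak
picking when Pi is a small peak riding on the PCr dispersion tail; see the
methods vignette. Phantom-like spectra recover pH to ±0.03.)

The muscle preset's ground truth is 12.4 / 10.3 / 10.0 / 2.6 / 60.2 / 4.4 %
at pH 7.0; at peak-SNR 50 the fit recovers each percentage within its
reported CRLB-scale uncertainty (the test suite verifies, over 100 seeded
replicates, that ≥ 90 % of major-signal estimates fall within ±3 CRLB of
truth and that empirical scatter matches the reported CRLBs to within
0.8–1.3×). A noiseless fit recovers amplitudes to better than 10⁻⁴
relative.

`print(fit)` also reports the shared extra broadening (here ≈ 4.1 Hz: the
5 Hz synthetic linewidth minus the 1 Hz basis width — Lorentzian widths
add), fitted phases, per-signal shifts, and CRLBs (`NA` for signals clamped
at zero).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/phosfit", package = "phosfit"))')
Rscript $CLI ph --shift 4.78            # pH 7.00 (delta 4.78 ppm)
Rscript $CLI basis --decoupled --out b.basis
Rscript $CLI simulate --preset muscle --seed 1 --out synth
Rscript $CLI fit --spectrum synth.txt --out report
Rscript $CLI compare --a a.json --b b.json
```

Spectra are exchanged as jMRUI-style two-column text or the package's JSON
container; basis sets export in an LCModel-style namelist container or as
per-member jMRUI text.

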