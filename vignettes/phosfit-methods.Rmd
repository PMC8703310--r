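---
title: "phosfit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosfit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfit)
```

# The problem

In vivo phosphorus-31 MR spectroscopy at 3 T resolves the dominant energy
metabolites (PCr, the three ATP resonances, Pi) well, but the
phosphomonoester and phosphodiester regions between roughly 2 and 8 ppm are
crowded with overlapping signals (PE, PC, sugar phosphates, GPC, GPE, PEP,
PtdC, NAD, UDPG, membrane phospholipids). Quantifying them requires prior
knowledge — chemical shifts, multiplicities and J-couplings measured under
near-physiological conditions — assembled into a basis of model spectra that
a linear-combination fit matches against the measured spectrum. phosfit
packages that whole chain: a curated signal registry, a multiplet simulator,
a frequency-domain linear-combination fitter with Cramér–Rao error bounds, a
Henderson–Hasselbalch pH probe, and a seeded synthetic-data generator so
every stage is testable without access to scanner data.

# The metabolite registry

`load_registry()` returns 17 entries covering 22 signals. Each signal stores
its multiplicity (singlet/doublet/triplet), J-coupling in Hz, an assigned
coupling-partner nucleus, and up to five chemical-shift variants: phantom
measurements at pH 7.0 and 7.5 (37 °C, PCr referenced to 0 ppm), an in vivo
reading, a literature basis value, and the fitting-basis value actually used
for analysis. Twenty signals carry a fitting-basis shift; the two ADP
resonances deliberately do not, because in vivo they are completely
overlapped by the far stronger α- and γ-ATP signals and would only
destabilize the fit.

Decisions worth recording:

* **Coupling partners are assigned, not tabulated.** The source table lists
  J values but not which nucleus causes the splitting. We assign *proton*
  to PE, PC, G1P, G6P, GPC, 2,3-DPG and PtdC (their multiplets collapse
  under ^1^H decoupling) and *phosphorus* to ATP, ADP, NAD⁺ and UDPG
  (J ≈ 6–20 Hz P–P couplings, unaffected by ^1^H decoupling).
* **NAD⁺ is special-cased**: an unresolved singlet without decoupling that
  *reshapes into a resolved doublet* (J = 6 Hz) when decoupled. The registry
  stores an explicit decoupled-multiplicity override for it.
* **PtdC has no printed J**; it is stored as a triplet with an assigned
  6.0 Hz proton coupling (typical for a choline headgroup) so that it
  behaves plausibly in both decoupling modes.
* **The 2,3-DPG fitting-basis shifts are stored as printed** (4.05,
  5.32 ppm) even though they differ slightly from the measured pH-7.0
  values (4.09, 5.338): the basis column is authoritative for fitting.
* **PtdC's "pH 7.0" slot** actually holds the value measured at pH 7.21
  (2.14 ppm, ethanol/surfactant solvent); a provenance note records this.
* **Counting ambiguity.** The source material variously counts "19 signals
  of 17 model spectra" and "19 signals of 18 model spectra"; direct counting
  of populated fitting-basis slots gives 20 signals (PEP and PtdC, 0.14 ppm
  apart, are plausibly merged in one of the counts). The registry stores all
  populated slots and makes no guess about the intended count.
* **Sign convention**: shifts left of PCr (ATP, NAD, UDPG region) are
  negative throughout, as in the source table; prose elsewhere sometimes
  quotes them positive.

# Signal simulation

A signal is a sum of exponentially damped complex sinusoids: one line per
multiplet peak at the centre shift ± J offsets with binomial weights
(doublet 1:1 split by J; triplet 1:2:1 at −J, 0, +J), damping rate
π·FWHM — a pure Lorentzian lineshape. Weights are normalized so the
time-zero amplitude (hence the integrated area) is independent of
multiplicity, J and decoupling; amplitude is therefore proportional to the
number of contributing ^31^P nuclei times concentration.

All multiplets are first-order. At 49.9 MHz the couplings (≤ 20 Hz) are far
smaller than the shift differences between coupled partners, so
strong-coupling (second-order) distortions are negligible; no density-matrix
simulation is attempted. Chemical-exchange lineshapes and B₀/B₁
inhomogeneity are likewise out of scope.

The transform contract halves the first FID point before the DFT so a
one-sided Lorentzian transforms to an absorption spectrum with no constant
pedestal, and reorders the output so the ppm axis decreases with index
(spectra read high-to-low ppm left to right). `spec_ifft` inverts it
exactly; the test suite verifies the contract against a brute-force DFT.

Defaults and why:

* **Transmitter frequency 49.9 MHz**: the protocol equates a 1000 Hz
  bandwidth with 20 ppm at 3 T, implying ~50 MHz; we fix the Siemens 3 T
  value 49.9 MHz and expose it as configuration.
* **Axis defaults 2048 points / 1000 Hz** mirror the phantom protocol. The
  synthetic generator defaults to a 2000 Hz bandwidth instead, because the
  β-ATP resonance at −16.18 ppm falls outside a ±10 ppm window; the source
  protocol handled this by moving the transmitter for ATP phantoms, we
  handle it by widening the simulated bandwidth (the in vivo muscle
  protocol it emulates also used 2000 Hz).
* **Basis linewidth 1 Hz FWHM**: the phantom shim achieved 3–4 Hz water
  half-width, so metabolite lines are narrow; the exact width used for the
  original basis is unpublished, and 1 Hz is our engineering choice — extra
  in vivo broadening is a fit parameter, and Lorentzian widths add exactly.
* **Membrane phospholipids (MP)** are a literature-only broad hump; we model
  them as a singlet at 2.3 ppm with 5× the basis linewidth (overridable).
  This width is likewise an engineering choice flagged here.
* **Acquisition delay (TE\* = 0.4 ms) is not applied to the basis**; the
  first-order phase it would induce is handled as a fit parameter. The
  generator can apply explicit phases to test that path.

# pH from the Pi–PCr shift difference

The probe is the pH-dependent Pi shift relative to pH-insensitive PCr:

pH = 6.75 + log₁₀((δ − 3.27)/(5.63 − δ)),  δ in ppm.

"log" is log₁₀ (stated explicitly because source material just writes
"log"). `ph_from_shift()` rejects δ outside the open interval (3.27, 5.63) —
an out-of-range δ signals a mis-referenced spectrum, not an extreme pH. The
inverse `shift_from_ph()` saturates asymptotically at the bounds.
`ph_from_spectrum()` locates the PCr and Pi magnitude maxima with
three-point parabolic refinement (the ~0.01–0.02 ppm grid of a clinical
acquisition is too coarse without it) and applies the calibration. The
phantom pH values were titrated to 7.03 and 7.50; we use the nominal header
values 7.0/7.5 throughout, which agree at one decimal.

Accuracy depends on the probe peak's own SNR, not the spectrum's overall
SNR. In phantom-like spectra (Pi dominant) the estimate is within ±0.03 pH
at realistic noise — this is the setting in which shift-based pH
verification was actually practiced, and the test suite asserts it there.
In tissue-like spectra two effects degrade it. First, Pi is only ~4 % of
the total amplitude (and the liver PCr reference ~2.5 % at 15 Hz
linewidth), so at an overall peak-SNR of 50 the random error is ~0.02 pH
SD for muscle and worse for liver. Second, the dispersion tails of the
dominant PCr line (which fall off as 1/Δ, not 1/Δ² like absorption tails)
interfere coherently with the Pi lineshape and skew the magnitude-spectrum
maximum, a deterministic bias of about +0.03 pH for the muscle preset.
The suite guards the measured tissue behaviour (|bias| < 0.05, worst case
< 0.15 pH) rather than claiming phantom-level accuracy; when the phase is
known, fitting the spectrum and reading the fitted Pi shift is the
accurate alternative.

# The linear-combination fit

The measured complex spectrum over the fit window (default [−20, 10] ppm,
clipped to the axis) is modeled as

D(ν) ≈ e^{i(φ₀ + φ₁·ppm(ν))} · [ Σₘ aₘ Bₘ(ν; δₘ, γ) + baseline(ν) ]

with nonnegative amplitudes aₘ, per-signal frequency adjustments δₘ
(Gaussian prior, SD 0.01 ppm; the reference signal PCr pinned at 0), one
shared extra Lorentzian broadening γ ≥ 0 (applied in the time domain), and
zero/first-order phases with Gaussian priors (−96° ± 10°, 7 ± 4 °/ppm).
These prior means and SDs, the shift SD, and the baseline knot spacing and
regularizer bounds are direct translations of the published control values
for ^31^P analysis. The optimizer itself is our own separable nonlinear
least squares, **not** a clone of any proprietary fitting engine: the
contribution being reproduced is the basis and its configuration, not an
optimizer implementation.

Mechanics: for fixed nonlinear parameters the inner problem (amplitudes +
spline coefficients) is linear and solved exactly by active-set least
squares with nonnegativity on the amplitudes; the outer L-BFGS-B iteration
over (δ, γ, φ₀, φ₁) uses analytic envelope gradients. Because the envelope
gradient vanishes if a grossly wrong phase clamps every amplitude to zero,
φ₀ is first initialized by a coarse 30° grid scan. Initialization is fixed
and documented (shifts 0, γ from the tallest peak's apparent width minus
the basis width, phases at prior means); there is no randomness anywhere in
the fit. Phases are reported wrapped to (−180°, 180°].

The **baseline** is a cubic B-spline per channel (real and imaginary) with
minimum knot spacing 99 ppm — the published "2*99" control value read as
Fortran repeat syntax — which reduces it to one cubic segment across the
window: a deliberately rigid baseline appropriate for FID data with little
macromolecular background. The second-difference penalty weight is chosen
once per fit by generalized cross-validation over a log grid inside the
configured bounds (7.8×10⁻¹⁰ … 3.9×10⁻⁷, applied to the unit-normalized
data). With only four coefficients per channel the choice is nearly
inconsequential, which is the intended behaviour.

The **prior weighting** multiplies the squared prior deviations by the
estimated noise variance, which makes the objective a proper MAP criterion:
for noiseless data the priors vanish and the fit reproduces generating
amplitudes to < 10⁻⁴ relative (tested); for noisy data they regularize
without noticeably biasing high-SNR signals.

**Noise** is estimated as the SD of the real/imaginary channels in a
signal-free window (default 12–18 ppm, outside the fit window; the code
falls back to the outermost high-ppm decile if the window misses the axis).

**CRLBs** come from the Fisher information of the full model — amplitudes,
free shifts, broadening, both phases, and all baseline coefficients — over
the stacked real/imaginary channels, scaled by the noise variance. Reported
per signal as 100·√((F⁻¹)ₘₘ)/aₘ. Amplitudes clamped at zero are reported as
`NA` (the bound is undefined at the constraint); a singular information
matrix falls back to a pseudo-inverse with a warning. The test suite checks
the single-Lorentzian bound against an independent finite-difference oracle
built on the closed-form geometric-series spectrum, and checks Monte-Carlo
calibration (empirical SD / mean CRLB within [0.8, 1.3] over 100 seeded
replicates at SNR 50).

**Relative intensities** are amplitude percentages over a reporting subset,
by default the six prominent signals used in tissue comparisons (γ-, α-,
β-ATP, GPC, PCr, Pi); the published comparison rows sum to ≈100 in both
tissues, from which we infer six-signal normalization was used for liver as
well (PCr kept as contamination) — documented here as an inference.
`compare_methods()` reproduces the published agreement metric: per spectrum
and signal the CV of the two paired estimates (|a−b|/√2 over their mean),
averaged across spectra, graded <10 very good / 10–20 good / 20–30
acceptable / >30 not acceptable.

# The synthetic generator: what it emulates, what it does not

`muscle_preset()` and `liver_preset()` state the six-signal relative
amplitudes published for resting calf muscle (12.4, 10.3, 10.0, 2.6, 60.2,
4.4 %) and liver (23.3, 26.9, 13.4, 21.6, 2.5, 12.3 %; the small PCr is
contamination from overlying tissue) as measured by the time-domain
reference method. Those relative intensities are treated directly as
amplitude fractions — they are presumably saturation-uncorrected, and no
T₁ correction is modeled. `phantom_preset()` follows the phantom recipe:
metabolite 10 mM (2 mM for UDPG and 2,3-DPG), PCr 5 mM internal standard,
phosphate buffer 40 mM (10 mM in the low-concentration phantoms), one
amplitude unit per ^31^P nucleus.

Values the sources do not state, chosen once here: muscle linewidth 5 Hz
and liver 15 Hz (liver is visibly broader in the published example
spectra); default peak SNR 50; phantom linewidth 1.5 Hz. Peak SNR is
defined formulaically — tallest noiseless peak magnitude divided by the
frequency-domain per-channel noise SD σₜ√n of time-domain noise with
per-channel SD σₜ — so tests can assert it exactly.

The generator emulates: correct shift patterns (Pi placed through the pH
calibration), multiplet structure and decoupling behaviour, Lorentzian
broadening, seeded complex white noise, optional phase errors. It does
**not** emulate: baseline from macromolecules or bone phosphate,
eddy-current or lineshape distortions, frequency drift, T₁/T₂ weighting,
or the hemoglobin-binding shift of blood 2,3-DPG. A green recovery test
therefore establishes correctness of the estimator under the stated model,
not robustness to every in vivo artifact. Published in vivo intensity
tables derive from unreleased scanner data and are **not** reproduction
targets; the acceptance suite instead uses property-based checks
(noiseless identity, CRLB-calibrated recovery, normalization, grading
thresholds).

# Numerical choices and degenerate inputs

* Active-set least squares warm-starts from the fully passive set; with a
  well-posed basis this converges in a few passes.
* The fit normalizes data to unit peak magnitude for optimizer
  conditioning; amplitudes are rescaled afterwards.
* Axis compatibility: a basis with equal dwell but more points than the
  spectrum is truncated; any other mismatch is a structural error.
* Shifts are hard-bounded at ±0.3 ppm on top of the prior, broadening at
  [0, 25] Hz; optimizer non-convergence is flagged in diagnostics and
  warned about, never silent.
* Peak detection errors name the missing signal; out-of-domain pH shifts
  name the valid interval; file parse errors name the offending line.

# Known limitations

* Lorentzian-only lineshape (no Gaussian/Voigt component).
* One global broadening parameter; per-signal widths only via explicit
  basis overrides.
* The fitter assumes white complex noise; correlated noise would bias the
  CRLBs.
* G6P's minor enantiomer/isomer satellite signals are not modeled.
* No absolute concentration calibration — relative intensities only.
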