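---
title: "Models and methods in photophyskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in photophyskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photophyskit)
```

photophyskit implements the photophysical analysis chain used to
characterize a solvatochromic dye (here, a fused thieno-triazine
fluorophore) and its interactions with silver and gold nanoparticles:
solvent-effect analysis and excited-state dipole estimation, relative
quantum yields, oscillator strengths and transition dipoles,
Stern–Volmer and Perrin quenching analysis, metal-enhanced fluorescence
(MEF) summaries, and nanoparticle post-processing (XRD crystallite sizing,
surface-plasmon band metrics). This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Solvatochromism and excited-state dipole moments

An intramolecular charge-transfer (ICT) fluorophore's Stokes shift grows
with solvent polarity because the polar excited state is stabilized more
than the ground state. Two standard estimators of the dipole-moment change
$\Delta\mu = \mu_e - \mu_g$ are implemented.

**Lippert–Mataga.** The Stokes shift in wavenumbers,
$\Delta\bar\nu = 10^7(1/\lambda_{abs} - 1/\lambda_{em})$ cm$^{-1}$, is
regressed on the solvent orientation polarizability

$$\Delta f = \frac{\varepsilon - 1}{2\varepsilon + 1} -
             \frac{n^2 - 1}{2n^2 + 1},$$

and the slope $m$ gives $\Delta\mu = \sqrt{m\,h c a^3 / 2}$. The unit
chain is CGS throughout (erg·s, cm·s$^{-1}$, cavity radius in cm,
$\Delta\mu$ in esu·cm) with a single conversion to Debye
(1 D = 10$^{-18}$ esu·cm) at the boundary. The Onsager cavity radius $a$
follows Suppan's relation $a = (3M/4\pi\delta N_A)^{1/3}$ from the molar
mass and density. For the triazine dye, $M = 292.38$ g·mol$^{-1}$ with a
density of 1.68 g·cm$^{-3}$ gives $a = 4.1$ Å; the density is always an
explicit parameter of `onsager_radius()`, never assumed.

**Reichardt.** The Stokes shift is regressed on the normalized empirical
polarity $E_T(N)$ (water = 1, tetramethylsilane = 0), and the slope is
converted through the betaine reference probe ($a_B = 6.2$ Å,
$\mu_B = 9$ D, prefactor 11307.6):
$\Delta\mu = \sqrt{m \cdot 81 / ((6.2/a)^3 \cdot 11307.6)}$. Because this
scale also absorbs specific interactions (notably hydrogen bonding), the
Reichardt estimate is typically smaller than the Lippert–Mataga one; both
are reported.

Both fits are unweighted ordinary least squares with a free intercept, as
is standard for these linear plots; the intercept absorbs the
polarity-independent part of the Stokes shift, so $\Delta\mu$ estimates
are invariant to adding a constant to all shifts. There is no automatic
outlier rejection, but both fitters take an `exclude` list of solvent
names, because which solvents enter a published fit is often not stated.
A negative slope is physically meaningless for these models and yields
$\Delta\mu = 0$ with a flag. Derived columns ($\Delta\bar\nu$, $\Delta f$)
are always recomputed from the wavelength maxima and $(\varepsilon, n)$,
never read from input tables, so there is a single source of truth.

The bundled solvent table (`triazine_solvent_table()`) keeps the published
derived columns alongside the raw inputs for cross-checking. Two printed
orientation-polarizability entries are inconsistent with their own
$(\varepsilon, n)$ pairs — cyclohexane (printed 0.008; the formula gives a
slightly negative value) and methanol (printed 0.308 vs 0.309) — and are
documented as table typos in the tests rather than reproduced.

**Oscillator strength and transition dipole.** From a molar extinction
spectrum on a wavenumber axis,
$f = 4.32\times10^{-10}\int\varepsilon(\bar\nu)\,d\bar\nu$ (trapezoidal
rule), and $\mu_{12} = \sqrt{f/(4.72\times10^{-7} E_{max})}$ with
$E_{max}$ in cm$^{-1}$. Published $\mu_{12}$ values are not exactly
recoverable from printed $f$ and $\lambda_{abs}$ pairs because the
integration limits behind $f$ are usually unstated; the package exposes
the limits explicitly.

**Relative quantum yield.** $\Phi_s = \Phi_r\,(I_s/I_r)(A_r/A_s)
(n_s^2/n_r^2)$ against a reference such as quinine sulfate in 0.5 M
H$_2$SO$_4$ ($\Phi_r = 0.54$). A warning is emitted when either absorbance
exceeds 0.1, where reabsorption biases the comparison.

## Nanoparticle quenching and enhancement

**Stern–Volmer.** $I_0/I = 1 + K_{SV}[Q]$ is fitted by OLS with a free
intercept (robust to an error in $I_0$), and $K_{SV}$ is the slope; an
intercept deviating from 1 by more than 5% is flagged. The bimolecular
rate constant is $k_q = K_{SV}/\tau_f$ with the unquenched lifetime in
seconds. Classification: a negative slope is *enhancement*;
$K_{SV} \ge 10^7$ M$^{-1}$ is *superquenching* (the accepted
$10^7$–$10^{10}$ M$^{-1}$ range and above, orders of magnitude beyond
diffusion-controlled quenching at $\sim10^2$ M$^{-1}$); otherwise the
lifetime diagnostics decide. *Static* quenching (ground-state complex)
leaves lifetimes unchanged — the package uses a 5% relative-range
threshold — while *dynamic* (collisional) quenching makes $\tau_0/\tau$
track $I_0/I$, tested at a 10% tolerance. Both thresholds are package
choices; the underlying physics is only qualitative. When lifetimes are
missing, a $k_q/k_d$ ratio above 10 asserts a bound/static mechanism; the
diffusion rate constant $k_d$ is always user-supplied (literature values
for ethanol and ethylene glycol, $9.2\times10^{10}$ and
$5.8\times10^{8}$ M$^{-1}$s$^{-1}$, are cited constants, not recomputed).

**Perrin active sphere.** For static quenching by nanoparticles,
$\ln(I_0/I) = V N_0 [Q]$, where $V$ is the active-sphere volume and
$N_0 = 6.02214\times10^{20}$ molecules per cm$^3$ at 1 M, so a slope in
M$^{-1}$ divided by $N_0$ lands $V$ in cm$^3$; the sphere radius is
$r = (3V/4\pi)^{1/3}$. Comparing $r$ with the fluorophore–quencher contact
radius $R = R_y + R_q$ distinguishes contact quenching from longer-range
(energy-transfer) quenching: $r \gg R$ indicates the latter, consistent
with a large emission/plasmon spectral overlap, which
`overlap_integral()` quantifies as the integral of the pointwise minimum
of the two unit-area spectra (a symmetric, scale-invariant number in
[0, 1]).

**Lifetimes.** `fit_monoexponential_decay()` fits $\ln(\text{counts})$
against time by least squares — an idealized estimator that neglects the
instrument response function, adequate for the invariance diagnostic the
classification needs, not for sub-nanosecond lifetime metrology.

**MEF.** `enhancement_curve()` reports per-point enhancement factors
$I/I_0$, a monotonicity summary, and, when emission spectra for the first
and last titration points are supplied, the emission red-shift as the
difference of band centers.

## Nanoparticle characterization

**XRD.** A Gaussian plus constant baseline is fitted to one reflection by
Levenberg–Marquardt least squares; the angular FWHM $\beta$ (radians)
feeds the Debye–Scherrer relation $D = K\lambda/(\beta\cos\theta)$ with
$\theta = 2\theta/2$. Defaults are $K = 0.98$ and the Cu K$\alpha_1$
wavelength 0.15406 nm, stored in nm (source texts sometimes print
"0.154 Å", an evident unit slip — Cu K$\alpha$ is 1.54 Å). Only a
Gaussian profile is supported (no Voigt, no instrumental-broadening
subtraction, no strain separation): this mirrors common practice for
quick colloid sizing, and its output should be read accordingly. The
starting width for the nonlinear fit comes from the half-height crossings
of the windowed data, falling back to the second moment; the
moment estimate alone can be inflated several-fold by baseline noise and
then stalls the optimizer. `fcc_consistency()` converts a four-reflection
list to per-reflection lattice constants as an indexing sanity check.

**SPR bands.** Plasmon bands of citrate colloids are broad (FWHM tens of
nm), so near the maximum the signal varies by less than typical noise
between neighboring grid points. `spr_characterize()` therefore refines
the grid maximum with a parabolic vertex fitted over all points in the top
quarter of the band, which averages tens of points and is unbiased for any
symmetric band; a 3-point refinement at the noisy argmax would wander by
several nm at 1% noise. The same estimator is used for the MEF red-shift.
`peak_maximum()` itself keeps the classical 3-point parabolic refinement
(appropriate for narrow, well-sampled peaks), with the FWHM measured by
linear interpolation at half height above the window minimum — no baseline
model beyond that minimum is applied.

## Numerical and degenerate-input conventions

* Axis grids are sorted ascending at construction; duplicate axis values
  are averaged. Peak ties break toward the smaller axis value; maxima on a
  window edge are flagged and not refined.
* Band integrals interpolate the range edges linearly, so integration is
  additive over adjacent ranges and invariant to grid refinement for
  piecewise-linear signals.
* nm ↔ eV conversion uses $hc = 1239.842$ eV·nm (CODATA rounding);
  nm ↔ cm$^{-1}$ uses $10^7$. Both invert to 10$^{-9}$ relative.
* Exact linear fits (zero residuals) report their standard errors and
  $R^2$ directly from the residual sums, avoiding spurious warnings; a
  flat response has $R^2 = 1$ by convention (the line reproduces the data
  exactly).
* Atomic weights are the IUPAC 2021 conventional values, frozen in a
  plain-text table so composition arithmetic is bit-stable.

## The synthetic-data generators

Every analysis stage has a seeded generator
(`gen_band_spectrum()`, `gen_solvatochromic_series()`,
`gen_reichardt_series()`, `gen_quenching_series()`, `gen_xrd_pattern()`,
`gen_decay_trace()`) producing data with exactly the statistical structure
the stage assumes, so the whole chain is testable with no instrument data.
Each generator draws from a pseudo-random stream derived from
`(seed, operation name)`: results are bit-reproducible and independent of
call order, and the caller's RNG state is restored.

Noise conventions: spectra get additive Gaussian noise scaled to 1% of the
clean maximum by default (or multiplicative `1 + N(0, σ)`); quenching
intensities get 5% multiplicative noise; solvatochromic Stokes shifts get
additive noise with σ in cm$^{-1}$, 100 cm$^{-1}$ being the representative
scale used in the recovery studies (a few percent of a typical
6000–8000 cm$^{-1}$ shift, i.e. about the reproducibility of locating
broad band maxima). These magnitudes are package choices — real
instruments are not this simple: the generators do not emulate baseline
drift, wavelength calibration error, inner-filter effects, detector
nonlinearity, correlated (1/f) noise, or instrument response convolution
in decays. Passing the recovery tests therefore demonstrates estimator
correctness under idealized noise, not robustness to every artifact of
real spectra.

**Study conditions for the recovery checks** (as exercised in the tests
and the acceptance script):

* Solvatochromic recovery uses the nine bundled solvents, 200 replicates,
  σ = 100 cm$^{-1}$, at the study's two dipole changes (4.28 D
  Lippert, 1.86 D Reichardt). Recovery of much smaller dipole changes
  (≲2 D) from nine solvents at this noise is statistically impossible for
  the Lippert regression — the implied slope falls below its own standard
  error — which is a property of the experiment design, not of the code.
* Stern–Volmer recovery uses 8 concentrations titrated to about 8% of the
  initial intensity ($K_{SV}\,[Q]_{max} \approx 12$), matching the
  near-complete quenching visible in published nanoparticle titrations.
  Depth matters: noise on the $[Q] = 0$ point multiplies every $I_0/I$
  ratio, putting a floor of about 3.4% on the median slope error at 5%
  noise, and a shallow titration ($K_{SV}[Q]_{max} \approx 2$) cannot
  reach 5% median recovery at all.
* Perrin recovery uses 8 concentrations with $\ln(I_0/I)$ up to ≈2.5.
* XRD sizing uses the four-reflection silver pattern at D = 50 nm on a
  30–80° grid (0.02° steps) with 2% additive noise; sizing errors stay
  within ~3% per pattern.

These problem sizes keep the full suite and the acceptance script each
under a few seconds while leaving the medians stable to a fraction of a
percentage point.

## Known limitations

* Only the simplified Lippert–Mataga and Reichardt estimators are
  provided — no Bakhshiev or Kawski–Chamma–Viallet variants, and no
  hydrogen-bonding corrections; protic-solvent points can bias the
  Lippert fit accordingly.
* The Stern–Volmer model is strictly linear; upward-curving (mixed
  static + dynamic) data should be truncated or fitted elsewhere.
* The Perrin conversion assumes the quencher concentration is the molar
  concentration of independent spheres; for nanoparticles this is the
  particle (not atom) molarity.
* No FRET rate or Förster-radius calculation; the overlap metric is a
  normalized diagnostic, not a $J(\lambda)$ integral in
  M$^{-1}$cm$^{-1}$nm$^4$.
* Spectral file support is two-column delimited text only; the axis kind
  is always declared by the caller, never guessed.
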