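---
title: "Methods and modelling choices in ontshine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in ontshine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontshine)
```

## The phenomenon and the pipeline

Optic-nerve-transmitted (ONT) eyeshine arises when downwelling light passes
through the thin dorsal skull of a small fish, is collected by the exposed,
pleated optic nerve, and re-emerges from the optic disc through the pupil
as a narrow, lens-projected beam. Quantifying it involves five loosely
coupled analyses, mirrored by this package's modules: spectral transmission
efficiency relative to a white standard, underwater irradiance attenuation,
emission-beam geometry, axial circular statistics of nerve-pleat angles
with a torsion regression, and a receptor-noise model of how conspicuous
the beam is to a conspecific. A sixth module generates seeded synthetic
inputs for all of them.

## Spectral conventions

* **Working grid.** 1-nm steps over 380–780 nm. Research-grade
  spectroradiometers report 1-nm resolved radiance over roughly this span;
  all cross-curve operations first resample (linearly) onto the
  intersection grid, and refuse to extrapolate.
* **Integration.** Trapezoid rule throughout. At 1-nm resolution on smooth
  biological spectra the difference from higher-order rules is far below
  measurement noise.
* **Photon conversion.** $N(\lambda) = L(\lambda)\lambda/(hc)$ with CODATA
  $h$ and $c$ to six significant digits. Quantities (energy vs photon,
  radiance vs irradiance) are explicit tags on every curve; nothing is
  converted implicitly.
* **Transmittance above 1.** Measured $T(\lambda) = L_{OT}/L_0 > 1$ is
  physically impossible but routinely produced by noise at dim wavelengths.
  Values are kept and flagged with a warning: clipping at 1 would bias
  band-integrated efficiencies downward asymmetrically.
* **Efficiency band.** The band over which published "relative to DWS"
  ratios were integrated is not stated with the summary tables;
  `band_ratio()` exposes it as a parameter with default 380–780 nm (the
  full working grid). Proportional spectra give the same ratio for any
  band, so the choice only matters for strongly non-proportional noise.

## Attenuation and depth

$K(\lambda)$ is minus the OLS slope of $\ln E(\lambda, z)$ on $z$; with two
depths this is the textbook two-point formula. Wavelengths with any
non-positive irradiance get `NA` rather than a fabricated coefficient —
downstream propagation interpolates across them only inside the measured
span. Propagation is the plain exponential decay model; it assumes the
water column is vertically homogeneous over the extrapolated range, which
is reasonable for the top tens of metres of clear coastal water at midday
but not for stratified or turbid water.

## Beam geometry

The apex angle at the eye follows from the measured triangle by the law of
cosines. For the refraction correction the package assumes a thin,
parallel-faced tank wall, so only the water and air indices matter (the
glass index cancels). The in-air half-angles on each side of the interface
normal — taken as the altitude from the eye onto the chord between the two
observation points — are individually converted with Snell's law and
summed. Where along the light path the correction is applied was an open
design point; applying it at the wall on the water side is the only choice
consistent with a flat interface and is recorded in the function
documentation. Defaults $n_{water} = 1.333$, $n_{air} = 1.000$ are
configurable.

## Axial circular statistics

Nerve-pleat angles are axes, not directions: $\alpha$ and
$\alpha \pm 180°$ are the same orientation. Averaging raw values across
that ambiguity is meaningless, so:

1. **Axial transformation.** Angles are reduced modulo 180°; the largest
   gap on the resulting 180°-period circle is located; the sample is cut at
   that gap and one side lifted by +180°. This minimises the circular range
   — the test suite proves equality with brute-force enumeration over all
   $2^n$ per-angle shifts for $n \le 12$ rather than assuming it. Ties
   between equally wide gaps are broken toward the solution with the
   smallest non-negative mean, a pure convention that only affects
   reporting, never the spread.
2. **Weighted mean and SD.** The mean uses the two-argument arctangent
   (the single-argument form printed in most methods sections is
   quadrant-ambiguous) with weights $l_i/\sum l_i$ (relative layer
   lengths). The circular SD $v = \sqrt{-2\ln\bar R}$ is reported in
   degrees. $\bar R = 0$ (e.g. an equal-weight antipodal pair) leaves $v$
   undefined; the package returns `NA` with a warning instead of infinity.
3. **Unwrapping.** Under the working assumption of continuous, roughly
   constant torsion, successive section means are shifted by multiples of
   180° so no step exceeds 90°; ties take the smaller shift.
4. **Torsion fit.** OLS of unwrapped mean angle on distance. The
   "starting angle" is the fitted intercept (it is reported alongside
   fit-derived torsion, and the intercept is the fit's estimate at the
   disc), not the first section's raw mean. Coefficients whose two-sided
   t-test (df = n − 2) fails significance at `alpha` (default 0.05 — the
   conventional level; the source analyses say only "not significantly
   different from zero") are set to zero and flagged. With exactly two
   sections the tests are skipped and flags stay unset. Total torsion uses
   |slope| — published summaries report magnitudes, and the sign convention
   of a section stack is arbitrary. Group summaries average per individual
   first, then per group, with sample SD (n − 1; the denominator is not
   stated in the source tables).

## Receptor-noise model

Receptor sensitivities come from the Govardovskii A1 template (alpha band
with the published constants and λmax-dependent $a$, plus the beta-band
Gaussian), peak-normalised, multiplied by ocular-media transmittance.
Quantum catches are trapezoid integrals of sensitivity × photon spectrum.
Per-class noise is $\omega_i = \nu\sqrt{\eta_{max}/\eta_i}$ with the Weber
fraction $\nu = 0.05$ assigned to the most abundant class and densities
1:4:4 mapped to (single cone, double-cone member, double-cone member) in
λmax order 468/516/530 nm. Chromatic contrast uses the log-signal
(bright-light) trichromat form; the study conditions are photopic, and log
signals make the von-Kries-like cancellation of common illumination factors
exact. The achromatic channel sums the two double-cone member sensitivities
after media filtering (no combination rule is published; summing weights
both members by their spectral overlap) and uses $\omega_D = 0.05$. Ocular
media enter as a single transmittance curve; when built from components
(dermal cornea, scleral cornea, lens) they should be multiplied — serial
filters — before being passed in.

The published conspicuousness values (4.85 and 5.04 JND at 5 and 20 m)
depend on measured spectra in supplementary material that is not
reproduced in text form, so they are not targets. The model is instead
validated by its exact structural properties: zero chromatic contrast for
spectrally proportional stimuli, $\Delta L = |\ln k|/\omega_D$ for a flat
factor $k$, invariance to common rescaling, and the dichromat limit of the
trichromat formula.

## Synthetic data: the stated world

The generators encode the conditions the source measurements describe, not
tunable knobs:

* **Eyeshine spectra.** DWS band-integrated photon radiance 1.51 × 10^19
  photons s⁻¹ sr⁻¹ mm⁻² (the published magnitude); optic-disc transmission
  a logistic rising with wavelength (tissue transmits long wavelengths
  better), scaled so the band efficiency is exactly the species default
  (2.03 % ONT, 0.47 % PET for the focal species) when noise is off.
  Measurement noise is multiplicative log-normal, default off; 5 % is a
  realistic instrument-repeatability level when wanted. The "about 8 % at
  the red end" figure-read value informs the logistic asymptote but is
  never asserted.
* **Depth profiles.** Default 0–10 m in 0.5-m steps (the published dive
  profile); a smooth K(λ) with its minimum in the blue-green. Hydrological
  realism is out of scope; what matters is the exponential structure the
  estimator assumes.
* **Nerve sections.** Section spacing uniform 40–60 μm, 4–11 layers of
  30–60 μm per section (the published ranges, giving 10–21 sections for
  realistic nerve lengths); truth angle = start + rate × distance; wrapped
  normal angular noise (default SD 10°, matching the per-section scatter a
  digitised section stack shows; von Mises offered as an option) and random
  ±180° flips emulating the axial ambiguity. Species defaults transcribe
  the published per-genus torsion summaries and are labelled defaults, not
  data.
* **Morphometry.** Truncated normals around the published per-species
  means/SDs; head width/height are synthesised so their mean is exactly
  the drawn head diameter, keeping per-individual ratios consistent.

What a green test establishes is therefore that the estimators recover the
parameters of data with this *structure* — exponential decay, constant
torsion plus wrapped noise, proportional spectra. Real data add
instrument drift, section-alignment error, non-constant torsion and
inter-individual covariance that the generators do not emulate.

## Numerical choices and degenerate inputs

* Resampling refuses extrapolation, naming the offending wavelength.
* `circular_sd()` snaps to exactly 0 when $1 - \bar R < 10^{-12}$
  (coincident angles up to floating noise).
* Perfect (zero-residual) torsion fits get p = 0 for nonzero coefficients
  and p = 1 for zero ones, avoiding 0/0 in the t statistic.
* Zero-weight layers are excluded by precondition (lengths must be > 0);
  the weighted mean's limit as a weight → 0 is continuous, which the tests
  check.
* Reference spectra that are zero where the sample is positive abort with
  the wavelengths listed; zero-over-zero is defined as 0.
* Printed-precision rounding (2 decimals for mm, etc.) is output
  formatting only; stored values keep full precision.

## Known limitations

* The beam correction ignores wall curvature and thickness; for thick
  curved aquaria a ray-traced correction would be needed.
* The attenuation model is single-exponential per wavelength; it cannot
  represent inelastic (Raman/fluorescence) contributions that matter below
  the euphotic zone.
* The visual model is the standard bright-light receptor-noise limit; it
  does not model spatial acuity, so a "visible" contrast says nothing about
  the distance at which the narrow beam subtends a resolvable angle.
* Group summaries assume individuals are exchangeable; no allometric
  correction is applied by default because no validated exponents are
  available (an optional user-supplied exponent would be the extension
  point).
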