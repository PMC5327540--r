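# ontshine

Quantitative analysis of **optic-nerve-transmitted (ONT) eyeshine** — the
narrow beam of light that small benthic fishes emit from the pupil when
ambient light enters through the thin dorsal skull, is collected and
partially guided by the pleated optic nerve, and leaves the eye through the
optic disc. The package is for visual ecologists who need to turn the raw
measurements of such a study — spectroradiometer curves, serial-section
layer angles, head morphometrics, underwater irradiance profiles — into the
standard derived quantities, with every step testable against seeded
synthetic data.

## What it computes

**Spectral transmission efficiency.** Eyeshine radiance is expressed
relative to a diffuse white standard (DWS) measured under identical
illumination. With photon spectra $L(\lambda)$ on a common grid, the band
efficiency is

$$\varepsilon = \frac{\int_{\lambda_1}^{\lambda_2} L_{\mathrm{eyeshine}}(\lambda)\,d\lambda}{\int_{\lambda_1}^{\lambda_2} L_{\mathrm{DWS}}(\lambda)\,d\lambda},$$

with energy-to-photon conversion $N(\lambda) = L(\lambda)\lambda/(hc)$ and
per-wavelength transmittance $T(\lambda) = L_{\mathrm{OT}}(\lambda)/L_0(\lambda)$.

**Underwater light.** Diffuse attenuation coefficients $K(\lambda)$ are the
per-wavelength OLS slopes of $-\ln E$ on depth from a measured profile;
irradiance is propagated as $E(\lambda,z) = E(\lambda,0)\,e^{-K(\lambda)z}$.

**Beam geometry.** The horizontal angular width of the emission beam from
triangulated side lengths (law of cosines), with each half-angle Snell-
corrected across the flat tank wall: $\theta_w = \arcsin(\sin\theta_a/n_w)$.

**Axial circular statistics and torsion.** Optic-nerve pleat angles are
axial (defined modulo 180°). The package minimises the circular range over
per-angle ±180° shifts (proven equal to brute force in the tests), computes
the length-weighted circular mean
$\bar a = \operatorname{atan2}(\sum \sin a_i\, l_{r_i},\ \sum \cos a_i\, l_{r_i})$
and circular SD $v = \sqrt{-2\ln \bar R}$, unwraps the per-section means,
and fits torsion (°/mm) by OLS with t-test-based zeroing of
non-significant coefficients.

**Morphometry.** Head diameter (mean of width and height), head
cross-sectional area $\frac{\pi}{4}HD^2$, relative percentages with explicit
unit reconciliation, optic-nerve depth estimation from relative depth, and
mean ± SD summaries.

**Conspicuousness (receptor-noise model).** Govardovskii A1 pigment
templates, ocular-media filtering, quantum catches, and Vorobyev–Osorio
chromatic ($\Delta S$) and achromatic ($\Delta L$) contrasts in
just-noticeable differences (JND) for a trichromat (defaults: λmax
468/516/530 nm, densities 1:4:4, Weber fraction 0.05).

## Worked example

```r
library(ontshine)

# synthetic fish with the package's default species profile
sp <- gen_eyeshine_spectra(seed = 1, species = "T_delaisi")
band_ratio(sp$ont, sp$dws)   # 0.0203  -> 2.03 % of incident light re-emitted
band_ratio(sp$pet, sp$dws)   # 0.0047  -> retinal background ~1/4 as bright

# nerve torsion from synthetic serial sections (truth: 93.4 deg/mm)
secs <- gen_nerve_sections(seed = 1, start_angle = 19.3,
                           torsion_rate = 93.4, noise_sd = 10,
                           nerve_length = 0.81)
analyze_nerve(secs)
#> <torsion_fit> n = 17 sections
#>   starting angle: 197.0 deg     (= 17.0 deg as an axis: mod 180)
#>   torsion rate:   99.8 deg/mm
#>   nerve length:   0.80 mm
#>   total torsion:  80.3 deg

# how visible is the eyeshine to a conspecific at 5 m depth?
ds <- gen_depth_profiles(seed = 1)
K <- attenuation_coefficients(ds)
eyeshine_contrast_at_depth(ds$curves[[1]], K, 5,
                           transmittance(sp$ont, sp$dws),
                           transmittance(sp$pet, sp$dws),
                           visual_system())
#> <contrast_result> depth 5.0 m: dS = 0.000 JND, dL = 29.261 JND
```

The torsion fit recovers the generating rate within sampling error (99.8 vs
93.4 °/mm under 10° angular noise on 17 sections); the starting angle is
recovered modulo 180° because pleat orientations are axes. In the synthetic
world the eyeshine and its retinal background share one spectral shape, so
the chromatic contrast is exactly 0 JND while the achromatic contrast is
ln(0.0203/0.0047)/0.05 ≈ 29.3 JND — far above the 1-JND discrimination
threshold.

A command-line front end is installed as `exec/ontshine` with subcommands
`spectra`, `beam`, `torsion`, `morpho`, `contrast`, `simulate`, `run`.

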