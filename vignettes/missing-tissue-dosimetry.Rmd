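---
title: "Missing-tissue perturbation of TG-43 brachytherapy parameters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-tissue perturbation of TG-43 brachytherapy parameters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyscatter)
```

## The problem and the model

TG-43 decomposes the dose rate around a sealed brachytherapy source as

$$\dot D(r,\theta) = \Lambda\, S_K\, \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\,
g_L(r)\, F(r,\theta),$$

with the reference point at $r_0 = 1$ cm on the transverse axis
($\theta_0 = \pi/2$). The decomposition is defined under *full scatter*: at
least 15 cm of water around the source in every direction. When an implant
sits near the skin, the scatter compartment on one side is truncated.
`brachyscatter` models this with a source at the origin of a
$30\times30\times30$ cm$^3$ water cube surrounded by vacuum, shifted so that
only $x$ cm of water overlies it along its transverse axis (labels
`H(30-x, x)`) or its longitudinal axis (`V(30-y, y)`); `(15, 15)` is the
centered full-scatter reference. The *missing tissue* is $15-x$.

The quantity of clinical interest is the perturbation factor

$$\mathrm{PF}(r, x) = \frac{g_{(30-x,\,x)}(r)}{g_{(15,15)}(r)},$$

the ratio of the radial dose function toward the missing tissue to its
full-scatter counterpart. Multiplying a standard full-scatter $g_L(r)$ by a
fitted $\mathrm{PF}$ polynomial corrects it for a given implant geometry;
`applyCorrection()` and `perturbationFactor()` are exact mutual inverses.

Side conventions: polar angles stay in $[0^\circ, 90^\circ]$ and each tally
point carries a `"toward"`/`"away"` tag for the hemisphere relative to the
missing tissue, rather than extending $\theta$ past $90^\circ$. A point
described elsewhere as $(r=3, \theta=140^\circ)$ toward a longitudinal shift
is $(r=3, \theta=40^\circ, \mathrm{toward})$ here. Points outside the phantom
are masked, never extrapolated.

## The transport engine

The Monte Carlo engine is deliberately simple — an analog photon random walk
under the kerma approximation, which is the same estimator family as a
track-length energy-flux tally converted to dose with $\mu_{en}/\rho$:

* **Free paths** are exponential with the total attenuation coefficient
  interpolated log-log from embedded ~28-point tables (1 keV–2 MeV) for
  liquid water and dry air, transcribed from the standard public compilation.
  Partial interaction fractions are derived from those columns: incoherent
  scattering from the free-electron Klein–Nishina cross section, coherent
  from a coarse transcribed column, photoelectric as the non-negative
  remainder, renormalized to sum to one.
* **Compton scattering** uses Kahn's rejection method for the Klein–Nishina
  energy/angle distribution (validated in the tests against direct quadrature
  of the cross section). Electron binding and Doppler broadening are ignored.
* **Rayleigh scattering** is on by default and sampled from the Thomson
  angular distribution; atomic form factors are omitted, which overweights
  large-angle coherent scattering at low energy. It can be disabled
  (`simulationConfig(rayleigh = FALSE)`), which turns the coherent channel
  into a straight-through no-op.
* **Photoelectric absorption** terminates the history; fluorescence is
  treated as locally deposited, consistent with the kerma scope.
* **Escape** through a cube face ends transport (vacuum outside is exactly
  the missing-scatter mechanism), but the photon still streams through any
  tally spheres ahead of it, so surface cells remain unbiased.
* **Tallies** are spheres whose chords accumulate
  $\ell \times E \times \mu_{en}/\rho(E)$; dose per history is the cell sum
  divided by cell volume. Radii follow a ramp from 0.2 mm near the source to
  0.7 mm at 10 cm, times a `radiusScale` (default 10). The ratio estimands
  (g ratios, side differences) are insensitive to cell size; the absolute
  inverse-square tests divide out the closed-form volume average of $1/s^2$
  over a finite sphere.
* **Sources** are simplified: bare active lines of 0.455 cm (Pd-103) and
  0.5 cm (Ir-192), and a pellet train for the Cs-137 LDR source (default
  `NANAANAN`, 0.25 cm pitch, effective active length 1.5 cm; the six-active
  `AAAAAA` arrangement is available). Encapsulation, the Ir-192 delivery
  wire and the internal capsule structure are omitted: capsule effects
  largely cancel in the ratios that are the analysis surface, and absolute
  dose rate constants are not claimed. Emission spectra are packaged line
  lists (Cs-137 mono-energetic at 0.6617 MeV); lines below the transport
  cutoff (5 keV for Pd-103, 10 keV otherwise) are dropped at load with a
  warning.
* **Random numbers** come from a counter-based per-history substream
  (splitmix64-seeded xoroshiro128+), so a run is bit-reproducible for a fixed
  seed and independent of batching. Uncertainties are batch statistics
  (32 batches by default); zero-hit cells are flagged, never silently zero.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `histories` | 1e6 | photon histories per run; statistical error scales as $1/\sqrt{N}$ |
| `cutoff_MeV` | 0.005 (Pd), 0.010 (Ir, Cs) | transport cutoff energy |
| `radiusScale` | 10 | multiplier on the 0.02–0.07 cm tally-radius ramp |
| `rayleigh` | `TRUE` | include the coherent channel |
| `nbatch` | 32 | batches for error estimation |
| active length $L$ | 0.455 / 0.5 / 1.5 cm | line-source geometry function scale |

Reference-quality studies use $10^9$ histories to reach 0.5% at 10 cm. At
desk scale this package runs $10^6$–$4\times10^7$ histories per configuration
(a few seconds to ~15 s each) with proportionally larger tally spheres; that
reaches ~1% on the r = 5 cm g-ratio, which is sufficient for the ±0.02
agreement asserted on the published Cs-137 `H(25, 5)` ratio. These sizes are
the package's validation choice, stated here so results are interpretable.

## Numerical choices

* $\beta$, the angle subtended by the active line, is computed from the two
  endpoint vectors, which reduces to
  $\beta = \operatorname{atan2}(L r \sin\theta,\; r^2 - L^2/4)$ — robust
  near the line extension; the on-axis branch $(r^2-L^2/4)^{-1}$ is applied
  when $\sin\theta < 10^{-12}$ and matches the oblique branch continuously.
* $g$ interpolates log-linearly in $r$, $F$ bilinearly in $(r,\theta)$,
  standard TG-43U1 practice; both are exact at nodes, and reconstruction
  outside the tabulated grids raises rather than extrapolates. The $r_0$
  normalization always uses the exact reference sample.
* Cross sections interpolate log-log (exact power-law behavior between
  nodes); interaction-channel sampling assigns a deviate on a cumulative
  boundary to the upper channel.
* Polynomial evaluation is nested (Horner). `fitPolynomial()` raises the
  degree until the residual RMS gain over the next degree falls below 10%,
  and reports the residual RMS.
* Percent differences carry an explicit denominator convention, because the
  published tables use three: `"sides"` divides by the away-side value,
  `"vs_full"` by the full-scatter value, `"vs_shifted"` by the
  shifted-configuration value. These are the only conventions consistent
  with the printed columns.
* Packaged correction polynomials carry a validity range of
  $[1, x]$ cm — up to the overlying thickness. Beyond the phantom surface the
  toward-side ratio is not defined by the fitted data and the degree-6
  polynomials diverge rapidly (some by orders of magnitude by 10 cm), so
  evaluation outside the range is an error. One printed coefficient set
  (Cs-137, 6 cm overlying) is internally inconsistent with its own tabulated
  ratios beyond about 2 cm; it is shipped as printed with a warning note in
  the data file.

## The synthetic-data generator

`syntheticSpec()`/`generateDoseTable()` emulate tally output without
transport: an analytic full-scatter $g$ model per isotope (near-flat decline
for Cs-137, rise-then-fall for Ir-192, quasi-exponential decline for Pd-103 —
fixtures calibrated loosely to published full-scatter columns, not physics
claims), a mild anisotropy model, an injected perturbation on the toward side
(a packaged polynomial or any function), and independent multiplicative
Gaussian noise growing linearly to at most 0.5% at 10 cm. This supports the
closed-loop property the module exists for: generate → extract $g$ → ratio →
fit → recover the injected generator within 1% under 0.5% noise.

What the generator does *not* emulate: batch correlations between tally
cells, energy-dependent noise, capsule anisotropy, or 3D dose grids. Passing
closed-loop tests therefore demonstrates that the analysis chain is
self-consistent and noise-stable, not that the transport physics is exact.

## Design decisions taken where the problem was open

* The mapping of tally radius to distance is not fully specified in the
  reference setup ("0.2–0.7 mm depending on distance"); a linear ramp is
  used, scalable for desk-scale variance.
* The perturbation-ordering property (which isotope is most sensitive at
  r = 5 cm transverse) is tested as printed in the published side-difference
  columns — Ir-192 > Pd-103 > Cs-137 — with a 2σ statistical allowance on
  the Ir/Pd pair, whose published gap is about one standard error at the
  history counts used here.
* The cross-section library behind the reference simulations is unknown, so
  absolute dose-rate agreement is not claimed anywhere; all acceptance-grade
  comparisons are ratios or printed-table arithmetic.

## Known limitations

No electron transport (kerma ≡ dose assumes charged-particle equilibrium,
questionable within ~1 mm of a ^192^Ir source); free-electron Compton and
form-factor-free Rayleigh (a few-percent channel distortion below ~30 keV,
which matters most for Pd-103); simplified bare sources (absolute $\Lambda$
and near-axis anisotropy differ from encapsulated reality); coarse embedded
cross-section grids (log-log interpolation error well under 1%, but not a
certified library). The analysis layer — perturbation factors, corrections,
fits, reports — is exact arithmetic and carries none of these caveats.
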