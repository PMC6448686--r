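---
title: "Modelling equatorial small-angle scattering from cellulose microfibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling equatorial small-angle scattering from cellulose microfibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsas)
```

## The physical picture

The secondary cell wall of wood consists of semi-crystalline cellulose
microfibrils, 2–3 nm in diameter, embedded in a hemicellulose/lignin
matrix. In a fibre-symmetric small-angle scattering experiment (fibre axis
vertical), the lateral cross-section and packing of these microfibrils show
up in the *equatorial* intensity: a correlation peak near
q = 0.15 Å⁻¹ in wet wood reflects the centre-to-centre packing distance
(a ≈ 4 nm), while the shoulder at higher q carries the cross-sectional
form factor of the individual fibrils.

`fibrilsas` models the microfibrils as infinitely long circular cylinders
with a Gaussian radius distribution (mean R̄, sd ΔR), packed on a 2D
hexagonal lattice whose lattice-vector length fluctuates — a paracrystal of
the second kind with spacing a and distortion Δa. The full equatorial
model is

$$I(q) = A\, I_\mathrm{cyl}(q) + B\, e^{-q^2/2\sigma^2} + C\, q^{-\alpha},$$

where the Gaussian (scale B, width σ in q) absorbs scattering from larger
pores and unspecified nanoscale features, and the power law (scale C,
exponent α ≈ 4) describes surface scattering from pores and cell lumina.
The cylinder term uses the decoupling approximation

$$I_\mathrm{cyl}(q) = \langle f^2\rangle_R - \langle f\rangle_R^2 +
  \langle f\rangle_R^2\, \tilde Z(q),$$

with the cross-section amplitude $f(q,R) = \pi R^2\, 2J_1(qR)/(qR)$ (any
contrast and number-density constants are absorbed into A) and the
orientation-averaged paracrystalline lattice factor $\tilde Z$.

### The lattice factor and its low-q modification

Each hexagonal basis vector (at 0° and 60°) contributes a 1D
paracrystalline interference factor

$$Z_k(q, \psi) = \frac{1-g^2}{1 - 2g\cos(qa\cos(\psi - \psi_k)) + g^2},
  \qquad g = e^{-q^2\Delta a^2/2},$$

and the crystal rotation ψ about the fibril axis is averaged uniformly —
an arithmetic mean of $Z_1 Z_2$ over 1001 points placed at
$2\pi k/1001$, $k = 0,\dots,1000$, which is the exact trapezoid rule for a
periodic integrand on $[0, 2\pi)$. The average depends only on the reduced
variables $qa$ and $\Delta a/a$; the inner loop is implemented in C++
because the fitting engine evaluates it thousands of times per fit.

Paracrystalline interference functions rise unphysically as $q \to 0$. The
model therefore continues $\tilde Z$ as a constant below its first local
minimum $q_0$: `turning_point()` scans the reduced variable $x = qa$ over
(0, 12] (600 points, refined by golden-section search) and `i_cyl()`
substitutes the plateau value $\tilde Z(q_0)$ for $q < q_0$. This makes
$I_\mathrm{cyl}$ continuous at $q_0$ by construction. The search is fast
enough (~1 ms) that no precomputed polynomial cache of $q_0 a$ versus
$\Delta a/a$ is needed; across $\Delta a/a \in [0.05, 0.8]$ the minimum
always exists, at $q_0 a \approx 2.7$.

### Numerical choices

* **Radius quadrature.** The Gaussian radius distribution is discretised
  on 11 equally spaced nodes covering R̄ ± 3ΔR, clipped at zero from
  below, with weights proportional to the Gaussian density and
  renormalised to unit sum. The ±3 sd truncation is configurable
  (`truncation_k`). At 11 points the rule's moment error is small (the
  density-weighted comb overestimates the distribution variance by ≈ 1.7 %,
  i.e. ≈ 0.3 % in ⟨f²⟩ at 20 % polydispersity), and over the
  correlation-peak and shoulder region the intensity agrees with a
  10×-denser quadrature to well under 0.5 %. Near and below the lattice
  factor's first minimum, however, the near-cancellation
  ⟨f²⟩ − ⟨f⟩²(1 − Z(q₀)) amplifies that moment error to ≈ 0.7 % — an
  intrinsic property of the prescribed 11-point discretisation, not of the
  implementation, and far below the 2 % measurement noise the model is
  fitted against.
* **Units.** All internal lengths are Å and q is Å⁻¹; the user-facing flat
  parameter vector reports lengths in nm (`d_mean` is the mean *diameter*
  2R̄, `a` the lattice spacing) because that is how results are tabulated
  in this field.
* **Degenerate inputs.** ΔR = 0 collapses the quadrature to one node, so
  $\langle f^2\rangle - \langle f\rangle^2 = 0$ exactly; Δa = 0 (a perfect
  lattice) is rejected, since the paracrystalline factor degenerates to
  Bragg deltas that the model is not meant to describe.

## Reduction of 2D patterns

Fibre symmetry lets the equatorial contribution be separated from the
isotropic background without any model:

1. `azimuthal_profile()` averages intensity in azimuth bins over a chosen
   q annulus.
2. `fit_azimuthal_peak()` fits a pair of Gaussians 180° apart on a
   constant background. The background is *anchored at the profile
   minimum* in the sense that it is initialised there and the default
   slope is zero; it remains free in the least squares so that counting
   noise in the single minimum bin does not bias the arc parameters. A
   flat profile yields a flagged degenerate result with the baseline at
   the profile level.
3. `isotropic_component()` takes the azimuthal minimum at each q as the
   isotropic curve — the equatorial arcs vanish at the meridian.
4. `sector_average()` integrates radially over the two opposite 25°-wide
   sectors centred on the fitted equatorial maximum (both sectors by
   default, fibre symmetry; azimuth is measured counter-clockwise from
   detector +x).
5. `equatorial_excess()` subtracts the interpolated isotropic curve,
   propagating uncertainties in quadrature.

`merge_curves()` joins curves from different detector distances with a
least-squares multiplicative factor on the overlap and can rebin onto a
log-spaced grid. The q map uses the exact $q = 4\pi\sin\theta/\lambda$.

## Fitting engine

`fit_curve()` minimises
$\sum_i \left[(I_i - I_\mathrm{model}(q_i))/(0.02\, I_i)\right]^2$
with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`); the 2 % relative
error is the conventional weighting for such data and is configurable per
recipe. Recipes (`fit_recipe()`) declare starting values, per-parameter
box bounds, and fixed parameters; fixed parameters are returned
bit-identical with no uncertainty. Parameter uncertainties come from the
Jacobian covariance at the optimum scaled by the reduced χ². Because the
weighting is relative, rescaling a curve (and the three scale factors)
leaves the structural parameters — a, Δa/a, diameter, ΔR/R̄, α —
unchanged.

With the cross-section-area form-factor normalisation, the cylinder term
evaluates to large absolute values, and for correlation-peak-dominated
parameter sets the Gaussian and power-law terms contribute far below the
2 % noise floor. Such parameters are then not identifiable from the data:
the optimizer leaves them wherever the flat likelihood happens to end,
their reported uncertainties are huge, and a parameter whose Jacobian
column is numerically negligible is reported with `stderr = NA`. The
structural parameters are unaffected; this is the expected behaviour of
an over-complete background model, not a fitting failure.

`fit_series()` fits an ordered series (e.g. curves measured every ~30 min
during drying), warm-starting each fit from the last converged result and
applying per-step overrides; the restricted-q-range drying protocol fixes
α = 4 and bounds σ ≤ 0.08. Non-converged steps are flagged, never dropped.

Typical fixed-parameter recipes mirror tabulated practice: SANS fits fix
ΔR/R̄ = 0.2 (the form-factor shoulder is too weak to constrain it), and
fits to dry-state data additionally fix the diameter at 2.0 nm.

## WAXS peak fitting

`fit_waxs()` fits the equatorial wide-angle intensity on
q ∈ [0.5, 2.25] Å⁻¹ with three Gaussian reflections of cellulose Iβ
(1-10, 110, 200, initialised at d = 0.578, 0.521, 0.389 nm), a broad
amorphous Gaussian near 1.4 Å⁻¹, and a straight line. Each reflection
yields $d_{hkl} = 2\pi/q_{hkl}$ and a Scherrer size
$L_{hkl} = 2\pi K/\Delta q_{hkl}$ from the *integral* breadth
($\Delta q = s\sqrt{2\pi}$ for a Gaussian of sd s), with K = 1 by default
(configurable and recorded in the result). No instrumental-broadening
deconvolution is applied, so L values are conventionally read as lower
bounds on the true crystal dimension. Fits whose reflection centres are
not in ascending order are flagged rather than silently repaired.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every pipeline stage can be validated against
a known truth:

* `simulate_curve()` draws $I_\mathrm{obs} = I_\mathrm{model}(1+\epsilon)$,
  $\epsilon \sim N(0, 0.02)$ by default — matching the 2 % relative
  weighting convention — with σ set to the true relative error.
* `simulate_pattern2d()` builds an isotropic radial profile plus
  equatorial Gaussian arcs (at φ₀ and φ₀ + 180°) and draws Poisson counts
  at a chosen exposure; the default geometry (128² pixels, 4 mm pixels,
  1.2 m distance, λ = 6 Å) covers q up to ≈ 0.18 Å⁻¹ like a short SANS
  detector distance.
* `simulate_drying_series()` ramps the truth linearly from a wet-like to a
  dry-like parameter set (a: 4.2 → 3.3 nm, diameter 2.5 → 2.2 nm, C
  rising), emulating the ~20 % contraction of the interfibrillar distance
  seen in drying softwood.

What the generators deliberately do **not** emulate: instrumental
resolution smearing (wavelength spread, collimation), detector artefacts
(flat field, polarization), multiple scattering, and the meridional
streaks of real fibre patterns. Passing recovery tests therefore
demonstrates that the estimator is consistent and stable under realistic
counting noise — not that the model is correct for any particular real
sample, where smearing and imperfect background separation add systematic
error.

## Validation protocol and problem sizes

The bundled reference parameter sets (`reference_params()`) describe wet
softwood: a SANS-like set (a = 4.21 nm, Δa/a = 0.271, diameter 2.04 nm,
Gaussian term present) and a SAXS-like set (diameter 2.51 nm, a = 3.75 nm,
no Gaussian term). The standard validation (`recovery_study()`, also run
by `scripts/acceptance.R`) simulates 20 replicate curves per set — 120
log-spaced q points on [0.005, 0.35] Å⁻¹ (SANS-like) or [0.01, 0.5] Å⁻¹
(SAXS-like) — at 2 % noise, perturbs all free starting values by ±20 %,
and refits. With ΔR/R̄ fixed at 0.2 in the SANS-like protocol (as in the
reference practice) all 40 fits converge and the replicate means land
within a fraction of a percent of the truths. These sizes keep the whole
protocol within a few minutes on a single core; they are stated here as
the package's validation conditions.

## Known limitations

* The cylinder cross-section is circular; elliptical sections and
  microfibril bundling are outside the model.
* Absolute-intensity calibration is not handled; A, B, C are relative
  scales in the units of the input curve.
* The low-q continuation below q₀ is a pragmatic constant; the true
  scattering below the first interference minimum is dominated by terms
  (pores, lumina) the other model components absorb.
* The paracrystalline description breaks down as Δa/a → 0 (Bragg limit)
  and becomes uninformative above Δa/a ≈ 0.8, where the lattice factor is
  essentially flat; bounds in the default recipes keep fits inside the
  meaningful range.
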