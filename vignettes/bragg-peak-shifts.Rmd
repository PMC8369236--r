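---
title: "Bragg-peak shifts and dose asymmetry in a uniform magnetic field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bragg-peak shifts and dose asymmetry in a uniform magnetic field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggshift)
```

## The problem

In MRI-guided proton therapy the scanned pencil beam traverses the imager's
main magnetic field. The Lorentz force bends the proton track into a spiral,
so the Bragg peak — the sharp dose maximum at the end of the range — no
longer sits where the field-free plan put it. Two scalars summarize the
displacement for a beam entering a water phantom perpendicular to a uniform
field $B$:

* $WD$, the lateral shift of the Bragg-peak position perpendicular to both
  the beam axis and the field, and
* $\Delta DD$, the retraction (shortening) of the penetration depth along
  the incident direction caused by the curved path.

This package combines a closed-form model of both quantities with a
desk-scale transport surrogate that scores full 3D dose grids, plus the
analysis metrics used to quantify how the planar spot shape at the peak is
distorted (axis-wise Gaussian sigma ratios, inscribed/circumscribed isodose
circles, and a rotating FWHM scan).

## The analytical model

Ranges follow the Bragg–Kleeman rule $R = \alpha E_0^p$, with
$\alpha = 2.43\times10^{-3}$ cm MeV$^{-p}$ and $p = 1.75$ for water; the
consistent stopping power is $S(E) = E^{1-p}/(\alpha p)$, and curvature is
$\kappa = q B / (p c)$ via the rigidity constant 0.29979 GeV T$^{-1}$
m$^{-1}$. To leading (small-angle) order, integrating the curvature of the
CSDA depth–energy profile twice gives the lateral shift, and the
accumulated $\tfrac12\theta^2$ path-length excess gives the retraction:

$$WD = \frac{7}{12}\,\frac{qB}{\sqrt{2m}}\,\alpha^2 E_0^{3},
\qquad
\Delta DD = \frac{q^2B^2}{2m}\,\alpha^3 E_0^{3p-1}
\frac{2p^2}{(4p-1)(3p-1)},$$

where the $7/12$ and cubic exponent are the $p=1.75$ specialization of a
general-$p$ form the package implements (`lateral_shift()` exposes the
general shape factor, so a refitted $\alpha, p$ stays self-consistent). A
first-order relativistic correction multiplies $WD$ by
$1 - \tfrac38 E_0/(2mc^2)$. Both formulas invert algebraically
(`energy_for_lateral_shift()`, `energy_for_depth_retraction()`), which is
the clinically interesting direction: given the displacement needed to
clear an organ at risk and the scanner's field strength, they return the
incident energy. The inverses are exact for the non-relativistic forms, so
those are the defaults; round trips close to $10^{-9}$ relative, which the
test suite asserts over random energy/field pairs.

The forward formulas are validated in the tests against independent
midpoint-quadrature oracles of the defining integrals
($WD=\iint\kappa\,dz'\,dz$, $\Delta DD=\tfrac12\int\theta^2 dz$) to 0.5%
over 70–270 MeV and 0.5–3 T.

## The transport surrogate

`integrate_central_track()` advances the central trajectory with exact
circular arcs of $\kappa(E)\,\mathrm{d}s$ per step, with the residual
energy following the closed Bragg–Kleeman schedule
$E(s) = ((R_0 - s)/\alpha)^{1/p}$ (the exact CSDA solution, so no energy
integration error accumulates). The default step is 0.01 cm; halving it
moves the endpoint by well under 0.1 mm. Tracks stop at the 0.1 MeV cutoff
and the residual is deposited locally.

A deliberate design choice: the default curvature uses the
*non-relativistic* momentum $\sqrt{2mc^2E}$, making the integrator the
exact-geometry counterpart of the closed-form model; with relativistic
rigidity the two drift apart by up to ~7% in $\Delta DD$ at 170 MeV/3 T,
while reference Monte Carlo transport is reported to agree with the
(non-relativistically derived) formula to 0.1 mm. The relativistic form is
available via the `relativistic` flag on every affected function.

`simulate_dose_grid()` scores deposited energy on a voxel grid in two
modes:

* **mc** — condensed-history sampling (compiled): entry positions from the
  5 mm Gaussian spot, Highland multiple-scattering kicks
  ($X_0 = 36.08$ cm) each 0.05 cm step, and Gaussian range straggling with
  $\sigma_R = 0.012\,R^{0.935}$ cm applied as a per-history arc-length
  stretch, so every history still deposits its full energy and the
  energy-conservation invariant is exact. Reproducible bit-for-bit from
  the seed.
* **pencil** — deterministic: the central track carries a longitudinal
  straggling convolution and an analytic lateral Gaussian whose width is
  the entrance spot combined in quadrature with the accumulated scattering
  width $\sigma^2_{\mathrm{MCS}}(s) = \sum_i \theta_{0,i}^2 (s-s_i)^2$,
  projected onto the slab with the local track inclination.

The two modes agree on the peak depth within one voxel and on planar
sigmas within a few percent. The default phantom is 20 × 20 × 35 cm with
0.5 × 0.5 × 1 mm voxels; tests and the worked examples use reduced extents
(e.g. 12 × 6 × 17 cm for the 141/148 MeV examples, 2 × 10⁵ histories for
Monte Carlo studies) purely as the package's own desk-scale problem sizes —
peak localization uses parabolic sub-voxel refinement, so sub-millimetre
shifts are resolved on millimetre grids once they span a few voxels.

### What the surrogate emulates, and what it does not

It emulates: the curved central axis, the Bragg depth-dose with realistic
peak width, lateral spread growth from multiple Coulomb scattering, the
entrance spot, and the coupling between range straggling and lateral
deflection. It omits: nuclear interactions (so the entrance-region dose
and the low-dose halo are not faithful), secondary particles, energy-loss
straggling beyond the Gaussian range perturbation, non-uniform fields, and
oblique incidence. Two consequences matter for interpreting results:

* Absolute planar FWHM values and entrance-dose ratios are not comparable
  to full Monte Carlo transport; the rotating-FWHM machinery is therefore
  validated against constructed Gaussians with known covariance, not
  against published absolute widths.
* The field-induced *planar ellipticity* at the Bragg peak is only ~1% in
  this physics model at 100–200 MeV — much weaker than full-transport
  studies report. At desk-scale statistics (2 × 10⁵ histories) the
  energy-ordering of sigma ratios and isodose-circle radius differences is
  dominated by fit and contour noise, so a pass or fail of those ordering
  checks at one seed should not be read as reproducing (or refuting) the
  full-transport asymmetry trend. The deterministic signatures the
  surrogate does reproduce — the shift magnitudes, their $B$ and $B^2$
  scalings, and the proximal-tail half-width asymmetry along the bending
  axis — are asserted instead wherever a hard assertion is appropriate.

## Measurement conventions

* Geometry: beam along $+z$, field along $+y$, bending in the $x$–$z$
  plane; $q\,\vec v\times\vec B$ deflects a proton toward $-x$; the sign is
  recorded in provenance, analyses report magnitudes.
* Planar axes at the peak are relabelled $u$ (bending axis) and $v$ (field
  axis); field-induced distortion is expected along $u$. The sigma ratio
  is $\sigma_u/\sigma_v$, stated in its output.
* $WD$ is measured from the *field-free beam axis* (the entry axis), as in
  the schematic geometry of the displacement; $\Delta DD$ as field-free
  peak depth minus in-field peak depth; the deflection angle uses the
  retracted depth as the adjacent side,
  $\arctan(WD/(R-\Delta DD))$.
* Isodose levels default to 0.8/0.5/0.2 of the planar maximum (relative
  levels; the choice of three levels is configurable). The IC/EC fit
  minimizes the annulus area $\pi(r_{EC}^2 - r_{IC}^2)$ over a shared
  center found by a coarse bounding-box grid followed by Nelder–Mead; it
  is rotation- and translation-invariant to the $10^{-3}$ cm optimizer
  tolerance and returns zero radius difference for circles.
* The FWHM scan rotates a line through the refined peak in the bending
  plane (default; field plane by flag) in 1° steps, sampling by trilinear
  interpolation, with linear interpolation of the half-maximum crossings.
  Peak ties break toward smaller depth, then smaller $|u|$, for
  determinism.

## Numerical and degenerate-input behaviour

Zero energy maps to zero range/shift; zero field to zero curvature and
zero shifts; inverting a non-zero shift at zero field is an error rather
than an infinity. Dose grids that are identically zero, profiles without
positive mass, contours cut by the slab boundary, and collinear contours
all raise informative errors. Gaussian fits start from moments and fall
back to direct least squares when `nls` declines a zero-residual problem.
Sub-cutoff residual energy is deposited locally. Below-voxel quantities
(e.g. $\Delta DD \lesssim 0.05$ cm at low energies) are not measurable
from grids at any sensible voxel size; grid-based shift validation is
therefore asserted where the retraction spans several voxels, while the
closed-form/track agreement is asserted across the whole energy–field
grid.

## Limitations

Protons only, perpendicular incidence only, uniform field only, water
only. Percentages and absolute widths that depend on full Monte Carlo
transport physics are carried as read-only packaged reference tables (with
checksums) and exercised through the comparison arithmetic, not
recomputed. The pencil mode's slab projection approximates the transverse
width by $\sigma/\cos\phi$ of the local track angle, adequate below the
~30° deflections reached at 200 MeV/3 T.
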