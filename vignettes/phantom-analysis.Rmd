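---
title: "Quantitative system-phantom analysis: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative system-phantom analysis: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysphantom)
```

# Scope

`sysphantom` analyses images of the ISMRM/NIST-style MRI system phantom: a
200 mm water-filled sphere carrying a 57-sphere fiducial lattice, three
14-sphere MR parameter arrays (NiCl~2~, MnCl~2~, proton density), two
resolution insets, and a pair of opposed 10° wedges. The package measures
geometric distortion and image uniformity, T~1~ (inversion recovery and
variable flip angle), T~2~ (spin echo), proton density and SNR, in-plane
resolution, and slice profile. A digital-reference-object (DRO) simulator
renders synthetic phantom series with known ground truth, so every analysis
stage is validated in a closed loop without scanner data.

# Phantom geometry

The layout is built in phantom coordinates (mm): +X left, +Y posterior
(down), +Z superior, origin at the centre of the central fiducial sphere.
The fiducial lattice is a central 3×3×3 block on a 40 mm cubic grid plus
five spheres at each of the six outward faces; all spheres have 10.0 mm
inner diameter. Plates lie in coronal (XZ) planes on the same 40 mm grid,
ordered posterior to anterior; numbering proceeds from plate 1, right to
left, inferior to superior, which places the central sphere at index 29 and
reproduces the plate census of 5/13/21/13/5 spheres. The exact five-sphere
face pattern is not enumerated in public descriptions of the lattice; we
use the face-centre grid point plus its four in-plane 40 mm neighbours (a
cross), which is the cubic lattice clipped to the shell. The layout
serializes to JSON at full floating-point precision (17 significant
digits), so it round-trips bit-exactly and can be replaced wholesale with
coordinates taken from the published 3D model files.

Each parameter array has ten 15 mm-ID spheres equally spaced on a 50 mm
radius ring and four on the interior 40 mm grid. Array planes are offset
14 mm from their plates; the offset is a mounting convention — only the
relative in-plane geometry enters any analysis.

Each resolution inset carries five hole sizes (fine 0.4–0.8 mm, coarse
0.6–1.0 mm), each a 4×4 array with centre-to-centre pitch of twice the
hole diameter (the convention of the accreditation-phantom insets the
design mirrors), duplicated at 10° sharing one corner hole: 31 holes per
size, 155 per inset. Rotating the duplicate about the shared corner on the
same side would overlap the neighbouring hole (a 10° rotation displaces it
by only 0.17× the pitch), so the duplicate is the point-reflected grid
through the shared hole rotated by 10° — still a 4×4 array at 10° sharing
exactly one hole, with no overlaps.

```{r}
lay <- phantomLayout()
lay
```

# The simulator

`renderVolume()` rasterizes the layout at the configured acquisition.
Signal models are the standard closed forms, per region (PD, T~1~, T~2~):

* Inversion recovery (magnitude): $S(TI) = |A\,(1 - (1+\delta)e^{-TI/T_1})|$,
  with $\delta$ the inversion efficiency (1 = perfect 180° pulse) and $A
  \propto$ PD.
* Spoiled gradient echo: $S(\alpha) = S_{90}\sin\alpha\,(1 - E)/(1 -
  E\cos\alpha)$, $E = e^{-TR/T_1}$, maximal at the Ernst angle
  $\cos\alpha_E = E$.
* Spin echo: $S(TE) = S_0\, e^{-TE/T_2}$.

Partial volume is handled by 3× per-axis supersampling of boundary voxels;
each sub-cell contributes a linearly ramped indicator over its own width
rather than a hard threshold, which suppresses alignment-dependent
quantization (painted sphere volumes are accurate to ~0.2% at 1 mm voxels;
the shipped tolerance is 1%). Geometric distortion is a similarity
transform composed with a low-order polynomial displacement evaluated at
sphere centres; receive bias is a smooth multiplicative field (uniform,
linear, or radial); noise is Rician — Gaussian draws on two quadrature
channels followed by the magnitude — because every analysis in the package
operates on magnitude images (a Gaussian option is retained for estimator
oracles). Renders are deterministic: a configuration plus its seed fixes
every voxel.

What the DRO does *not* emulate: Gibbs ringing from sphere walls (the
inset synthesis models k-space truncation exactly, but 3D sphere renders
are band-unlimited rasterizations), B~0~/B~1~ field maps, eddy currents,
chemical shift, dielectric resonance, and temperature drift. Passing the
closed-loop tests therefore demonstrates correctness of the estimators
under the stated models, not robustness to every scanner artifact.

The background fill renders as long-T~1~ water (T~1~ = 3100 ms, T~2~ =
1800 ms at the simulated field), so short-TR gradient-echo protocols show
the fiducials bright on a dim background, as on a scanner, and the
proton-density protocol sees a water background that serves as the local
normalization reference. The protocol presets (`acquisitionPreset()`)
encode the recommended series: 3D GRE at 1 mm isotropic (TR 6.3/TE 1.89
ms) for the fiducial analysis; IR with ten TIs from 50 to 3000 ms at TR
4500 ms; VFA with flips 2–30° at TR 5.37 ms; SE with TE 10–320 ms in 10 ms
steps at TR 5000 ms; and a two-repeat SE protocol for SNR.

# Fiducial analysis

Sphere localization cross-correlates the image with a noiseless rendered
sphere kernel (mean-subtracted, so constant background does not bias the
peak), computed over the whole volume by FFT. Each sphere's peak is sought
within ±10 mm of its nominal position (capped at half the 40 mm lattice
spacing to prevent neighbour capture) and refined to sub-voxel precision
by a full 3D quadratic fit to the 3×3×3 neighbourhood; offsets are clamped
to one voxel. On 1 mm renders the mean centre error is ~0.02 mm noiseless
and stays well below 0.1 mm at SNR 50.

Defect rejection is numeric: a sphere is flagged when its peak sits on the
search-window edge, its correlation falls below 0.6 of the median peak, or
its integrated ROI intensity deviates more than 40% from its group median
(air bubbles present this way); thresholds are configurable and flagged
spheres are excluded downstream.

The phantom-to-scanner map is a similarity transform (rotation,
translation, isotropic scale; reflections disallowed) fitted to the
unflagged correspondences by the closed-form weighted orthogonal-Procrustes
solution (SVD of the weighted cross-covariance). The "generalized"
iteration matters only when flagging changes the point set, in which case
the fit is simply repeated. Geometric distortion is the per-sphere residual
$\delta \vec R = \vec R_a - (s R \vec R_p + \vec t)$, reported per axis and
per fiducial group; the scale factor measures overall gradient calibration.
Uniformity is each sphere's integrated 10 mm-ROI intensity normalized to
the maximum unflagged sphere (the reference sphere for this normalization
is a declared choice; normalizing to the mean would change only the axis
scale). Local volume distortion is the above-half-maximum intensity support
counted on a 3× interpolated sub-grid, as a ratio to the nominal sphere
volume; a locally 1.1× scaled region reads ≈1.33.

# Relaxometry

The IR fit uses the magnitude model directly — no polarity restoration,
since phase is typically unavailable. The absolute value makes the
objective non-smooth at the signal null, so the optimizer is seeded from a
variable-projection grid (40 log-spaced T~1~ values × 4 inversion
efficiencies, amplitude solved linearly) before Levenberg–Marquardt
refinement; standard errors come from the Jacobian-based covariance. Both
ROI-mean fitting and voxel-map fitting (fit every ROI voxel, average the
T~1~ values, not the signals) are provided and agree within combined
errors on simulated data. The shortest-T~1~ elements recover with few
informative points and correctly carry much larger standard errors.

The VFA fit initializes from the standard linearization
$S/\sin\alpha = E \cdot S/\tan\alpha + S_{90}(1-E)$ and warns when all
flip angles sit on one side of the fitted Ernst angle (ill-conditioned).
The T~2~ fit excludes points at or below a noise floor before fitting; the
floor is mean + 2 SD of a signal-free background sample (the multiplier is
configurable — the level used on scanner data is not standardized), and an
optional first-echo drop handles the anomalously low first spin echo seen
on some systems. Excluded points are recorded with reasons. Relaxivity
fits regress rate (1000/T, s⁻¹) on concentration with the intercept fixed
to the water rate by default.

Reference tables shipped under `inst/extdata/` are **synthetic**: public
sources print only anchor values (fiducial T~1~/T~2~ = 407/347 ms; the
Ni-12 archival pair 44.53/31.86 ms), and the arrays are stated to span
roughly 20–2000 ms in a factor-of-√2 progression, which anchored at Ni-12
reproduces both printed endpoints. Real phantoms should substitute their
calibration certificate via `referenceTable(path)`.

# Proton density and SNR

Receive-coil bias varies severalfold across the phantom, so raw PD-array
means are not proportional to proton density. Each sphere's ROI mean is
normalized by its local background — four small spherical samples 3 mm
outside the sphere wall at ±x/±z in the plate plane — then scaled so the
100% sphere reads 100. A point-symmetric sample quad cancels the curvature
of a smooth bias field to second order, so when a sample would land inside
another sphere the whole quad is rotated in-plane (15° steps) rather than
dropping individual points; this keeps worst-case errors under 5
percentage points even for a factor-6 edge-to-centre bias. SNR follows the
two-acquisition difference method: $N = SD(S_2 - S_1)/\sqrt{2}$ per ROI,
$SNR = \bar S/N$; identical inputs are flagged rather than reported as
infinite. The method assumes negligible inter-scan drift; a large
background-ROI variant is intentionally de-emphasized because it is more
drift-sensitive.

# Resolution

The inset image is synthesized analytically: each hole contributes the
exact disk spectrum $a J_1(2\pi a q)/q$ phase-shifted to its centre,
multiplied by the Gaussian PSF transfer function, truncated to the finite
k-space window implied by the voxel size, and inverse-transformed. The
reconstruction is taken as a magnitude image by default — scanners export
magnitude, and the folded Gibbs undershoot is precisely what limits visual
resolvability of the smallest holes. The PSF width is estimated by a 1D
grid search (0.005 mm steps) minimizing the L2 difference to the measured
image after a least-squares amplitude + offset match; the residual curve
is reported and a boundary minimum raises a warning. The report separates
resolution into the sampling-limited component (the voxel size) and the
Gaussian broadening 2σ.

The visual resolvability rule is automated as: a hole-size group is
resolved when, in every row and column of both its 4×4 blocks (0° and
10°), each hole-centre intensity exceeds the midpoints to its neighbours
by 10% of the block's local dynamic range. On a 0.35 mm-voxel synthetic
with no extra blur this yields 0.5 mm as the smallest resolved fine-inset
group (the 0.4 mm group fails the margin on the magnitude image), matching
the outcome reported for scanner data at that voxel size.

# Slice profile

Each wedge ROI (4 × 50 mm) is averaged across its short axis to an edge
response function (ERF); its derivative, with image position scaled by
tan(wedge angle), is the slice profile. With two opposed 10° wedges the
slice-plane misalignment is
$\theta = \tfrac12 \sin^{-1}[(w_2-w_1)\sin 20° / (w_2+w_1)]$ from the two
projected widths, and the NEMA-style thickness is the FWHM (linear
interpolation between samples) of the angle-corrected profile. The
automated method fits each ERF with a continuous flat–ramp–flat
piecewise-linear model (breakpoints free, plateau levels profiled out;
coarse grid then Nelder–Mead), takes $w = $ ramp length, and reports
$t = \tfrac12 (w_1+w_2)\tan 10°$ with an uncertainty from the breakpoint
covariance. That first-order formula carries an intrinsic
$\theta^2/\sin^2 10°$ bias (≈4% at θ = 2°), so the result also includes
`t_corrected_mm` $= \tfrac12[w_1\tan(10°+\theta) + w_2\tan(10°-\theta)]$,
which is exact in θ; both round-trip simulated 3 and 5 mm boxcar slices
within 2% with θ recovered to 0.05°. Derivative smoothing is off by
default and reported when used, because it biases the FWHM. Thicknesses
above the 10 mm wedge height are rejected as unmeasurable.

# Numerical and IO choices

* Voxel indices are 1-based in R; world coordinates are millimetres with
  the voxel (1,1,1) centre at the volume origin. Reports state phantom-frame
  quantities after the similarity transform has been removed.
* Volumes are exchanged as NIfTI-1 plus a JSON sidecar carrying TR/TE/TI/
  flip and geometry; the sidecar is authoritative for timing. Floating
  point NIfTI keeps round trips lossless. Series read back sorted by
  TI/TE/flip regardless of file order; mixed geometry or unreadable files
  abort with the offending file named.
* All randomness flows from explicit seeds; renders restore the caller's
  RNG state.

# Problem sizes used in the shipped tests

The test suite closes the loop at desk scale: whole-phantom renders at
1 mm isotropic voxels (220³ FOV) for the end-to-end distortion/uniformity
check; 27-sphere sub-lattices for localization statistics; 100-repetition
Monte Carlo runs at SNR 100 for relaxometry bias and coverage; 200
repetitions for the SNR estimator and relaxivity coverage. These sizes
give Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping the full suite around a minute of compute.

# Known limitations

* The DRO omits Gibbs ringing in 3D renders; the correlation kernel is the
  clean rendered sphere. On scanner data with strong truncation artifacts
  a finite-k kernel would be preferable (the 2D inset synthesis shows the
  machinery).
* VFA fitting uses the ideal spoiled-GRE model; B~1~-corrected variants
  are out of scope, so VFA deviations on real data reflect flip-angle
  miscalibration as much as T~1~.
* DICOM is not read or written; NIfTI + sidecar is the exchange format.
* The shipped reference tables are synthetic stand-ins (see above), fit
  for simulation and for exercising the deviation formulas only.
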