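---
title: "4DCT lung-function imaging: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{4DCT lung-function imaging: models, phantoms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Respiration-correlated CT (4DCT) captures the lungs at maximum inhale and
maximum exhale. Given a deformable registration between the two phases,
image processing can turn the pair into surrogate maps of regional lung
function: ventilation (local air-volume change) and, under a
mass-conservation model, perfusion (local breathing-induced mass change).
Such maps drive functional-avoidance radiotherapy planning, where the
optimizer preferentially spares high-function lung.

`vent4d` implements four voxelwise function images and the comparison
machinery used to study how much the choice of method matters for planning:
percentile functional contours, Dice overlap, dose-function metrics, reader
agreement, and paired nonparametric statistics. Because clinical 4DCT pairs
with a trustworthy voxel-level ground truth do not exist, the package also
provides a deformable phantom generator whose every quantity is known in
closed form.

## The four function images

All methods consume an exhale HU volume, an inhale HU volume, a
displacement field `u` on the exhale grid (pull convention: exhale point `x`
corresponds to inhale point `x + u(x)`), and a lung mask.

**HU density change (`vent_hu`).** Each voxel is modelled as a mix of
water-like material (HU 0) and air-like material (HU -1000), with the
tissue compartment conserved between phases. Bookkeeping of the air volume
gives the specific air-volume change

$$SV(x) = 1000\,\frac{H_{in}(x) - H_{ex}(x)}{H_{ex}(x)\,(1000 + H_{in}(x))},$$

with `H_in` pulled to the exhale grid through `u`. The formula divides by
`H_ex`, so voxels with `H_ex >= -10` (no measurable air) or pulled
`H_in <= -990` (nearly pure air) are excluded from the output mask rather
than reported as unstable numbers; more than 20% exclusions abort with a
mask/image mismatch error.

**Integrated Jacobian (`vent_ijf`).** The lung is covered by overlapping
cubic subregions. Each subregion's deformed volume is estimated by
hit-or-miss Monte Carlo integration over the mapped region (below), divided
by the region's exhale volume to give a mean volume-change factor with a
known standard error. A voxelwise Jacobian image is then recovered by
constrained linear least squares, with a global equality constraint pinning
the reconstructed total volume to the inhale lung-mask volume.

**Mass-conserving volume change (`vent_mcvc`).** Under mass conservation
the mean Jacobian of a subregion equals the ratio of its mean exhale
density to the mean inhale density sampled at the mapped points. Densities
come from the two-material HU conversion `rho = (HU + 1000)/1000`. The
voxelwise image is recovered by the same least-squares machinery with the
physical inequality bound `J >= 0.05` and no global equality.

**Perfusion surrogate (`perf_image`).** With a Jacobian image `J` in hand
(by default the MCVC reconstruction), the per-voxel mass change per unit
exhale volume is `dm(x) = J(x) rho_in(x + u(x)) - rho_ex(x)`; breathing
perfuses blood in and out of lung regions, so the magnitude `|dm|` acts as
a perfusion surrogate. Subregional means of `|dm|` are reconstructed with
lower bound 0. The sign is discarded at the regional level; the signed
voxel field is retained internally for diagnostics.

## Subregional estimation

**Partition.** A cubic window (default 8 voxels) slides with stride 4
(50% overlap); windows are clipped to the mask and kept when they hold at
least 8 lung voxels; a trailing flush window per axis guarantees boundary
coverage; any mask voxel left uncovered is an error, not a silent gap.
Overlap matters: it is what makes the voxelwise recovery more than
piecewise-constant.

**Hit-or-miss volumes.** Each voxel cell is decomposed into 5 tetrahedra
(with mirror-image tables on odd-parity cells so neighbouring cubes share
face diagonals), corners are mapped through the trilinearly interpolated
field, and `N` points are sampled uniformly in the mapped bounding box.
The volume estimate is (hit fraction) x (box volume). `N` is the smallest
count with worst-case binomial standard error below `tau` times the box
volume, i.e. `N = ceil(0.25 / tau^2)` — halving `tau` quadruples `N`, and
the reported plug-in SE makes every estimate carry its own uncertainty.
Points on tetrahedron faces count as hits; the choice is measure-zero and
fixed for determinism. An exact tetrahedral-sum volume
(`exact_deformed_volume`) serves as the oracle in tests.

**Density ratios and mass changes.** `mcvc_regional_jacobian` propagates
the two within-region sample variances through the ratio (delta method,
covariance neglected); a mean mapped density at or below 0.01 is refused —
that region is air-free or mismapped. `perf_regional_masschange` reports
the mean magnitude and its standard error.

## Voxelwise reconstruction

The recovery solves

$$\min_j \sum_r w_r\,(\mathrm{mean}_{i\in r}\, j_i - v_r)^2
  + \lambda \lVert D j\rVert^2
  \quad \text{s.t. } j \ge \epsilon,\; \textstyle\sum_i c_i j_i = V
  \text{ (optional)},$$

with `w_r = 1/SE_r^2` (floored at `se_floor = 1e-3` so noise-free
estimates cannot carry infinite weight), `D` the first differences between
6-neighbour mask voxels, and `c_i` the voxel volume.

Two numerical points deserve emphasis:

* **The roughness weight is a spatial prior, not a tie-break.** Regional
  means constrain nothing at the voxel scale; the null space is large, and
  with a token penalty the exact optimizer happily dumps sampling noise
  into high-frequency modes. `vent4d` therefore derives the weight from a
  correlation length: `lambda = d (s w / 2)^2` with `d` the mean per-voxel
  curvature of the weighted data term, `w` the window size and `s` the
  `smooth_scale` parameter (default 2). The effective averaging kernel of
  the recovery then has a fixed width of about one window radius per unit
  of `s`, independent of how precise the regional estimates are. Constant
  fields are never biased — first differences vanish on them — and an
  absolute `lambda` override remains available.
* **Solver.** The Hessian is applied as a sparse operator (forming
  `A'WA` densely is quadratic in the neighbourhood size). Bounds are
  handled by an active-set loop; each inner solve is conjugate gradients
  projected onto the equality constraint. The weighted-data +
  small-roughness spectrum is tightly two-clustered, which CG resolves in
  tens of iterations. Projection onto the simultaneous bound + equality
  set reduces to a monotone one-dimensional root-find (the voxel volume is
  constant), solved by bisection; the equality is satisfied to near
  machine precision.

Infeasible configurations (a global volume below `epsilon` times the mask
volume) and non-convergence raise errors with diagnostics; they are never
papered over.

## The phantom

`make_phantom` builds the study scene: an ellipsoidal lung (density 0.2
with a smooth cosine texture of relative amplitude 0.15) inside water-like
body tissue, deformed by an analytic transform. Transforms are restricted
to affine maps and separable monotone polynomials so the Jacobian is in
closed form; the default is uniform expansion with `J = 1.15`, a typical
tidal volume change. The inhale scene is constructed on its own grid by
exact mass conservation, `rho_in(y) = rho_ex(x)/J(x)` at `x = phi^{-1}(y)`
(the inverse found by fixed-point iteration to machine precision), so the
phantom is internally consistent for every method at once.

* **Defects** attenuate the displacement inside a sphere:
  `u -> alpha(x) u` with a C1 radial profile that is fully attenuating on
  a plateau core (`r < radius/2`, where `J = 1` exactly for strength 1)
  and ramps smoothly to no attenuation at `r = radius`. The Jacobian
  ground truth stays exact through the rank-one determinant identity
  `det(M0 + u grad(alpha)') = det(M0) + grad(alpha)' adj(M0) u`.
* **Perfusion anomalies** implant a uniform extra mass `delta` inside a
  sphere, carried through the same mass-conserving construction, so the
  truth mass-change grid is exact.
* **Noise** (Gaussian, default sd 20 HU — typical 4DCT) is added last,
  after the mass-consistent construction, and a seed makes every phantom
  bit-reproducible.
* **Analysis mask.** The mask handed to the estimators is the anatomical
  ellipsoid eroded by 2 voxels. Clinical pipelines likewise exclude the
  lung boundary, airways and vasculature; numerically the margin keeps
  trilinear samples at mapped points inside parenchyma instead of mixing
  lung (0.2) and body (1.0) densities across the boundary.

What the phantom does **not** emulate: real anatomy (no airway tree,
vessels, lobes or sliding at the pleura), registration error (fields are
analytic, not estimated), CT artifacts beyond white noise, and actual
radiologist behaviour (reader calls are simulated at configurable
sensitivity/specificity). Tests passing on the phantom therefore validate
the estimators and the pipeline plumbing — not clinical performance.

## Contours, dose-function metrics, statistics

Function images are compared after conversion to percentile images:
`100 (rank - 0.5)/n` over mask voxels with mid-ranks on ties. The
convention is invariant to any strictly increasing transform — which is
what makes the HU method (a specific volume change) comparable to the
Jacobian methods without rescaling — and sends a constant image to 50
everywhere, so its 75% contour is empty rather than full (the conservative
reading). Contours threshold inclusively at 25/50/75; Dice is
`2|A∩B|/(|A|+|B|)`, with two empty contours defined as overlapping
perfectly (flagged). Dose-function metrics are the unweighted mean dose
over a contour (fMLD) and the percentage of contour voxels at or above
20 Gy (fV20, inclusive); four methods x three levels x two metrics give
the 24 records per patient.

Method differences are tested with a Friedman test (mid-ranks within
patients, standard tie correction, chi-square reference) and post-hoc
two-sided Wilcoxon signed-rank tests: exact signed-rank null for n <= 25
without ties, normal approximation with tie and continuity corrections
otherwise, zero differences dropped with a logged count. The family alpha
0.05 over three comparisons is Bonferroni-corrected and truncated (not
rounded) to three decimals — 0.016, the conventional printed level. A
vectorized null simulation (`wilcoxon_null_calibration`) checks that the
test holds this size; its p-value routine is the same function the
post-hoc test uses, which the suite verifies directly.

Reader agreement reduces binary defect calls to a confusion summary
(sensitivity, precision, specificity, accuracy). In location mode a
positive call only counts as concordant when the called lobe matches; a
wrong-lobe positive on a defect-positive patient scores as a false
positive (the stricter reading; an all-lobes-match variant sits behind
`lobe_match`). Zero denominators yield flagged `NaN`s, never invented
rates. The peritumoral heterogeneity criterion expands the tumor by a
30 mm shell within the lung and passes when function in the shell is at
least 15% below the rest of the lung (inclusive at the boundary).

## Choices made where the design was open

* **What "truth" means for the HU method.** Under mass conservation the
  density-change formula measures specific *air*-volume change, which is
  `(J - 1)/(1 - rho_ex)`, not `J - 1`; at lung density 0.2 the two differ
  by a factor 1.25. Accuracy checks of `vent_hu` therefore compare against
  the air-volume bookkeeping truth (`truth$sv_air` in the phantom), the
  quantity the method actually estimates. Downstream comparisons are
  unaffected: percentile conversion absorbs any monotone rescaling.
* **MCVC ratio orientation.** The exhale grid is the fixed side (mean
  exhale density over the region, divided by the mean mapped inhale
  density). The opposite convention would estimate the inverse Jacobian of
  the reverse map; the choice is documented, not claimed canonical.
* **Percentile ranking over the whole lung**, not per-lung, and one
  caller-supplied mask applied uniformly to all four methods.
* **Problem sizes.** Recovery accuracy is exercised on 48^3 phantoms
  (~10,000 lung voxels, ~365 subregions); the voxelized-mask mass audit
  uses 64^3, where ellipsoid surface discretization drops to ~0.3%; the
  null-calibration simulation uses 5,000 families of three comparisons at
  n = 63 patients. These sizes are the package's validation conditions and
  are stated here so they can be reproduced exactly.

## Known limitations

* The reconstruction's spatial resolution is bounded below by the
  subregion scale; function structure much smaller than a window is
  smoothed (visible as dilution of the implanted perfusion signal relative
  to its true amplitude, while localization is preserved).
* The mean-|dm| perfusion statistic rectifies noise: with HU noise of
  sd 20 the per-voxel magnitude floor exceeds a genuinely conserving
  scene's zero signal, so near-zero conservation statements hold in the
  noise-free limit only.
* Displacement fields are inputs; the package neither estimates
  registrations nor models their errors.
* Reader simulation draws independent Bernoulli calls; real readers are
  correlated across methods and patients.
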