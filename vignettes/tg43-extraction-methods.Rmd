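---
title: "Extracting TG-43 source parameters from 3D dosimetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting TG-43 source parameters from 3D dosimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The AAPM TG-43 formalism decomposes the dose rate around a sealed
brachytherapy source into a dose rate constant, a line-source geometry
function $G_L(r, \theta)$, a radial dose function $g_L(r)$ and a 2D
anisotropy function $F(r, \theta)$.  For most sources, $g_L$ and $F$ come
from Monte-Carlo transport with sparse experimental spot checks.  A 3D
dosimeter read out at sub-millimeter resolution measures the whole
distribution at once: every voxel is an independent sample, and the growing
number of voxels per spherical-shell bin with radius offsets the falling
signal, keeping the standard error of the extracted factors roughly
constant with distance.

This package implements the analysis chain for such a measurement — a
cylindrical radiochromic dosimeter with a channel drilled to mid-height for
source insertion, scanned as a voxel grid of dose-proportional intensity —
together with a synthetic phantom generator so the chain can be validated
end to end against a known ground truth.

## Estimators

With the source pose (active-length midpoint $\mathbf{c}$, unit long axis
$\mathbf{a}$) known, each voxel center $\mathbf{p}_i$ has polar coordinates
$r_i = \lVert\mathbf{p}_i-\mathbf{c}\rVert$ and
$\theta_i = \angle(\mathbf{p}_i-\mathbf{c}, \mathbf{a})$.

**Reference intensity.** $\bar I(r_0,\theta_0)$ is the mean intensity over
ROI voxels with $|r_i - r_0| \le 0.5\,$mm that lie on the transverse plane.
Plane membership is $|\theta_i - \theta_0| \le 0.1^\circ$ *or* perpendicular
distance to the plane $\le 0.5\,$mm.  The pure angular criterion selects no
voxel centers at $r_0 = 1\,$cm unless a voxel plane happens to pass through
the source center (at 0.5 mm spacing it would require a center within
0.017 mm of the plane), so the slab alternative is what makes the bin
well-defined for arbitrary registered poses; on an aligned grid both
readings agree to better than 0.1%.

**Radial dose function.** Transverse voxels (same union rule) yield
per-voxel samples
$$y_i = \frac{I(r_i,\theta_i)}{\bar I(r_0,\theta_0)}
        \frac{G_L(r_0,\theta_0)}{G_L(r_i,\theta_0)},$$
with the geometry correction evaluated at the voxel's radius but the
*reference* angle.  An ordinary unweighted degree-5 polynomial in $r$ is
fit through the unbinned per-voxel samples and renormalized so
$\hat g_L(r_0)=1$; 1-mm radial binning (mean, SD, SE, count) is produced
for reporting only.  Because voxel counts grow like the annulus area, the
fit is dominated by large radii; the residual RMS is retained both as a
quality measure and as one factor of the registration score.

**Anisotropy function.** For each node $(r_j, \theta_k)$ of the reporting
grid (default: radii 0.75–4 cm and angles
$10^\circ$–$176^\circ$), voxels within $\pm 1.0\,$mm and $\pm 0.5^\circ$
contribute terms
$$\hat F_i = \frac{I(r_i,\theta_i)}{\bar I(r_0,\theta_0)}
             \frac{G_L(r_0,\theta_0)}{G_L(r_i,\theta_i)}
             \frac{1}{\hat g_L(r_i)},$$
whose mean, SD and SE $=$ SD$/\sqrt n$ are recorded per bin.  The typeset
form of this estimator is a bare sum over bin voxels; it is implemented as
the mean, which is the only reading under which
$\hat F(r_0, \theta_0) = 1$.  Bins with fewer than `n_min` voxels
(default 5) or containing radii outside the radial fit's data range are
flagged and left blank in tables — mirroring the empty cells of published
comparisons, whose occupancy floor is not stated.  Comparison tables report
$100(\hat F/F_\mathrm{ref}-1)$ with cells formatted as
`percent ± SE% (count)`.

**Geometry function.** The line-source form
$G_L = \beta/(L\,r\sin\theta)$, with $\beta$ the angle subtended by the
active length, is computed as
$\beta = \operatorname{atan2}(\rho L,\; r^2 - L^2/4)$ where
$\rho = r\sin\theta$ — a single expression that is exact in all quadrants
(including $r < L/2$ beside the source), continuous into the on-axis limit
$(r^2-L^2/4)^{-1}$, and reduces to $1/r^2$ as $L \to 0$.  Points on the
active segment itself are a domain error.  The point-source variant
$G_P$ is deliberately not implemented: the line-source form is the one the
extraction equations name.

## Source pose registration

The pose is recovered by minimizing
$$S(\mathbf{c}, \mathbf{a}) = \mathrm{RMS}_\mathrm{radial}
  \times \overline{\mathrm{SD}}_\mathrm{anisotropy},$$
the product of the radial-fit residual error and a count-weighted mean of
the within-bin SD of the per-voxel anisotropy terms.  The second factor is
one concrete reading of "residual error" for $\hat F$: it needs no external
reference table, and it is pose-sensitive because a wrong pose mixes
genuinely different $(r, \theta)$ into one bin.  An alternative (residual
to a smooth fit in $\theta$) would also work; the choice is isolated in
`pose_score()` and swappable.

Initialization comes from the drilled channel itself: interior voxels
excluded from the material mask form a cylindrical cloud whose principal
direction gives the axis and whose terminal full-bore slab gives the tip
(the one-voxel-wide carving left by the source line protruding past the
tip is ignored by requiring a slab to hold at least half the median
cross-section count).  The axis sign points from the drilled face toward
the tip, which resolves the $180^\circ$ ambiguity whenever the anisotropy
is asymmetric.

Minimization is derivative-free Nelder–Mead over five parameters
(three translations, two axis-deviation components in the tangent plane of
the initial axis), with a 1 mm translation scale, score tolerance
$10^{-8}$, and up to 500 iterations per run.  Two optimizer behaviors
required explicit handling.  First, the 5-simplex reliably collapses along
the weakly curved orientation directions before the translations finish
converging, so the minimizer restarts from the incumbent with a fresh
simplex until the score stops improving (at most 4 restarts).  Second, on
noisy volumes the score has micro-roughness at the $\sim0.1^\circ$ scale
(rotating the axis re-assigns a fraction of voxels between anisotropy
bins, resampling their noise), which traps simplices whose orientation
steps start below that scale; the orientation scale is therefore 0.1
(initial steps $\approx 0.6^\circ$), and the contracting simplex still
resolves the axis to well below $0.1^\circ$ on clean data.
Candidate poses at which the reference bin is empty score $+\infty$ and
are rejected without raising an error.  Registration is deterministic:
identical volume, initialization and options give an identical trace.

## The synthetic phantom

`build_phantom()` voxelizes a cylinder (default 9.5 cm diameter, 9.2 cm
height — a 190 × 190 × 184 grid at (0.5 mm)³) with a 0.35 cm channel from
one flat face to mid-height, seats the source with its active-length
midpoint at the channel tip and axis along the channel, evaluates the
TG-43 product at every material voxel center with the prescription
(default 5.3 Gy at $r_0 = 1$ cm, $\theta_0 = 90^\circ$) as the reference
dose, and adds noise.  Ground truth (pose, spec) is returned and written
as a JSON sidecar, so recovery experiments never re-derive it from the
data.

Design choices that matter:

* **Grid alignment.** The grid is symmetric about the cylinder center with
  voxel centers at $\pm(k-\tfrac12)\,\Delta$: no voxel center column
  coincides with the source axis.  The degenerate axis-on-center alignment
  makes the lattice radii inside thin annular bins coherently skewed
  (mean lattice radius 0.9956 cm in the reference annulus instead of
  1.0000), which biases the reference bin by about $+1\%$ — an artifact an
  arbitrarily seated physical dosimeter does not exhibit.  The symmetric
  grid behaves like the continuum ($+0.08\%$).
* **Source line exclusion.** The seating convention places the lower half
  of the active segment beyond the channel tip, inside material.  Voxel
  centers within half a voxel of the active segment are excluded from the
  material mask (the line-dose there is singular and a real reading would
  be inside the source); everything else is kept, however hot.
* **Noise model.** The reports this package emulates show per-bin scatter
  but state no noise model.  The default is additive Gaussian with
  constant $\sigma$ in dose units, $\sigma = 1\%$ of the prescription
  (consistent with near-constant standard error along the transverse plane
  when counts grow like $r$); a dose-proportional variant is available.
  $\sigma$ is a free simulator parameter, not a calibrated one.
* **Units.** The optical-density-to-dose conversion of a real readout is
  assumed linear and absorbed into the intensity units: the simulator
  emits Gy directly.  Lengths in configs are cm, except voxel size and
  tolerances, which are mm; field names carry their units.
* **What is not simulated.** Optical-CT physics (projection, refraction,
  scatter, reconstruction artifacts), energy response, signal diffusion
  and drilled-surface damage are all outside the generator.  Passing
  recovery tests therefore demonstrates the correctness of the estimators
  and the pipeline, not the accuracy of any physical measurement.

The bundled source model (`synthetic_source_model()`) is labeled synthetic:
a 1.48 cm active length, a smooth low-order-polynomial $g_L$ close to the
mild fall-off of a high-energy (Cs-137-like) source, and an anisotropy
table $F = 1 - a(r)\cos^2\theta + 0.06\cos^3\theta$ sampled on a
27-angle × 10-radius grid, with the cable side a few percent lower than
the tip side.  The published reference tables for any real source are a
required user input; none are shipped.

## Numerical choices and degenerate inputs

* $g_L$ tables interpolate with a monotone (Fritsch–Carlson) piecewise
  cubic; polynomial models use Horner evaluation.  Both are expressed as a
  ratio to their value at $r_0$, making $g_L(r_0) = 1$ exact in floating
  point; the same ratio trick makes $F(r,\theta_0) = 1$ and
  `tg43_dose()` at the reference point exact.  Requests outside a curve's
  valid radial range are errors, never silent extrapolation; anisotropy
  lookups beyond the table hull clamp to the nearest row/column and carry
  an `extrapolated` flag.
* ROI rules run in a fixed order — material mask, then non-positive
  exclusion, then ball erosion (default radius 1.5 mm = 3 voxels, a knob) —
  so eroding after the defect exclusion removes a shell around
  imperfections as well as the surface.  Erosion that empties the mask is
  an error naming the radius.
* Bin assignment uses half-open interval bisection when tolerance windows
  do not overlap and falls back to a per-bin scan when they do (adjacent
  $1^\circ$-spaced angle bins with $\pm0.5^\circ$ tolerances share edges;
  an edge value goes to the upper bin).
* Radial bins with one voxel report `NA` SD/SE rather than zero.
* A voxel exactly at the source center ($r=0$, $\theta$ undefined) is
  flagged and excluded from every downstream estimator.

## Problem sizes used in the shipped validation

The test suite and the acceptance script choose sizes that keep a full run
on one CPU comfortable while preserving the voxel size that sets every
discretization scale: the default 9.5 cm phantom at (0.5 mm)³ for the
radial/anisotropy/reference-bin recovery checks; a half-scale 5 cm × 4.8 cm
cylinder at the same (0.5 mm)³ resolution for registration recovery (the
perturbations and tolerances are sub-voxel, so resolution — not cylinder
size — is what matters); and coarse 1 mm phantoms for unit tests of
plumbing.  Statistical checks (SE doubling under doubled $\sigma$) use
five fixed seeds.

## Known limitations

* The radial fit is a global degree-5 polynomial: adequate for smooth
  high-energy sources, but it will ring for sources whose $g_L$ has strong
  curvature at small $r$; deviations beyond the fitted radial range are
  flagged rather than extrapolated.
* The registration score's anisotropy factor measures within-bin spread
  only; with very smooth anisotropy *and* heavy noise the orientation
  signal is weak, and the recovered axis is correspondingly less precise
  than the center.
* Real-measurement systematics — dosimeter edge effects that depress the
  radial function beyond 3 cm, channel-wall partial-volume voxels,
  refraction near the surface — are not modeled and not compensated;
  the ROI erosion radius is the only mitigation exposed.
* Merging multiple irradiations (e.g. a reversed-orientation second
  volume to fill the channel shadow) is supported only to the extent that
  the simulator can generate such volumes; joint estimation is not
  implemented.
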