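---
title: "Designing and commissioning a divergence-matched proton GRID collimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and commissioning a divergence-matched proton GRID collimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridcollim)
```

## The problem

Spatially fractionated radiotherapy (SFRT, "GRID" therapy) treats bulky
tumors with a lattice of narrow high-dose channels ("peaks") separated
by low-dose "valleys", rather than a uniform dose bath. On a compact
proton machine the pencil-beam spots are too wide for useful peak/valley
contrast, so the classical solution is a thick brass block pierced by a
hexagonal pattern of circular channels, mounted on the nozzle snout.
Because the scanned beam diverges from an upstream virtual source, each
channel must be tilted ("divergence-matched") so that its axis points at
that source; otherwise the block shadows its own channels and the
optimizer wastes monitor units forcing fluence through mismatched holes.

`gridcollim` models this entire desk-side commissioning workflow:

1. **Aperture design** — hexagonal layout, per-channel tilts, watertight
   STL mesh of the block, and mass/volume reporting.
2. **Placement** — homogeneous 4x4 transforms that place the block for
   arbitrary gantry/couch angles and snout extensions.
3. **Planning structures** — divergence-matched optimization cylinders
   through every channel, cropped to a depth slab, plus the cuboid
   scoring PTV.
4. **Synthetic GRID dose** — an analytic raster-scanned pencil-beam
   engine standing in for a Monte Carlo TPS calculation.
5. **QA analytics** — 2D gamma index, SFRT metrics (Dxx, Dmean, PVDR,
   D90/D10, gEUD), and detector-chain models (chamber array,
   partial-volume averaging, scintillator saturation, film
   calibration).
6. **Robustness** — gamma pass rate versus simulated collimator
   mis-positioning, Gaussian fits, and positional tolerances at a 90%
   pass-rate threshold.

## Geometry model and conventions

The frame is right-handed with the origin at isocenter; +z points from
isocenter toward the snout, x is crossline, y inline. Angles are stored
in degrees and converted to radians at a single internal boundary.

The default block is 270 x 215 x 50 mm brass (8.4 g/cm^3) with 77
channels of 15 mm diameter in 9 rows: odd rows carry 9 holes, even rows
8, offset by half a pitch (20.35 mm crossline, 23.50 mm inline) — the
densest circle packing for the target peak spacing. The nominal pitches
are defined on the *downstream* face, which is placed at the divergence
match plane 195 mm from isocenter (a 235 mm snout extension minus the
40 mm snout-to-mount offset). Some surface must carry the nominal
pitches and the match plane is stated at 19.5 cm, so the downstream
face is the natural choice; the upstream openings are displaced by
`thickness * tan(tilt)`.

### Channel tilts

A channel at lateral offset u cm is nominally tilted by `u * rate`
degrees (0.375 deg/cm crossline, 0.324 deg/cm inline), which corresponds
to virtual sources 1527.9 and 1768.4 mm upstream of the match plane.
Composing the two nominal tilts as literal rotations does not make the
outermost axes meet the virtual source exactly — a tan() versus
linear-angle mismatch of up to ~1.5 mm at the face corners. We instead
define each axis to point *exactly* at the per-axis virtual source,

$$\mathbf{d} \propto \left(-\frac{x}{D_x}, -\frac{y}{D_y}, 1\right),$$

and report the nominal tilt angles alongside. The two definitions agree
to better than 1e-4 rad everywhere on the face, so either is within
machining tolerance; the convergent definition makes every downstream
projection an exact similar-triangles scaling, which the planning and
dose modules rely on.

### Placement transforms

`beam_transform()` builds the rigid 4x4 placement matrix from the
gantry and couch angles with the standard rotation block (first row
$\cos\theta_g\cos\theta_c, -\sin\theta_g\cos\theta_c, \sin\theta_c$,
and so on); its orthonormality (det = +1, to 1e-12) is asserted by a
validity contract. The analogous cylinder placement uses the proper
rotation $R_x(\theta_y) R_z(\theta_x)$: a commonly printed variant of
this matrix is not orthonormal as typeset, and a rigid transform is the
only physically meaningful reading, so the nearest valid rotation
consistent with the stated per-axis divergences is used.

### Mesh construction

The block mesh is built by **direct boundary construction**, not boolean
CSG: each face is tessellated into per-hole rectangular cells (an
annulus of triangles between the hole polygon and the cell boundary)
plus filler rectangles, channels become tubes joining the two face
openings, and four side walls close the solid. All shared cell edges
use a single subdivision rule, so the mesh is watertight *by
construction* — no boolean robustness failures, no T-junctions. Channels
are circles swept along the tilted axis (exact circular openings); a
true tilted cylinder differs by a factor $1/\cos\theta \le 1.0004$ in
volume at these sub-1.5 degree tilts. With the default 64 facets per
circle the mesh volume is within 0.1% of the analytic
cuboid-minus-channels value.

```{r mesh}
spec <- collimator_spec()
mesh <- build_collimator_mesh(spec, n_facets = 32)
mesh_is_watertight(mesh)
collimator_mass(spec, mesh)  # kg, reported; never asserted to a nominal
```

The computed mass (~18.7 kg) is reported but deliberately never asserted
against a nominal figure: quoted masses for such blocks typically
include mounting hardware or conservative rounding.

## Planning structures

`generate_cylinders()` threads one cylinder per channel, collinear with
the channel axis extended into the phantom and cropped by two planes
perpendicular to the beam axis at 5 and 15 cm depth (the isocenter sits
at 10 cm depth; dose peaks and valleys are governed by lateral geometry
so this depth slab is where SFRT metrics are scored). Diameters of 5,
10 and 15 mm are the clinically explored set; 10 mm (two-thirds of the
channel diameter) is the default since optimization cylinders matching
the physical aperture push spots onto the channel edges where scatter
is worst. The scoring PTV is the axis-aligned bounding cuboid of all
cropped cylinders with a 5 mm lateral margin. Rasterization uses the
voxel-center inclusion rule on a 1 mm default grid.

## The synthetic dose engine

The engine replaces a Monte Carlo TPS calculation with the minimal
physics the commissioning analytics actually exercise:

* a **raster of Gaussian spots** (default sigma 12 mm at the collimator
  plane, 2.5 mm spacing — typical of compact synchrocyclotrons at
  therapeutic energies) whose fluence is multiplied by the aperture
  **transmission map** (1 in the projected openings,
  `brass_transmission = 0.005` elsewhere) in the thin-collimator
  approximation;
* projection of the pattern from the per-axis virtual sources, so peak
  center-to-center distances grow with depth exactly as similar
  triangles dictate;
* lateral convolution with a depth-dependent Gaussian
  (`mcs_sigma_rate = 0.4` mm per cm of depth) for multiple Coulomb
  scattering in the phantom;
* a **flat depth-dose plateau** between 5 and 15 cm. No Bragg-curve
  model: peak spacing and PVDR in a GRID field are governed by lateral
  geometry, not by proton energy, so a plateau suffices for every
  analysis in this package.

Dose is exactly linear in monitor units. The engine does **not** model
channel-edge scatter, nuclear halo, or detector-specific energy
response; these are the known fidelity gaps between this synthetic dose
and a commissioning-grade TPS calculation, which is why measured gamma
pass rates and PVDR values from a real system are not reproduced here —
the engine's role is to provide dose distributions with *known* geometry
for validating the analytics. Its defaults are stated as package
choices; no acceptance-grade quantity depends on them.

```{r dose}
model <- beam_model()
plane <- simulate_plane(spec, model, depth = 100,
                        xlim = c(-45, 45), ylim = c(-45, 45))
pk <- projected_hole_centers(spec)
vl <- projected_valley_points(spec)
keep <- function(p) p[abs(p$x) < 40 & abs(p$y) < 40, ]
pvdr(plane, keep(pk), keep(vl))
```

## Gamma analysis

`gamma_2d()` implements the global-normalization 2D gamma index at
3%/3 mm with a 10% low-dose threshold by default (50% supported for
low-resolution chamber arrays). Internals the vendor literature leaves
unstated are fixed explicitly here:

* the minimum is searched over interpolated reference positions on a
  sub-grid of `dta / 10` within a radius of `3 * dta` (common practice;
  finer subsampling moves pass rates by < 0.1 percentage points on
  smooth planes);
* the low-dose threshold excludes points where the *reference* dose is
  below threshold (reference-based exclusion);
* the boundary passes (gamma <= 1), and the reference plane defines the
  normalization, which is why gamma is intentionally not symmetric
  under swapping the two planes.

The implementation is verified against an exhaustive brute-force search
over all reference points (agreement to 1e-6 on random planes) in the
test suite.

## SFRT metrics

`compute_dvh()` builds cumulative DVHs (0.01 Gy bins) with linear
interpolation for Dxx; `geud()` is the generalized power mean
$(\frac{1}{n}\sum d_i^a)^{1/a}$, computed after scaling by the dominant
dose so that arbitrarily large |a| cannot overflow; `a = 0` is rejected
rather than silently switching to the geometric-mean limit, and no
default exponent is provided because no clinically safe one exists.
PVDR is defined as the mean dose over 4 mm sampling disks at the peak
points divided by the same at the valley points (projected hole centers
and hexagon-cell centroids by default) — point-sample PVDRs are noisier
and ROI conventions differ between clinics, so the estimator is recorded
in the report. The report mirrors the standard SFRT reporting set
(D90, D50, D20, D10, D5, Dmean, PVDR, D90/D10, EUD).

## Detector chain

The chamber array is modeled as disk averages (4.5 mm default element
disk, configurable — per-chamber geometry is rarely published) on a
7.6 mm pitch; the single-chamber partial-volume reference uses the
stated 9.9 mm contour diameter on one 1 mm slice. The absolute-dose QA
rule is |percent difference| <= 3%. Film calibration is a pure
monotone OD-to-dose polynomial over 0.25-12 Gy (degree 3 default;
LET-dependent under-response is documented but deliberately not
modeled), and the scintillator iris setting is treated as a saturation
ceiling in cGy with explicit flagging.

## Positional robustness and tolerances

`shift_sweep()` displaces the collimator along one axis, re-simulates,
and scores gamma against the fixed reference; `fit_gamma_gaussian()`
fits $G(d) = A e^{-(d-\mu)^2 / 2\sigma^2}$ (bounded $A \le 100$,
initialized at the maximum rate / argmax offset / half the span, with a
jittered-start retry because a start exactly on the symmetry point of
symmetric data has a vanishing $\mu$-gradient); `tolerance_at()`
evaluates the closed form

$$w = \sigma \sqrt{2 \ln(A / t)},$$

the half-width **about the fitted center** at which the curve crosses
the threshold t. Centering on the fitted $\mu$ rather than on zero is
the only reading under which a published inline-direction example
(A = 95.2%, sigma = 2.70 mm, t = 90%) reproduces its stated 0.905 mm
tolerance exactly; the corresponding crossline and longitudinal examples
(0.818 and 20.09 mm) are *not* consistent with their own printed fit
parameters under any centering (the closed form gives 1.156 and
20.55 mm; the former matches a missing factor of 2 under the square
root, the latter plausibly unrounded parameters), so only the inline
value is treated as exactly reproducible.

```{r tol}
fit <- gamma_gaussian(amplitude = 95.2, center = -0.360, sigma = 2.70)
tolerance_at(fit, pass_threshold = 90)
```

On the synthetic engine, lateral tolerances come out several times
tighter than longitudinal ones — shifting the block sideways translates
every peak directly, while moving it along the beam only rescales the
pattern by parts-per-thousand of magnification — matching the clinical
experience that snout position is far more forgiving than lateral
alignment. The test suite asserts this as an ordering, not a magnitude,
because the magnitudes depend on the synthetic beam model.

## Numerical choices and problem sizes

* Simulations in the tests and demo use 1-2 mm lateral grids over
  windows of roughly +/- 35-50 mm, 5 x 5 to 9 x 9 hole layouts, and
  coarsened gamma search steps (0.5-1 mm) for sweep scoring; these sizes
  were chosen so the whole validation suite runs in well under a minute
  per module while every geometric assertion stays sub-voxel.
* All randomness (noise studies, fixture generation) flows from a single
  integer seed; the demo writes the seed and the full parameter set to
  its run log, and fixed-seed runs are byte-identical.
* Degenerate inputs fail loudly: zero-area layouts, non-fitting faces,
  transforms with non-orthonormal rotation blocks, constant sweep
  series, amplitudes at or below the tolerance threshold, all-zero count
  planes, non-monotone film fits.

## Known limitations

* The dose engine is a geometric stand-in: no channel-edge scatter, no
  Bragg peak, no RBE. Passing tests demonstrate the *analytics* are
  correct on dose distributions of known geometry, not that a clinical
  TPS would be reproduced.
* Gamma is 2D only, matching planar QA practice; no 3D gamma.
* The mesh models the block and channels only — no mounting hardware,
  threads, or baseplate.
* Film LET corrections and scanner color processing are out of scope.
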