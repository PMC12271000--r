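# gridcollim

Desk-scale R toolkit for designing, digitally modeling and
dosimetrically commissioning a **divergence-matched GRID collimator**
for proton spatially fractionated radiotherapy (SFRT).

Compact proton machines deliver pencil-beam spots too wide for useful
peak/valley dose contrast, so GRID treatments use a thick brass block
pierced by a hexagonal pattern of circular channels mounted on the
nozzle snout. Because the scanned beam diverges from an upstream
virtual source, every channel must be tilted to point at that source.
`gridcollim` covers the whole commissioning workflow for such a block:

* **Aperture design** — hexagonal layout (9 rows alternating 9/8 holes
  by default, 77 channels of 15 mm diameter), per-channel divergence
  tilts, a watertight STL mesh built by direct boundary construction,
  and volume/mass reporting.
* **Placement transforms** — homogeneous 4x4 matrices for arbitrary
  gantry/couch angles with a rotation-validity contract
  (orthonormality, det = +1), plus snout-extension placement
  (23.5 cm snout − 4 cm mount offset → reference face 19.5 cm from
  isocenter).
* **Planning structures** — divergence-matched optimization cylinders
  (5/10/15 mm) threaded through every channel, cropped to the 5–15 cm
  depth slab, scoring-PTV cuboid, voxel-center rasterization.
* **Synthetic GRID dose engine** — raster-scanned Gaussian spots,
  analytic aperture transmission, virtual-source projection with depth,
  multiple-Coulomb-scattering blur, flat plateau depth dose.
* **Gamma analysis** — global 2D gamma index (3%/3 mm, 10% or 50%
  threshold), verified against an exhaustive brute-force oracle.
* **SFRT metrics** — cumulative DVH, D90/D50/D20/D10/D5, Dmean, PVDR
  (disk-sampled peaks/valleys), D90/D10 and gEUD
  (the generalized power mean `(mean(d^a))^(1/a)`).
* **Detector models** — ion-chamber array resampling, 9.9 mm
  partial-volume chamber averaging, percent-difference QA rule (≤ 3%),
  scintillator iris saturation, monotone polynomial film calibration
  (0.25–12 Gy).
* **Positional robustness** — gamma pass rate vs. collimator offset,
  Gaussian fits `G(d) = A·exp(−(d−μ)²/2σ²)`, and positional tolerances
  at a 90% pass threshold via the closed form `σ·sqrt(2·ln(A/t))`.

## Worked example

```r
library(gridcollim)

spec <- collimator_spec()
spec
#> <collimator_spec> Brass block 270.0 x 215.0 x 50.0 mm
#>   9 rows alternating 9/8 holes, diameter 15.0 mm, pitch 20.35 x 23.50 mm
#>   divergence 0.375 / 0.324 deg/cm, match plane 195.0 mm from isocenter

nrow(layout_holes(spec))
#> [1] 77

mesh <- build_collimator_mesh(spec, n_facets = 32)
mesh
#> <grid_mesh> 5624 vertices, 11552 triangles, volume 2226512.0 mm^3
mesh_is_watertight(mesh)       # TRUE
collimator_mass(spec, mesh)    # ~18.7 kg (reported, not asserted)

# synthetic GRID dose at the isocenter plane (10 cm depth)
model <- beam_model()
plane <- simulate_plane(spec, model, depth = 100,
                        xlim = c(-45, 45), ylim = c(-45, 45))
keep <- function(p) p[abs(p$x) < 40 & abs(p$y) < 40, ]
pvdr(plane, keep(projected_hole_centers(spec)),
     keep(projected_valley_points(spec)))
#> [1] 7.82

# gamma comparison against a 1.5 mm mis-positioned collimator
shifted <- simulate_plane(spec, model, depth = 100,
                          xlim = c(-45, 45), ylim = c(-45, 45),
                          collimator_shift = c(1.5, 0, 0))
gamma_2d(plane, shifted, gamma_criteria())
#> <gamma_result> 99.0% pass (6672 / 6737 points at 3%/3 mm, threshold 10%)

# positional tolerance from a fitted gamma-score curve
fit <- gamma_gaussian(amplitude = 95.2, center = -0.360, sigma = 2.70)
tolerance_at(fit, pass_threshold = 90)
#> [1] 0.9049655   # mm
```

The numbers read: 77 channels laid out and meshed into a closed solid
of ~2.23 L of brass; the synthetic engine produces a GRID pattern with
a peak-to-valley dose ratio of ~7.8 at isocenter depth; a 1.5 mm
lateral mis-positioning still passes 3%/3 mm gamma at 99%; and a
gamma-score curve with amplitude 95.2% and width 2.70 mm stays above a
90% pass rate within ±0.905 mm of its center.

A full end-to-end run (layout → STL → structures → dose → gamma →
metrics → robustness, with all tables and a run log) is
`run_commissioning_demo()`; a thin CLI wrapper with subcommands
(`design`, `export-stl`, `plan-structures`, `simulate`, `gamma`,
`metrics`, `robustness`, `demo`, `fixtures`) is installed at
`inst/cli/gridcollim`.

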