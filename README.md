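# wbafem

Quantifies the **weight-bearing area of the femoral head in standing
position** from anteroposterior (AP) pelvis-radiograph landmarks, lifts it
onto a 3D proximal-femur mesh, and compares proximal-femur finite-element
stress fields when the hip joint reaction force is applied over that
quantified patch versus the two conventional shortcuts (a 2 cm circle at the
head apex, or a single apical point).

Intended users: musculoskeletal biomechanics and computational-anatomy
researchers building subject-specific FE models of the isolated femur, who
need a defensible, individualized loading surface instead of an arbitrary
ellipse or point load.

## Method

On the magnification-corrected AP radiograph (scale `s = d_true/d_measured`
from a coin marker), 19 named landmarks `p1..p19` define:

* the **lateral margin** of the weight-bearing area: the internal bisector
  of the angle ∠ p7–p4–p11 anchored at the lateral acetabular edge p4,
  direction `(û₄₇ + û₄₁₁)/‖·‖`;
* the **medial margin**: the line from the medial sourcil point p5 through
  `W = (p6 + p18)/2`;
* the **center-edge angle of Wiberg**: the signed angle at the head centre
  p19 between the superior vertical and the ray to p4.

Named 3D landmarks on the femur mesh are projected onto the coronal datum
plane and registered to the radiograph by closed-form 2D similarity
Procrustes (`T(x) = s R x + t` minimizing `Σ‖T(xᵢ) − yᵢ‖²`). The margin
lines are lifted onto the plane, extruded along the projection direction,
and used with a 30° inferior elevation limit (superior sense = −JRF
direction) to trim the fitted head sphere. The patch area is the exact sum
of the surviving facet areas, cross-checked against a Monte-Carlo surface
integral that applies the same half-space tests to uniformly sampled sphere
points.

The FE stage solves small-strain linear elasticity on a bi-material
(cortical/cancellous) 4-node tetrahedral mesh with the distal shaft fully
clamped, distributes the same total joint force over each loading surface by
tributary-area nodal weights, and reports per-case maximum cortical Von
Mises stress, its location, and twelve-station principal-stress profiles
along the path from the head apex to the head-neck junction.

A parametric synthetic femur (spherical head, conical neck, cylindrical
shaft, matched synthetic radiograph with known ground truth and a
requested CE angle) makes the whole pipeline testable without scan data.

## Worked example

```r
library(wbafem)

dir <- tempfile("demo")
fx  <- make_demo_fixture(dir, seed = 1)   # STL + INP/VTK + landmark JSON
res <- run_pipeline(fx$config)
```

The run logs each stage (numbers from this exact run):

```
landmarks: 19 points (right hip), magnification scale 0.8696
boundary construction: CE angle 32.63 deg
head sphere: centre (0.00, -0.00, 0.00), radius 24.00 mm, rms 2.79e-08 mm
registration: rot -0.162 deg, scale 0.99739, rms 0.234 mm
margin trim: removed 8240 (lateral) + 5219 (medial) of 24448 head facets
inferior limit 30 deg: patch 9903 facets, area 3042.51 mm^2
muscle loads: iliotibial_band (1200 N over 56 nodes), iliopsoas (750 N over 133 nodes)
case A: max cortical Von Mises 35.848 MPa -- peak at neck-body junction
case B: max cortical Von Mises 29.451 MPa -- peak within loaded region
case C: max cortical Von Mises 343.153 MPa -- peak within loaded region
```

Reading it: the coin marker implies an 1.15× film magnification (scale
0.8696 restores true size); the synthetic hip's CE angle is recovered at
32.63° (33° requested, 0.3 mm landmark jitter); the registration recovers
the known overlay to 0.23 mm RMS; the two margin lines plus the 30° inferior
limit leave a 3042.5 mm² crescent on the superior-anterior head. Loading
that patch (case A) puts the cortical stress peak at the neck-body junction,
away from the articular surface, while the 2 cm circle (B) and the apical
point (C) concentrate the peak inside their own loaded regions — the point
load by an order of magnitude. `res$patch`, `res$registration` and
`res$comparison` hold the corresponding objects;
`plot(res$comparison, "s3")` draws the per-case path profiles.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/wbafem.R demo --out /tmp/demo --seed 1
Rscript inst/cli/wbafem.R landmarks validate /tmp/demo/landmarks.json
Rscript inst/cli/wbafem.R wba compute --config /tmp/demo/config.json
Rscript inst/cli/wbafem.R report --dir /tmp/demo/results
```

Exit codes: 0 success, 2 configuration error, 3 computation error.

## Package layout

* `R/synthetic-anatomy.R` — parametric femur, voxel-template tet meshing,
  synthetic radiograph with ground truth
* `R/radiograph-geometry.R` — landmark set, magnification correction,
  margin lines, CE angle
* `R/registration.R` — datum plane, projection, similarity Procrustes,
  line lifting
* `R/wba-surface.R` — sphere fit, half-space trims, inferior limit, area,
  Monte-Carlo oracle, boundary fillet
* `R/fe-solver.R` — C3D4 elasticity, load cases, Von Mises/principal
  stresses, path extraction, load-case comparison
* `R/io.R` — ASCII STL, legacy VTK, minimal Abaqus INP dialect, landmark
  JSON/CSV
* `R/pipeline.R` — configuration, orchestration, manifest, demo fixture
* `vignettes/weight-bearing-area.Rmd` — the methods account: model,
  parameters, numerical choices, limitations
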