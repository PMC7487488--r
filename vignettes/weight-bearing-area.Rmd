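---
title: "Quantifying the femoral-head weight-bearing area and its effect on proximal-femur stress"
author: "wbafem"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Finite-element (FE) studies of the isolated femur must decide where on the
femoral head the hip joint reaction force (JRF) acts. Common shortcuts — a
2 cm circle at the top of the head, or a single apical point — are easy to
set up but place the load somewhere the joint does not actually transmit it
in standing. The region that does transmit it, the *weight-bearing area*, is
patient-specific: it depends on acetabular coverage (the center-edge angle),
on head size, and on the direction of the JRF.

`wbafem` implements a radiograph-driven quantification of that area and an
FE comparison of the three loading surfaces. The 2D construction follows the
classic landmark geometry on a magnification-corrected anteroposterior (AP)
pelvis radiograph; the 2D margins are registered onto a 3D surface mesh of
the proximal femur, extruded through the femoral head, and combined with an
inferior elevation limit to produce a crescent-shaped surface patch whose
area is reported in mm². A linear-elastic tetrahedral solver then contrasts
the stress fields obtained by loading (A) the quantified patch, (B) the 2 cm
circle, and (C) the apical point.

## Coordinate conventions

All lengths are millimetres, forces Newtons, stresses MPa. The 3D frame is
`+x` medial, `+y` anterior, `+z` superior (right hip; the left side mirrors
`x`). The AP projection drops `y`. In the 2D radiograph frame `x` increases
toward the patient's left and `y` is superior, so readers of top-left-origin
pixel coordinates must flip the vertical axis first.

## The 2D construction

Nineteen named landmarks `p1..p19` are placed on the AP radiograph
(trochanters, femoral-head contour and centre, acetabular rim, sourcil,
teardrop, pelvic midline points). Three steps use them:

1. **Magnification correction.** A coin of known diameter imaged with the
   pelvis gives the film magnification; all points are scaled by
   `true/measured` about the image origin (`correct_magnification()`). Every
   downstream construction is translation-equivariant, so the choice of
   scaling origin is immaterial.
2. **Margin lines.** The lateral margin of the weight-bearing area is the
   internal bisector of the angle `p7–p4–p11` anchored at the lateral
   acetabular edge `p4` (`lateral_margin_line()`; the direction is the
   normalized sum of the two unit rays, which provably makes equal angles
   with both). The medial margin joins the medial sourcil point `p5` to
   `W`, the exact midpoint of `p6` and `p18` (`medial_margin_line()`).
3. **Center-edge angle.** `ce_angle()` measures the signed angle at `p19`
   between the superior vertical and the ray to `p4`, positive when `p4` is
   lateral — the standard acetabular-coverage measurement, used here both
   as a reported parameter and as a round-trip test of the synthetic
   radiograph generator.

## 2D–3D registration

The published workflow overlays the 3D reconstruction on the radiograph by
hand. `wbafem` replaces this with a closed-form planar similarity Procrustes
fit (`register_landmarks()`): named 3D landmarks on the mesh are projected
onto the coronal datum plane and matched by name to the corrected radiograph
landmarks, minimizing the sum of squared distances over rotation,
translation and (optionally) scale. The solution is the standard 2×2 SVD
construction — no iteration, exact on noise-free similarity-transformed
data, and the per-landmark residuals and RMS error are reported so a bad
correspondence set is visible rather than silent. Scale is allowed by
default because it absorbs residual magnification error; a rigid option
exists for pre-corrected inputs.

Only the four in-plane degrees of freedom are estimated. Out-of-plane
rotation is deliberately not: the imaging protocol this method assumes
fixes the subject's posture between X-ray and CT, and a single AP view
carries no reliable out-of-plane information.

## Trimming the head surface

The fitted head sphere (`fit_head_sphere()`, an algebraic least-squares fit
with iterative band re-selection) provides the centre and radius. Each
margin line is lifted onto the coronal datum plane (`lift_line()`) and
extruded along the projection direction into a trim plane. A head facet
survives when its centroid lies on the patch side of both planes — the side
containing the head centre, mirroring the construction's requirement that
the head centre sit between the two margins. The inferior limit keeps
facets whose elevation above the horizontal plane through the centre is at
least −30°, with "superior" taken opposite to the JRF direction, so a JRF
with an anterior component tilts the patch anteriorly. The surviving facets
are reduced to their largest edge-connected component; the patch area is
the exact sum of facet areas.

Numerical choices worth knowing:

* **Centroid classification, not facet splitting.** Facets are kept or
  dropped whole; no boolean surgery along the trim curves. The error this
  introduces lives in a one-facet-wide band along the patch boundary and
  shrinks linearly with edge length; the test suite verifies closed forms
  (spherical zone 3πr², full sphere 4πr², 60° lune 2πr²/3) to 1 % on
  ~20 000-facet spheres and checks agreement with an independent
  million-point Monte-Carlo surface integral (same half-space tests applied
  to uniformly sampled sphere points) to 2 %.
* **One membership rule.** The three half-space tests are recorded in the
  patch's provenance and reused verbatim by the Monte-Carlo oracle and by
  the resolution of the FE load region on the volume mesh, so the patch
  cannot silently mean different things in different modules.
* **The 1 mm fillet is off by default.** `smooth_patch_boundary()` rounds
  boundary corners by arc replacement in the local tangent plane and drops
  facets in the removed corner wedges. On a faceted boundary most "corners"
  are mesh-scale jags, so the fillet mainly planes those off; it exists to
  ease FE post-processing. Reported areas exclude it unless requested,
  since it is a post-processing convenience rather than part of the area
  definition.

## The synthetic volunteer

No scan data ships with the package; a parametric proximal femur
(`femur_params()`, `generate_femur_surface()`, `generate_tet_mesh()`,
`generate_radiograph()`) stands in for it with full ground truth, so every
stage is testable end to end.

* **Geometry.** A head sphere (default radius 24 mm — a conventional adult
  value; the method's source imaging provides none), a conical neck flaring
  from 13 mm at the head to just over the shaft radius at the trochanteric
  junction, and a vertical shaft (radius 14.5 mm), at a 128° neck-shaft
  angle. The primitives are blended with a 14 mm smooth-union radius: the
  real bone has a broad concave flare (the calcar region) where the neck
  meets the shaft, and a hard primitive union would leave a sharp
  re-entrant crease there that acts as an artificial stress riser.
* **Volume mesh.** The implicit solid is voxelized and each interior voxel
  split by a fixed conforming template (six-tet Kuhn by default, a
  parity-alternated five-tet template as an alternative) — watertight by
  construction, all volumes positive, total volume within 5 % of a
  Monte-Carlo integral of the primitive union at the default 2 mm voxel.
  Elements are labeled cortical within a distance of the outer surface:
  4 mm along neck and shaft (diaphyseal cortex) but 2 mm inside the head
  sphere, because the subchondral plate is much thinner than diaphyseal
  cortex — and that distinction is what makes concentrated head loading
  physically meaningful.
* **Radiograph.** Femoral landmarks are vertical projections of their 3D
  ground truth; pelvic landmarks are placed from configurable coronal
  offsets, with the lateral acetabular edge positioned so a requested CE
  angle (default 33°, inside the normal adult 26–37° range) is achieved
  exactly at zero noise. Magnification (default 1.15) scales everything
  including the 25 mm marker; landmark jitter is isotropic Gaussian
  (default 0.3 mm, typical manual picking precision) under the run seed.
* **What it does not emulate.** Real cortical geometry, greater/lesser
  trochanter shapes (muscle attachments are coordinate bands), acetabular
  anteversion, cartilage, and inter-subject shape variation. Passing tests
  on this family therefore demonstrate the correctness of the geometric
  and numerical machinery, not clinical validity on patient data; the
  published patient areas (roughly 1200–1900 mm²) arise from individual
  anatomy this generator does not reproduce, and the demo patch area
  (≈3000 mm² at the defaults) is accordingly not a clinical number.

## The finite-element comparison

`assemble_and_solve()` implements standard isoparametric 4-node (C3D4)
constant-strain tetrahedra with bi-material isotropic linear elasticity
(defaults: cortical E = 16 800 MPa, ν = 0.3; cancellous E = 840 MPa,
ν = 0.2 — conventional literature values, configurable, and never used as
test ground truth), assembled into a sparse symmetric stiffness and solved
by sparse Cholesky factorization; the factorization is computed once per
model and shared across load cases. Stresses are evaluated at element
centroids; Von Mises via the deviatoric invariant and principal stresses by
a closed-form symmetric 3×3 eigensolver. Quadratic (C3D10) input meshes are
accepted through their corner nodes.

Verification, all in the test suite: the constant-strain patch test is
exact to 1e-10 on a randomly distorted mesh; a uniform traction reproduces
the uniaxial closed form exactly; an end-loaded 2×2×20 mm cantilever at 8
elements through the thickness lands within 10 % of Euler–Bernoulli plus
first-order shear correction; global equilibrium (Σ reactions + Σ applied
= 0) holds to 1e-8 relative on every solve; external work equals twice the
strain energy; and the solution is invariant under node renumbering.

**Loading.** The three cases distribute the same total JRF: (A) over the
quantified patch, resolved on the volume-mesh boundary by the patch's own
half-space tests; (B) over a 20 mm-diameter circle at the head apex; (C)
onto the single apex node. For A and B each boundary facet in the region
assigns a third of its area to each of its nodes (tributary-area weights)
and the nodal forces sum to the total exactly. A distributed load was
chosen over a rigid coupling constraint because coupling suppresses local
deformation of the loaded surface and manufactures edge singularities; the
choice is recorded in the output metadata.

**The stance load model.** The demo JRF is 1800 N (about 2.4 body weights
for a 75 kg adult, the accepted single-leg-stance magnitude), tilted 13°
laterally and ~5° posteriorly from vertical — orientations in the range
reported by instrumented-implant measurements. A joint force applied alone
to a distally clamped femur is, however, not a physiological load state:
it exaggerates proximal bending, which the lateral soft-tissue tension
band normally counteracts. The default configuration therefore completes
the load model with two simplified muscle groups — an iliotibial-band
tension of 1.6 body weights acting inferiorly at the lateral greater
trochanter and an iliopsoas pull of 1.0 body weight acting
superomedially-anteriorly at the lesser trochanter
(`default_muscle_loads()`), applied identically in all three cases so only
the JRF surface differs. Muscle loading can be disabled or replaced per
configuration.

**Postprocessing.** `compare_load_cases()` reports each case's maximum
cortical Von Mises stress and location, excluding a Saint-Venant zone
(three voxel edges) above the fully clamped distal cut, where any fixed
boundary manufactures artificial concentrations; twelve arc-length-uniform
stations along the path from the head apex to the head-neck junction with
principal and Von Mises stresses per station; and a qualitative classifier
("peak within loaded region" vs "peak at neck-body junction") based on
which of the two the peak element is nearer. On the demo volunteer the
patch-loaded case peaks at the neck-body junction while the circle and
point cases peak inside their loaded regions — the loading-surface
contrast the method exists to demonstrate.

## Problem sizes and runtimes

The shipped demo volunteer uses a 24 576-facet head surface
(96 × 128 sphere tessellation), a 2 mm voxel volume mesh
(~103 000 tetrahedra, ~20 000 nodes), and the three-case comparison with
one shared factorization; the full pipeline runs in about a minute on one
CPU. Closed-form spherical checks use ~22 000-facet unit spheres; the
cantilever benchmark uses 30 720 elements. These sizes were chosen so the
discretization error stays inside each check's stated tolerance while the
whole suite remains comfortable to run interactively.

## Known limitations

* Facet-level trimming means the patch boundary is jagged at mesh scale;
  refine the surface mesh, not the fillet, if a smoother boundary curve is
  needed for area reporting.
* The registration is in-plane only; a systematically rotated posture
  between radiograph and mesh is absorbed into the residuals, not
  corrected.
* Constant-strain tetrahedra are stiff in bending; comparative conclusions
  between load cases are robust, but absolute stress magnitudes carry the
  usual C3D4 discretization bias and the voxel-staircase surface noise.
* The muscle set is a two-group simplification with literature-scale
  magnitudes, adequate for restoring a physiological bending state but not
  subject-specific.
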