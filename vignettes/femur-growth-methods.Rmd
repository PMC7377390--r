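---
title: "Mechanobiological simulation of proximal femoral growth: models and methods"
author: "femurFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanobiological simulation of proximal femoral growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femurFE)
```

## The scientific problem

During childhood the proximal femur remodels dramatically: the neck-shaft
angle (NSA) drops from roughly 150 degrees at birth to about 120 degrees at
skeletal maturity, and femoral anteversion (AVA) falls from about 50 to
about 20 degrees. Mechanobiological theory attributes much of this to the
loading of the cartilaginous growth plate during gait: cyclic octahedral
shear stress promotes endochondral growth while cyclic hydrostatic
compression inhibits it. `femurFE` implements a complete in-silico version
of this hypothesis: it builds femur finite-element (FE) models with
systematically varied NSA and AVA, loads them with the hip joint contact
force (JCF) and muscle forces of a gait cycle, evaluates a growth stimulus
on the growth plate, grows the bone along the direction of the deflected
femoral neck, and measures how NSA and AVA change. The package exists to
ask a sensitivity question: *how strongly do femoral growth predictions
depend on the starting geometry?*

## Model components

### Parametric femur (geometry module)

The femur is an idealized swept solid: a condyle block and straight shaft
along the superior axis, a neck leaving the shaft at the NSA (rotated
anteriorly about the shaft axis by the AVA), and a spherical head. Cross
sections are butterfly (O-grid) disks, so the mesh is all-hexahedral with
no degenerate elements; the default discretization has roughly 5,000
elements and a minimum scaled Jacobian around 0.38. Default dimensions
(260 mm femur, 17 mm head radius, 27 mm neck, 9.5-10 mm neck/shaft radii)
describe a child of about eight years.

The growth plate is a stack of `nGpRows = 7` transverse element rows near
the head-neck junction, flanked by `nTransitionRows = 10` rows on each
side whose elastic modulus grades linearly from trabecular bone
(300 MPa) to growth-plate cartilage (6 MPa); cortical bone is
17,000 MPa, Poisson ratios 0.3 (bone) and 0.45 (cartilage). All values are
configuration, not constants, because reported growth-plate moduli span
more than an order of magnitude.

Angle measurement (`measureAngles()`) is defined, not inherited: the head
centre HC is a least-squares sphere fit to the head-surface nodes, the
neck base NB is the centroid of the neck-base ring, the shaft axis is the
principal line through the shaft-centre markers and the condylar axis is
the medial-to-lateral marker line. NSA is 180 degrees minus the 3D angle
between the neck axis (NB to HC) and the proximal shaft axis; AVA is
measured between the neck axis and the medial condylar direction after
projection onto the transverse plane. Everything derives from node
coordinates, so the measures are rigid-motion invariant; on generated
meshes they reproduce the requested angles to well under 0.1 degrees.

### Morphing (host-mesh fitting)

`rigidRegister()` is plain iterative-closest-point with a Kabsch update
(optionally Umeyama scaling, optionally landmark-seeded). `hostMeshFit()`
lays a 4 x 4 x 4 tricubic Bezier control lattice over the principal-axis
bounding box of the target surface and solves a ridge-regularized least
squares problem for the control displacements, re-matching correspondences
between solves. Two correspondence rules are provided:

* `"nearest"` (default): iterated symmetric nearest-neighbour matching
  with a 60-degree normal-compatibility filter. This is the right tool
  when source and target are unrelated meshes.
* `"index"`: vertices correspond by list position. When both surfaces come
  from the same parametric template this pins anatomical locations and
  avoids the tangential sliding that a nearest-point objective cannot see
  (sliding does not change the surface distance but does move landmarks
  such as the neck-base ring).

The ridge weight `lambda = 1e-3` merely stabilizes the under-covered
corner control points; the fit is data-dominated. The best iterate by
correspondence residual is kept, and the function refuses to return a fit
whose exact symmetrized surface RMS is worse than rigid alignment alone.
Morphing a full mesh (`morphMesh()`) transforms surface and internal
(passive) nodes alike and carries connectivity, sets and materials over
unchanged. Elements inverted by morphing may be removed only distal to
the growth plate (`dropInvertedElements()`); an inversion in or proximal
to the plate aborts, because growth-plate integrity is a precondition of
the growth engine.

### Synthetic gait loads

`synthHipJCF()` builds the resultant hip JCF as two raised-cosine bumps in
stance (centres 18% and 42% of the gait cycle, half-width 15%), exactly
zero in late swing and exactly symmetric when the peaks are equal. The
default peaks (4.9 and 4.2 body weights) correspond to hip contact forces
reported for typically developing children at self-selected walking
speed; body weight defaults to 298 N (a 30.4 kg child).
`selectLoadInstances()` picks the nine quasi-static instances as both
peaks, the inter-peak valley, and equally spaced stance samples.

`buildLoadSet()` distributes each instance's JCF over the head-surface
nodes closest to the line of action, accumulating nodal tributary areas
until the patch reaches about 30 mm^2; weights are proportional to
tributary area and sum to one, so nodal forces sum exactly to the JCF
vector. Muscles act as concentrated forces at heuristic anatomical
landmarks (greater/lesser trochanter, linea aspera, distal attachment
sites). The muscle table (`defaultMuscleSpec()`) - peaks of 0.03 to 0.5
body weight inside raised-cosine activation windows - is an explicit
placeholder for subject-specific musculoskeletal simulation, which is out
of scope; every number in it is user-replaceable configuration and was
chosen conservatively so that the contact force, not the muscle model,
dominates the growth-plate stimulus.

The JCF orientation rule deserves its own paragraph, because it is the
one genuinely open design choice. In `neck_tracking` mode (default) the
JCF keeps a fixed 3D angle `alpha0Deg = 25` degrees to the femoral neck
axis, with its off-axis component pointing along a fixed mixture
(`tiltLocal = c(1, 0.5, 1)`) of the neck-local inferior, posterior and
medial directions. The physical argument: the acetabulum rotates with the
head and neck, so the orientation of the contact force *relative to the
neck* is approximately preserved when NSA or AVA change - observationally,
the hip JCF follows the femoral neck axis. The mixture coefficients were
calibrated once, while designing the synthetic load model, so that the
emulation reproduces the known qualitative mechanics of femoral growth
(simultaneous NSA and AVA reduction, the damping of the NSA correction by
anteversion, the amplification of the AVA correction by coxa valga, and a
geometry-insensitive osteogenic index); they are held fixed thereafter
and across all models of any run. `pelvis_fixed` mode instead applies the
waveform's global direction (inferior-lateral-posterior in the femur
frame) unchanged, letting users break the neck-following assumption.

### Elasticity solver

Small-strain isotropic elasticity on 8-node hexahedra, units mm-N-MPa.
Elements are trilinear bricks with 2 x 2 x 2 Gauss quadrature plus the
three Wilson incompatible bending modes with Taylor's correction,
statically condensed per element. The incompatible modes matter: the
plain trilinear brick carries parasitic shear stiffness in bending, and
both the femur problem and the package's verification problems are
bending-dominated. With them, a 40 x 4 x 4 cantilever matches the
Euler-Bernoulli tip deflection to 0.2%, while the single-element patch
test remains exact to machine precision (the Taylor correction guarantees
this for distorted elements, and a constant per-element eigenstrain
excites no incompatible modes at all). The global system is solved by
sparse Cholesky factorization (`Matrix`), factorized once per mesh and
reused across the nine instances and the growth solve; the relative
equilibrium residual on femur solves is of order 1e-10. Element stresses
are volume-weighted Gauss-point averages evaluated at the centroid of the
compatible strain field; the growth stimulus is evaluated on growth-plate
rows, with row 1 the distal (shaft-side) layer.

### Growth engine

Per growth-plate element, over the nine instances *i*:

* octahedral shear stress `sigmaS = sqrt((s1-s2)^2 + (s2-s3)^2 +
  (s3-s1)^2)/3` (zero for any hydrostatic state) and hydrostatic stress
  `sigmaH = (s1+s2+s3)/3`, from the sorted principal stresses;
* osteogenic index `OI = a * max_i sigmaS + b * min_i sigmaH` with
  `a = 1`, `b = 0.5` (only the ratio matters for trends). The maximum and
  the minimum are taken per element independently, so the critical
  instance may differ between elements and between the two invariants.
  `min sigmaH` is the signed minimum - the most compressive value - which
  is what "hydrostatic compression inhibits growth" requires.

The growth strain per step is `eps = max(0, epsBio + kScale * OI)` with a
constant biological rate `epsBio = 0.005`. The stimulus has stress units
and the growth strain is dimensionless, so a scale is unavoidable;
`kScale` is calibrated on the reference model (largest |OI| maps to
`targetMechStrain = 0.01`) and then held fixed across the entire geometry
grid, which keeps between-model comparisons meaningful. Negative totals
are clamped: resorption is not modelled.

The growth direction is the unit vector from the deflected neck base to
the deflected head centre, where both landmarks are displaced by the mean
of their deflections over the nine instances (head-centre deflection =
mean displacement of the head-surface nodes; neck-base deflection = mean
over the neck-base ring). An alternative per-element mode grows along the
eigenvector of the largest principal stress at the instance of maximum
octahedral shear, sign-resolved toward the head, with a logged fallback
to the neck-axis-nearest eigenvector for (near-)repeated eigenvalues.

Growth is applied as an anisotropic eigenstrain - the thermal-expansion
analogy with expansion coefficient one along the growth direction and
zero transverse - in a second elastic solve with the same fixed condyles.
Nodal coordinates are then updated with the growth displacement times
`amplification = 10`, which makes single-step geometry changes visible
without simulating many growth increments; amplification is exactly
linear, so it rescales but never reshapes the outcome. Multi-step mode
(`nSteps > 1`) re-builds loads and re-solves on each grown mesh.

## The sensitivity experiment

`runGrowthPipeline()` runs the full workflow over a grid of seven models
(NSA 120 with AVA 20/30/40/50, and AVA 20 with NSA 120/130/140/150;
NSA-120-AVA-20 is the reference). With all defaults it reproduces,
deterministically, the qualitative mechanics expected of neck-deflection
growth under neck-tracking loads:

* NSA and AVA decrease in every model;
* increasing AVA damps the NSA correction monotonically;
* increasing NSA amplifies the AVA correction monotonically;
* the osteogenic index is nearly geometry-invariant (across-model
  coefficient of variation of the row-mean OI below 0.2).

These are exactly the checks encoded in `tests/testthat/test-acceptance.R`.

## Numerical choices and problem sizes

* Default meshes are about 5,000 elements (`nCirc = 24`); unit tests use
  about 300-element meshes (`nCirc = 8`, 3 growth-plate rows), which keeps
  the full suite at a few minutes on one CPU. The seven-model default grid
  runs in under two minutes.
* The mitered neck-shaft junction requires the first neck station to clear
  the kink ring's axial overshoot (`rNeck * tan(bend/2)`); the generator
  enforces this and errors for neck lengths that cannot accommodate the
  requested NSA.
* Sphere fits use the linear algebraic formulation; with 200+ exactly
  spherical head-surface nodes the fit is exact to rounding.
* Surface RMS is the symmetrized mean of directed RMS point-to-triangle
  distances, with candidate triangles from the stars of the three nearest
  vertices.
* All randomness (waveform noise, if enabled) flows from a single seed;
  with default settings every stage is fully deterministic and repeated
  runs produce byte-identical results files.

## Limitations

The synthetic femur has no trochanters, no cortical shell thickness map
and a planar growth plate; muscle forces are placeholders, not inverse
dynamics; material behaviour is linear-elastic and isotropic, which is
adequate for short loading durations at whole-organ scale but ignores the
poro-viscoelasticity of cartilage. Growth is simulated at the proximal
growth plate only - no distal or trochanteric physes, no periosteal
(width) growth, no density remodelling. Passing tests therefore
demonstrate the internal consistency of the mechanobiological pipeline
and its qualitative geometric trends, not subject-specific predictive
accuracy on real femora.
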