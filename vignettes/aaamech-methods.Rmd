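---
title: "Methods: structural mechanics of an AAA with intraluminal thrombus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural mechanics of an AAA with intraluminal thrombus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aaamech implements a complete desk-scale pipeline for the structural
analysis of an abdominal aortic aneurysm (AAA) whose lumen is lined by a
non-uniform intraluminal thrombus (ILT): synthetic segmentation-style
geometry, surface processing into two watertight solids, conforming
tetrahedral meshing, local material frames, anisotropic hyperelastic finite
elements under quasi-static intraluminal pressure, and regional
post-processing. This vignette is the package's own account of the models,
the numerical choices, and what the synthetic test bed does and does not
demonstrate about patient data.

## The synthetic aneurysm

Patient CT segmentations are not publicly available, so the package
generates an idealized stand-in that reproduces the *structure* of a
segmentation: two open boundary surfaces on a shared `(theta, z)` lattice —
the blood lumen and the inner aortic wall (lumen + thrombus) — plus a
centerline. The inner wall is a Gaussian-bulged tube,

    R(z) = r0 + (Rmax - r0) exp(-((z - z0)/w)^2),

with defaults r0 = 10 mm, Rmax = 37.5 mm (a 75 mm peak transverse diameter,
the scale of a large, surgery-indicated aneurysm), z0 = 60 mm, w = 20 mm,
length 120 mm, and an anterior centerline bow of 8 mm so that the local
material frames are exercised on a curved vessel. The thrombus thickness

    tau(theta, z) = tau_max * s(theta) * a(z)

vanishes over an anterior angular sector (defaults [-pi/4, pi/4]; the
anterior side of large AAAs typically carries the least thrombus), rises
with a C1 cosine taper of width `ilt_taper_width` at each sector edge, and
follows the bulge axially with a floor: `a(z) = 0.1 + 0.9 exp(-((z -
z0)/w)^2)`, so the thrombus lines the entire segment, thin near the neck
and the bifurcation end and thickest (14 mm default) at the bulge. The
floor keeps the thrombus band topologically simple (one connected band the
full length of the vessel), matching the intended fragment topology. Both
surfaces coincide *exactly* (to the last bit) over the ILT-free sector.

Units are mm / N / MPa throughout; pressures are entered in mmHg
(1 mmHg = 1.333224e-4 MPa).

What the generator does **not** emulate: the iliac bifurcation (a single
unbranched tube is used; all stitching logic is still exercised at two end
rings instead of three), calcifications, wall-thickness variability,
segmentation noise (surfaces are analytic; Taubin smoothing is available
but defaults to zero iterations), and the irregular, patchy thrombus
margins of real segmentations. Passing tests on this geometry demonstrate
the correctness of the machinery — not the patient-specific stress values,
which depend strongly on the individual anatomy.

## Surface processing

The pipeline mirrors the boundary-surface workflow used with segmented
scans:

1. **Thickness analysis** (`detect_ilt_free_region`): each lumen triangle
   is labeled by its exact centroid-to-wall distance; triangles closer than
   `distance_tol` are "wall contact". Labels transfer to the inner wall by
   nearest-centroid matching.
2. **Fragmentation** (`fragment_surfaces`): the wall-contact part of the
   lumen is discarded, leaving the luminal ILT surface; a strip of
   inner-wall triangles along the thrombus boundary is erased (cell-based,
   so the re-stitched chains never share vertices), separating the
   ILT-covered from the ILT-free wall.
3. **Offsetting** (`offset_surface`): the outer wall is the inner wall
   displaced 1 mm along area-weighted vertex pseudo-normals (the constant
   wall thickness reported by necropsy for thrombus-lined AAAs); a warning
   is raised where adjacent face normals spread beyond 60 degrees.
4. **Stitching and assembly** (`stitch_loops`, `assemble_closed_bodies`):
   boundary loops are joined by advancing-front triangle bands. The front
   advances the loop that lags in normalized arclength, with triangle areas
   breaking near-ties; a pure minimal-area rule is not used because it runs
   away around whichever loop has uniformly shorter edges. Orientation is
   repaired globally afterwards (flood fill + positive-volume sign). The
   ILT body (luminal surface + covered wall + one ring stitch) is a
   topological sphere; the wall body of an unbranched tube (inner + outer +
   two end-ring stitches) is necessarily a genus-1 shell, so its closed
   surface has Euler characteristic 0, not 2.

`distance_tol` defaults to 0.2 mm. Lattice cells whose corner thickness
falls below half this tolerance are not meshed as solid thrombus (they
belong to the coincidence region the thickness analysis exists to
eliminate), which keeps the thinnest thrombus prisms from degenerating.

## Meshing

No constrained-Delaunay tetrahedralizer exists in this package's
dependency environment, and writing a robust one is a project in itself.
Instead `tetrahedralize()` exploits the generalized-cylinder structure the
bodies carry from assembly: every `(theta, z)` lattice cell is extruded
radially — lumen-to-wall layers for the thrombus (`nr_ilt`, default 2),
wall-to-outer layers for the wall (`nr_wall`, default 1) — and each hex is
split by the Kuhn/Freudenthal 6-tetrahedron pattern, which tiles
conformingly across cells and matches the surface triangulation diagonals.
The wall and thrombus meshes share their interface nodes verbatim (merged
mode); penalty mode duplicates the interface nodes and returns spring pairs
with tributary areas. `max_element_volume` triggers conforming integer
subdivision of the lattice (piecewise-linear on the triangulated quads, so
refined surfaces stay exactly on the input geometry). Arbitrary external
STL bodies without lattice provenance are rejected with an informative
error rather than meshed badly.

Element counts at the default resolutions: 15.6k tetrahedra at the coarse
level (36 x 30 lattice), 24.7k at fine (x1.25) and 35.2k at finer (x1.5) —
a proportional, desk-scale analogue of the published 248k/427k/559k ladder.
The levels are spaced at least 25% apart in lattice resolution so that the
discretization trend in the maximum-stress statistic dominates the
lattice-phase noise of where the stress concentration lands relative to
the grid. Because the hyperelastic quasi-static problem is path
independent, the sensitivity ladder and the regional comparisons are run
with a short ramp (5 main increments plus the pre-ramp; the final state
matches the 40-increment protocol to solver tolerance, which the suite
exercises by comparing 10- and 40-step runs).

## Local material frames and fibers

Per the local-coordinate-system construction: for every outer-surface
triangle, e3 is the outward normal; the centerline (resampled to 90
equally spaced points, distal end first) supplies `a_centr`, the unit
vector between the consecutive points nearest the face centroid; then
e1 = normalize(a_centr x e3) (circumferential) and e2 = e3 x e1 (axial).
Interior and thrombus elements copy the frame of the nearest external wall
tetrahedron (squared-distance, lowest index on ties, for determinism).
Where `a_centr` is parallel to e3 the nearest non-degenerate frame is
reused with a warning — on the synthetic tube this can only happen at end
caps. The two collagen families are
M4/M6 = cos(alpha) e1 +/- sin(alpha) e2 with alpha = 5.6 degrees by
default. Frames are per element (single-point integration makes
per-element and per-integration-point equivalent here).

## Constitutive models

* **Thrombus** — isotropic linear elasticity (E = 0.11 MPa, nu = 0.45;
  lambda = 0.3414, mu = 0.03793 MPa) extended to finite strain. Two
  standard extensions are implemented, identical at small strain: the
  Saint Venant-Kirchhoff form `W = lambda/2 tr(E)^2 + mu E:E` on the
  Green-Lagrange tensor, and the compressible neo-Hookean form
  `W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2`. The thrombus preset
  uses the neo-Hookean form: the thrombus margin is locally crushed under
  intraluminal pressure (det F down to ~0.6 on the default geometry), a
  regime where SVK loses material stability and produces a spurious limit
  point in the quasi-static ramp, while the logarithmic volumetric barrier
  keeps the neo-Hookean response stable — the same behaviour as the
  large-strain isotropic materials of established FE solvers. SVK remains
  available (`form = "svk"`), is fully tested, and is the material of the
  linear verification benchmarks.
* **Wall, anisotropic** — Holzapfel-Gasser-Ogden: neo-Hookean ground
  matrix `c/2 (I1 - 3)` plus two dispersed, tension-only exponential fiber
  families `k1/(2 k2) [exp(k2 <E_a>^2) - 1]` with
  `E_a = kappa (I1 - 3) + (1 - 3 kappa)(I4 - 1)`; parameters c = 0.30055
  MPa, k1 = 0.01632 MPa, k2 = 1768.15, kappa = 0.1010, alpha = 5.6 deg.
  The fiber energy is implemented in the standard form that vanishes at
  the reference state (the printed form `exp(k2 <E_a>^2 - 1)` does not,
  and is read as a typesetting slip). The Macaulay bracket disables
  compressed fibers (E_a <= 0). Structure tensors are realized as
  `H = kappa I + (1 - 3 kappa) M (x) M`, the generalized-dispersion form
  implied by the fiber-strain expression.
* **Wall, isotropic** — two-parameter Mooney-Rivlin,
  `c1 (I1 - 3) + c2 (I2 - 3)` with c1 = 0.174, c2 = 1.881 MPa.

Both hyperelastic wall models are *decoupled*: the isochoric energies act
on modified invariants (`J^(-2/3) C`) and near-incompressibility is
enforced by `U(J) = K/2 (ln J)^2`. The bulk modulus defaults to 100x the
leading shear-like parameter (c for HGO, 2(c1 + c2) for Mooney-Rivlin) —
large enough for near-incompressible response, small enough to limit
volumetric locking of linear tetrahedra. Whether the fiber invariants are
isochoric or full is selectable (`invariants = "isochoric"` default,
`"full"` available), since the original description leaves this open.

Stress is evaluated analytically (`S = 2 dW/dC`, pushed forward to Cauchy
stress); the material tangent is obtained by complex-step differentiation
of the analytic stress — exact to machine precision and exactly
major-symmetric after symmetrization, so the Newton linearization is
consistent. The SVK tangent is closed-form. The test suite verifies the
analytic stress against central finite differences of the independently
implemented energy, and the tangent against finite differences of the
stress.

## The quasi-static solver

Total-Lagrangian 4-node tetrahedra with single-point quadrature.
Intraluminal pressure is a follower load on the deformed luminal faces
(luminal thrombus surface plus ILT-free inner wall); a dead-load option
exists for linear verification problems. The end rings are fixed in all
three DOF. The tied interface is merged-node by default; in penalty mode
the contact force is `f = eps_p g` per pair with
`eps_p = penalty_scale * K_local / h_local` computed from the local bulk
modulus and element size (scale 10 by default).

Each increment is solved by Newton's method with a backtracking line
search (factor 0.5), convergence at relative residual 1e-6 (of the
external-force scale or the initial step residual) or absolute 1e-9 N,
at most 25 iterations with early abort on divergence (residual above its
starting value after six iterations, or a collapsing line search twice in
a row), and up to 4 step bisections. The tangent is symmetrized (the
follower-pressure load stiffness is its only asymmetric part) and can be
mildly indefinite (tension-only fibers, follower pressure), so the linear
solver works with a supernodal sparse Cholesky of the tangent plus a
small cached diagonal shift (zero while the tangent is positive definite,
otherwise 1e-6 to 1e-2 of the mean diagonal — a damped Newton direction);
exact simplicial LDL' and sparse LU are fallbacks. Factorizations are
reused across iterations while the iteration contracts well (modified
Newton).

The loading program follows the published protocol: pressure ramps from 80
to 120 mmHg (physiological) or 200 mmHg (hypertensive) in 40 equal
increments, and since the reconstructed geometry is treated as stress-free
the start pressure itself is reached by an automatic pre-ramp from zero in
`ceiling(start/dp)` increments of the same size. Per-element Cauchy stress
and Green-Lagrange strain are recorded at every main step.

## Post-processing

First principal stresses are eigenvalues of the per-element Cauchy stress;
the "equivalent Von Mises strain" is defined here (the source names but
never defines it) as `sqrt(2/3 dev(E):dev(E))` on the Green-Lagrange
tensor. Wall elements are classified ILT-covered (inner face on the
interface) or ILT-free (inner face luminal), interior elements inheriting
the nearest label; regional averages are element-volume weighted (the
weighting is likewise unstated in the source and chosen here). Strength
limits: thrombus UTS 0.085 MPa; wall UTS from the circumferential
(0.0593 MPa) and axial (0.0895 MPa) mean limits via the plane Von Mises
combination, 0.079 MPa. Volume metrics (aneurysm volume, thrombus volume,
ILT%, growth) use divergence-theorem volumes of the closed bodies; open
tube ends are capped with centroid fans first. The mesh-sensitivity report
prints `|v - v_ref| / v_ref` against the chosen reference level; note that
applying this formula to the published sensitivity table reproduces its
coarse-level figure (2.18%) exactly but gives 1.33% where 1.42% is printed
— the computed value is reported.

## Verification ladder

* patch test: single-cube uniaxial follower traction is reproduced to
  machine precision (homogeneous state, SVK);
* Lame thick-wall cylinder (a = 5, b = 6, L = 40 mm, SVK, small pressure):
  plane-strain radial displacement at mid-length matches the closed form
  to ~0.2% on a 48 x 40 x 2 lattice;
* Mooney-Rivlin uniaxial stretch of one element at bulk modulus
  1000(c1+c2) matches the incompressible closed form
  `sigma = 2 (L^2 - 1/L)(c1 + c2/L)` to <0.1%;
* stress/energy and tangent/stress finite-difference cross-checks for all
  three materials;
* penalty tie converging to the merged-interface solution as the penalty
  scale grows.

## Known limitations

Linear tetrahedra lock volumetrically as the bulk penalty grows; the
moderate default (100x shear-like modulus) trades a small
compressibility error for usable elements. Maximum-stress values on the
synthetic geometry are substantially higher than published
patient-specific peaks, because the idealized ILT-free sector is a large
contiguous patch of bare 1 mm wall at 37.5 mm radius; regional *ratios*
(covered vs free) are the meaningful quantity here. The quasi-static
solver is load-controlled and cannot traverse limit points; the thrombus
film threshold discussed above exists precisely to keep the physiological
range free of them. Residual stress, prestress recovery (the geometry is
treated as stress-free although it corresponds to ~100 mmHg),
fluid-structure interaction, calcifications and poroelastic thrombus
behavior are out of scope.
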