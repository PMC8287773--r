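---
title: "Estimating tibiofemoral joint stiffness from loaded and unloaded knee volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tibiofemoral joint stiffness from loaded and unloaded knee volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfjstiff)
```

## The model

The quantity this package estimates is a single effective Young's
modulus — the combined compressive stiffness (CCS) — standing in for
everything that carries axial load across the tibiofemoral joint:
cartilage, menisci, synovial fluid, and the restraint of ligaments and
muscle. It is defined operationally by the inversion pipeline:

1. **Measured strain.** On paired segmentation volumes acquired with
   and without an axial load of 50% body weight, the bone gap of each
   sagittal slice is the minimum Euclidean distance between the distal
   femur-bone surface and the proximal tibia-bone surface (cartilage
   and meniscus lie inside the gap; the measurement is deliberately
   bone-to-bone, which is what makes it robust to soft-tissue
   segmentation error). The slice mean is the mBGFT; the joint
   compressive strain is ε = ΔmBGFT / mBGFT(unloaded), with
   ΔmBGFT = mBGFT(unloaded) − mBGFT(loaded).
2. **Simulated characteristic.** A finite-element model of the joint
   is solved at ten assigned soft-tissue moduli
   E ∈ {1, 2, 3, 5, 10, 15, 20, 25, 30, 50} MPa. The axial deformation
   δz of the femur under the same load, normalized by the unloaded
   mBGFT, gives a simulated strain per modulus.
3. **Power law and inversion.** The pairs (E, ε) follow
   ε = a·E^b closely; the fitted law is inverted at the measured
   strain, E = (ε/a)^(1/b). Averaging coefficient pairs across
   subjects gives a generalized model usable without any simulation.

The exponent has a mechanical meaning: b = −1 is the flat-punch limit
in which the contact area does not change with stiffness, and area
growth with compliance raises b above −1 (Hertz contact on a
half-space would reach −2/3). A congruent joint therefore sits in
(−1, −2/3), and the fitted b is a diagnostic of how conforming the
modelled contact is.

**Sign convention.** The law is stored internally as ε = a·E^b with b
signed (negative); all I/O reports the signed b, which is how the
subject tables print it. The inversion E = (ε/a)^(1/b) is the exact
algebraic inverse under this convention (tested to 1e−12 relative).

## The simplified contact FEM

The simulation branch of the original methodology used subject-specific
3-D meshes in a commercial solver, with run times of days per case.
This package replaces that stage with a bespoke 2-D solver whose
purpose is to reproduce the *shape* of the strain–stiffness
characteristic, not any particular subject's deformation values:

* **Dimensional reduction.** Default mode is axisymmetric — a single
  condyle idealization of femur bone, femoral cartilage, tibial
  cartilage, meniscus ring and tibia bone; plane strain is available
  as an alternative. Quadratic (6-node) triangles mirror the quadratic
  tetrahedra of the 3-D original in reduced dimension.
* **Materials.** Isotropic linear elastic. Bone is fixed at
  E = 1000 MPa, ν = 0.3; cartilage uses ν = 0.45 and meniscus ν = 0.3;
  one sweep modulus is applied to cartilage and meniscus
  simultaneously (the two can be decoupled via
  `material_set(cartilage_E=, meniscus_E=)` — the protocol does not
  state whether they ever received different values, so coupling them
  is the default).
* **Load and supports.** The total force (50% body weight; 400 N for
  an 80 kg subject) is applied in five equal substeps through the
  femur top surface, whose vertical dofs are tied to a single master
  dof — a rigid platen translating without rotation, matching a remote
  displacement with all rotations fixed and z free. The distal tibia
  is fully fixed. Substep increments are F/5 in general; 80 N is the
  special case F = 400 N.
* **Contact.** Frictionless node-to-segment contact between the
  femoral cartilage underside (slave) and the composite tibial surface
  (tibial cartilage top, meniscus inner face and top slope) enforced
  by augmented-Lagrange iteration: an inner active-set loop at fixed
  multipliers, an outer multiplier augmentation
  λ ← max(0, λ + k·penetration) until penetration ≤ 1e−3 mm. The
  penalty k is auto-scaled to 100 × the softest contacting modulus per
  unit length times each slave node's tributary contact area, which
  keeps the matrix conditioning independent of the sweep modulus.
  Bonded interfaces (bone–cartilage, meniscus–tibial cartilage) share
  mesh nodes, an exactly rigid tie. Compared with the contact scheme
  sketch of the source protocol, bonding the meniscus to the tibial
  cartilage (rather than to the tibia with a third frictionless pair)
  is the one deliberate simplification: it leaves a single contact
  pair, which keeps the augmented-Lagrange solve robust at desk scale
  while preserving the meniscal load-sharing that shapes the exponent.
* **Large deflection.** For sweep moduli below 5 MPa the solver
  switches to updated-coordinate incremental loading: each substep is
  solved as an increment on the geometry updated with the accumulated
  displacement. This is the minimal geometric nonlinearity consistent
  with the flag's purpose (soft cases deform by a large fraction of
  the tissue thickness); it is not a finite-strain formulation.
* **Adaptive convergence.** After each solve the mesh is uniformly
  refined (element size halved) and re-solved; the signed relative
  change of δz in percent, 100·(δ_prev − δ_new)/δ_new (negative when
  refinement increases deformation), is the convergence error, and the
  loop stops when its magnitude is at most 5%. Uniform h-refinement
  was chosen over error-indicator-driven refinement for exact
  reproducibility of the refinement sequence.

### Verification

Because the solver is bespoke, it is verified against closed forms
exercised through the same assembly, constraint and contact machinery
as the knee model (`analysis/02_solver_benchmarks.R` and the test
suite): a uniaxial column against δ = F·h/(A·E) at 1e−6 relative; a
rigid indenter on an elastic half-space against the Hertz closed form
δ = (9F²/(16RE*²))^(1/3) within 5% for E ∈ {10, 20, 50} MPa; global
equilibrium (support reaction = applied load within 0.5%) in every
configuration; exact linearity in F and 1/E with contact inactive; and
b = −1 within 0.01 for a flat punch on a rigid-backed layer. The Hertz
indenter uses the paraboloid profile r²/(2R) — the profile Hertz
theory itself assumes — on a 200 mm geometrically graded domain, so
the comparison isolates discretization error from model-mismatch
error.

### The default joint geometry

The default `geometry_model()` is the one genuinely open design
choice, fixed as follows. Its "condyle radius" is the **effective
relative-curvature radius of the articulation**, 600 mm — not the
~25 mm radius of a bare condyle. The femoral condyle articulates
against a concave tibial socket completed by the meniscus; two nearly
conforming surfaces of radii R₁ and −R₂ have relative curvature
1/R_eff = 1/R₁ − 1/R₂, an order of magnitude flatter than either
surface. This congruence is exactly the argument the source
methodology makes for why b lies near −1 rather than at the Hertzian
−2/3: an unconforming ball-on-plane model (set
`condyle_radius = 25`) produces strong contact-area growth and an
exponent near −0.4, outside the physiological range, while the
congruent default lands in the published band. The remaining defaults
are anatomical mid-range values: plateau radius 20 mm, condyle extent
10 mm, cartilage 2 mm per layer, meniscus wedge rising 0.2 → 3 mm
across the outer half of the plateau, bone segments 10 mm, initial
contact just touching (apex gap 0).

At the default sizes (soft-tissue elements 1.2 mm at the base level,
bone four times coarser through its thickness, one adaptive refinement
to 0.6 mm; roughly 350 → 1400 elements) the full ten-value sweep runs
in about half a minute. The 1 MPa case routinely fails on the refined
mesh — an element of the thin meniscus tip inverts under the
accumulated compression — and is reported as an absent row rather than
fabricated; the original commercial-solver study reports the same
softest-case non-convergence. The fit then uses the remaining
converged rows (fits require at least three).

## Fitting choices

Coefficients are estimated by Levenberg–Marquardt nonlinear least
squares **on the original strain scale**, initialized from an ordinary
least-squares fit of log ε on log E, and R² is reported on the
original scale (1 − SS_res/SS_tot). This matches what standard
curve-fitting tools do by default and what the published fits used.
Two consequences are handled explicitly:

* With noise-free power-law data the log-log initialization is already
  exact and the refinement preserves it (tested at 1e−10 relative).
* Under the multiplicative noise model of the synthetic sweeps the
  original-scale residuals are heteroscedastic, so the ordinary nls
  covariance understates the coefficient uncertainty. Standard errors
  are therefore computed with a heteroscedasticity-consistent (HC3)
  sandwich estimator; simulation tests check that ±3 SE intervals
  cover the generating coefficients at ≥ 95%.

Cohort summaries report the **sample** standard deviation (n−1) by
default, with the population SD available via
`cohort_summary(sd_type = "population")`; the published tables mix the
two conventions, and the recomputable stiffness summary is the sample
one.

## The phantom generator

`generate_knee_phantom()` emulates the acquisition geometry of the
in-vivo protocol — by default 72 sagittal slices of 2 mm and a
512 × 512 in-plane matrix over a 140 mm field of view (0.27 mm
pixels) — as integer label volumes (background 0, femur 1, femoral
cartilage 2, tibia 3, tibial cartilage 4, meniscus 5) with a
spherically curved condyle above a flat plateau. Loading is a rigid,
purely axial, downward translation of the femur complex, quantized to
the voxel grid; the quantized per-slice gaps are what the ground truth
records, so recovery tolerances are exact statements rather than
approximations. Nominal surfaces denote boundary-voxel-center
positions, and the tibia surface is placed a whole number of rows
below the femoral apex: the realized center-to-center bone gap — which
is what the morphometry measures — equals the requested gap within
half a voxel, with identical quantization phase on both surfaces.

What the phantom deliberately does **not** emulate: MR signal and
intensity, segmentation error beyond grid quantization, femoral
rotation or translation components other than axial, cartilage
thickness variation, and any load-dependent tissue deformation (the
femur complex is rigid). Passing the recovery tests therefore
demonstrates that the measurement machinery is exact on clean labels;
it says nothing about segmentation quality on real images, which the
original protocol handled with expert validation.

Two measurement details worth knowing: distances are computed between
boundary-voxel centers, via a Euclidean distance transform of one
facing surface sampled at the other (EBImage) when the in-plane
spacing is isotropic, and by an exhaustive vectorized nearest-pair
search otherwise — the test suite holds both against an independently
written brute-force oracle; and surfaces are restricted to "facing"
boundary voxels (femur voxels whose inferior neighbour is non-femur,
tibia voxels whose superior neighbour is non-tibia) so shaft-to-shaft
shortcuts cannot produce spurious minima. Slices missing either
surface yield an absent value and are excluded from both numerator and
denominator of the mBGFT; a gap that widens under load produces a
negative ΔmBGFT, which is reported with a warning rather than clamped.

## Degenerate inputs and error behaviour

Constructors validate their invariants up front: a loaded-gap
reduction at least as large as the unloaded gap, a gap too small to
hold both cartilage layers, geometry that does not fit the volume, a
non-increasing stiffness grid, or a non-positive strain all fail
immediately with a message naming the offending parameter. The sweep
propagates per-row solver failures as absent rows without aborting;
`run_cohort()` isolates per-session failures; an out-of-range slice
index is an error, distinct from the legitimate "surface absent in
this slice" case.

## Bundled reference values

`reference_sessions()` carries the printed measurements of the
six-session in-vivo cohort (three healthy adults, scanned twice)
verbatim, including three internal inconsistencies that are preserved
rather than resolved: the second stiffness-table row is labelled as a
Subject 2 session although its values belong to Subject 1's repeat
scan (flagged via `label_conflict`); that session's mBGFT prints as
5.64 mm in the gap table and 5.66 mm in the stiffness table (both
stored); and printed strains derive from unrounded gaps, so e.g.
0.50/7.31 = 0.068399 prints as 0.06839. Tests against printed strains
use a 5 × 10⁻⁴ relative tolerance for this reason, and inversion
checks use 0.5% to absorb printed-input rounding. The percent-ΔmBGFT
row of the gap table is inconsistent with its own printed gaps and is
stored but not used as a check target.

## Problem sizes

Chosen as the package's own defaults: test phantoms are 6–10 slices of
64–256² voxels (the acquisition-scale 72 × 512² phantom runs in the
analysis scripts); the recovery study uses 20 seeded phantoms; fit
recovery uses 200 seeded noisy sweeps at noise SD 0.02; the Hertz
benchmark uses a ~1500-node graded mesh; the acceptance sweep uses the
default mesh sizes above.

## Known limitations

* The solver is small-strain linear elastic with an
  updated-coordinate treatment of large deflection; no finite-strain
  kinematics, no poroelastic, viscoelastic or anisotropic tissue
  behaviour, no synovial fluid pressure, no ligaments or muscle tone.
* The 2-D idealization cannot reproduce any subject's absolute
  deformation values; only the shape of the strain–stiffness law and
  the closed-form benchmarks are claims the package makes about the
  solver.
* The generalized model averages six sessions from three healthy
  subjects; its coefficients are illustrative, not normative.
* Node-to-segment contact with frozen per-substep projections assumes
  small sliding, which the near-axial kinematics of this joint model
  satisfies but general contact problems may not.
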