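---
title: "Estimating craniectomy surface area from volumetric skull masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating craniectomy surface area from volumetric skull masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapmetrics)
```

## The problem

Decompressive craniectomy removes a piece of the skull (the *skull flap*) to
relieve intracranial pressure. The size of the opening — most usefully its
outer-table surface area — is a candidate predictor of decompressive effect
and of complications, but it is rarely quantified because no convenient,
validated measurement exists on routine imaging. This package implements and
cross-validates three estimators of the flap's outer surface area from
pre- and post-operative volumetric bone masks:

* **Marching-cube estimator (`mc_area()`)** — triangulate the flap surface,
  sum the triangle areas, and keep only triangles whose outward normal
  points away from the skull centre (the outer table).
* **Quasi-Monte Carlo Cauchy–Crofton estimator (`qmc_area()`)** — enclose
  the flap in a ball of known surface area $S_b$, cast $n_\ell$
  low-discrepancy chords of the ball, count the crossings $n$ of the flap
  surface, estimate the total surface as $S = (n / n_b)\,S_b$ with
  $n_b = 2 n_\ell$, and halve it for the outer table.
* **AC method (`ac_area()`)** — the bedside-usable product
  $S_{ac} = A \times C$ of the greatest axial defect length $A$ and the
  craniectomy height $C$ (number of axial slices showing a full-thickness
  defect, times the slice spacing).

Since clinical CT pairs cannot be redistributed, the package ships a
synthetic phantom generator with analytically known flap areas, so that the
entire pipeline — segmentation, rigid registration, subtraction, and the
three estimators — is testable end to end against closed-form ground truth.

## The phantom model

The skull is modelled as a spherical shell of outer radius $R$ (default
75 mm, adult vault scale) and thickness $t$ (default 5 mm, realistic
calvarium), digitized by centre-point sampling so that voxel counts are
directly comparable to analytic volumes. The craniectomy is an angular
window: azimuth within $\pm\theta$ of a centre direction, polar angle in
$[\varphi_1, \varphi_2]$. Its exact outer-table area is the surface
integral

$$S = R^2 \cdot 2\theta \cdot (\cos\varphi_1 - \cos\varphi_2),$$

implemented in `dome_patch_outer_area()` and used as the oracle throughout
the test suite. `chord_lengths()` gives the analytic counterparts of the AC
measurements: $A = 2R\sin\theta\sin\varphi^*$ at the widest polar ring
$\varphi^*$ (capped at $\theta = \pi/2$, where the in-plane extremal
distance saturates at the ring diameter), the axial height
$C = R(\cos\varphi_1 - \cos\varphi_2)$, and the great-circle chord
$C' = 2R\sin((\varphi_2-\varphi_1)/2)$. For equatorial patches the ratio
$A\,C / S$ equals $\sin\theta/\theta$ exactly, which is the geometric reason
the AC product under-reads very wide openings.

`simulate_cohort()` draws true areas uniformly over a requested range
(default 9.46–205.32 cm², the spread of a real craniectomy case series,
including small posterior-fossa openings), then solves the window angles so
each case's analytic area equals its draw exactly: polar centre
$\sim U(0.95, 1.45)$ rad and aspect ratio (azimuthal width over polar arc)
$\sim U(0.75, 1.3)$ emulate roughly isotropic frontotemporoparietal defects
away from the skull base. Optional rigid misalignment (patient
repositioning) and boundary salt noise (a lightweight stand-in for metal
artifacts, testing graceful degradation only) complete the emulation.

Two deliberate departures from a textbook sphere:

* **Basal prominences.** A perfect spherical shell maps onto itself under
  every rotation, so rigid registration of phantom pairs would be an
  ill-posed problem — unlike real skulls, whose structured base anchors the
  rotation. The phantom therefore carries two solid prominences near its
  inferior pole (polar angle > 2.6 rad, outside the patch sampler's range),
  restoring the rotational identifiability the clinical task has. We
  verified the necessity directly: without them, an alignment with the
  wrong rotation scores as high as the true one.
* **What the phantom does not model.** Hounsfield-scale CT physics, beam
  hardening, sutures and foramina, ellipsoidal vault shape, bilateral
  flaps. Passing phantom tests therefore demonstrates correctness of the
  geometry pipeline under known truth, not clinical segmentation
  performance.

## Numerical design choices

**Smoothed isosurfaces.** Both digital estimators measure the level-0.5
isosurface of the binary flap mask after a small Gaussian smoothing (one
voxel per axis by default). This is essential, not cosmetic: any
midpoint-vertex isosurface of the raw binary lattice inflates a digitized
sphere's area by about 9%, and crossing counts along rays measure the
staircase boundary, which for near-tangent rays inflates estimates by tens
of percent. With the smoothing, the mesh area of a 30 mm digitized ball is
accurate to 0.25% and the Crofton estimate to better than 0.1%. For masks
so small that smoothing would sink them below the crossing level, the sigma
is halved automatically down to the raw field, so single-voxel masks still
mesh. The two estimators share the same surface definition, which is also
why they agree as closely as the two digital methods do on real data.

**Isosurfacing.** Meshes come from marching tetrahedra (six tetrahedra per
cell sharing the main diagonal, identical face diagonals in every cell), a
tables-free constant-density surfacer that is watertight for interior
masks; orientation is fixed per tetrahedron so normals point out of the
flap. Masks touching the grid boundary are rejected rather than repaired.

**Chord sampling.** The 4-D Sobol generator (direction numbers from the
classical degree-1..3 primitive polynomials; Gray-code evaluation so any
`skip` is cheap) maps each point to a line by an area-preserving direction
map ($z = 2u_1 - 1$, azimuth $2\pi u_2$) plus an offset in the
perpendicular disk at radius $R\sqrt{u_3}$, angle $2\pi u_4$. That
construction realizes the invariant kinematic measure on lines meeting the
ball, which is what makes crossing counts unbiased for the Crofton
identity; every line meets the ball, so $n_b = 2 n_\ell$ holds exactly.
Index 0 of the sequence (the all-zeros point) is skipped by default.
Crossing counting marches each chord at half the smallest voxel spacing.
Grazing hits remain an irreducible digitization ambiguity (0 or 2 counts
depending on the lattice phase).

**Registration.** Mask-based rigid registration maximizes the mean
trilinearly interpolated fixed-mask value at the transformed moving-voxel
centres: translation first (coarse-to-fine smoothing, 3 mm then 1 mm), then
a 1.5-degree rotation grid on the smoothed field to find the right basin
(the vault is nearly spherical, so the rotation landscape is shallow), then
Nelder–Mead refinement of the best candidates and a deterministic
coordinate hill-climb on the crisp field using every moving voxel. The
misalignment is undone with trilinear-interpolated (threshold 0.5)
resampling, which halves the staircase noise of nearest-neighbour label
resampling. Typical residuals on phantoms are a few tenths of a degree and
under a millimetre.

**Subtraction and cleanup.** The flap is `pre & !post`, followed by two
filters: a full-thickness filter (keep directions, binned about the skull
centroid, where the flap's radial span covers at least half the local skull
thickness *without an internal radial gap* — paired thin mismatch sheets on
the outer and inner tables span the thickness but leave a gap, a solid
defect does not), and a 26-connected component filter with a 0.5 cm³
default minimum (smaller fragments are registration noise; this automates
the visual review step a clinician would perform). The full-thickness
filter runs only when registration ran; perfectly aligned pairs subtract
losslessly.

**Degenerate inputs.** Empty masks error early with explicit messages; a
zero crossing count returns a zero estimate with a warning; zero-variance
statistics are flagged (`NA` plus a note) in cohort reports rather than
erroring, so that fully agreeing method pairs still report.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `outer_radius_mm` | 75 | outer-table radius of the phantom vault |
| `thickness_mm` | 5 (≥ 2·max spacing) | calvarial thickness; watertightness bound |
| `spacing_mm` | (1, 1, 1) | voxel spacing; use (1, 1, 5) for CT-like axial stacks |
| `n_lines` | 20000 | Sobol chords per Crofton estimate |
| `smooth_sigma` | 1 voxel | isosurface smoothing for both digital estimators |
| `min_component_cm3` | 0.5 | subtraction cleanup threshold |
| `bin_deg` | 2 | angular bin width for the AC outer-table search |
| `margin_factor` | 1.05 | enclosing-ball radius safety factor |

## What the validation shows — and known limitations

On digitized spheres both digital estimators are accurate well below one
percent. On full-thickness shell patches both *overestimate* the
outer-table oracle, and the overestimate grows as the patch shrinks: the
mesh estimator keeps part of the digitized rim (cut faces are parallel to
the radial direction, so their normals straddle the strict
`normal · (centroid − centre) > 0` test), and halving the Crofton total
assigns half of the rim and inner-table area to the outer estimate. With a
realistic 5 mm shell this bias reaches ~15–20% near 10 cm² and falls below
3% above ~100 cm² — the small-craniectomy inaccuracy both estimators are
known for clinically. It could only be "fixed" by an unrealistically thin
phantom shell, which we decline; the acceptance suite records the failure
honestly at the small end of the size range.

The AC product is systematically low on dome-shaped phantoms: the
$\sin\theta/\theta$ factor for wide openings, plus the loss of edge slices
that are genuinely not full-thickness where the conical patch boundary
crosses a 5 mm slab. Its mean absolute deviation from truth is ~16% at
1 mm slices (the same order as AC-versus-digital deviations reported on
clinical cohorts) and ~21% at 5 mm. Real craniectomies are flatter than
spherical-dome patches, so the geometric component of this bias is a
phantom property, not a clinical one.

Across seeded 118-case cohorts the qualitative agreement structure of the
clinical comparison is reproduced: the two digital methods track each other
far more closely (RMSD ≈ 8 cm², $r > 0.999$) than either tracks the AC
product, and the per-case mean of the three serves as the cohort
metaestimate.

Problem sizes used by the automated validation — a 30 mm ball at 1 mm
spacing, 20-patch and 118-case cohorts, 2k–200k chords over ten Sobol
skips — were chosen so the full suite completes in minutes on one CPU while
keeping every estimator at its clinical operating point (20000 lines,
118 cases).

## A short tour

```{r tour, eval = FALSE}
library(flapmetrics)

cohort <- simulate_cohort(cohort_spec(n_cases = 10, seed = 1))
report <- cohort |>
  estimate_areas() |>
  agreement_report()
tidy(report)     # pairwise RMSD, r, Bland-Altman, mean deviation, paired t
glance(report)   # cohort-level summary
autoplot(report) # Bland-Altman panels
```
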