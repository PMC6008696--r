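# flapmetrics

Decompressive craniectomy removes part of the skull — the *skull flap* — to
relieve intracranial pressure, and the **outer surface area of the flap** is
the natural measure of decompressive effort. `flapmetrics` is an R package
for neurosurgical imaging researchers that reconstructs the flap from
pre-/post-operative volumetric bone masks and estimates its outer area
three independent ways, so the convenient bedside method can be validated
against computational ones:

* **Marching-cube estimator** `mc_area()` — triangulates the flap surface
  (marching tetrahedra over a lightly smoothed occupancy field), sums
  triangle areas, and keeps the triangles whose outward normal points away
  from the skull centre: the outer table.
* **Quasi-Monte Carlo Cauchy–Crofton estimator** `qmc_area()` — encloses
  the flap in a ball of known surface area `S_b`, casts `n_l` chords from a
  four-dimensional Sobol sequence (the invariant line measure on the ball),
  counts chord–surface crossings `n`, and estimates the total surface as
  `S = (n / n_b) S_b` with `n_b = 2 n_l`, halved for the outer table.
* **AC method** `ac_area()` — the manual estimate `S_ac = A x C`: greatest
  axial defect length times craniectomy height (full-thickness-defect
  slices x slice spacing), automated from the mask.

Around these sit the full working pipeline: bone thresholding
(`segment_bone()`), mask-based rigid registration (`register_rigid()`),
flap subtraction with full-thickness and component cleanup
(`extract_flap()`), a synthetic skull-phantom generator with analytically
known flap areas (`simulate_cohort()`), and Bland–Altman-style agreement
statistics over cohorts (`agreement_report()`, with `tidy()`, `glance()`
and `autoplot()` methods). Masks read and write NIfTI via `read_mask()` /
`write_mask()`.

## Worked example

Build a skull phantom, cut a craniectomy with a known outer area, misalign
the post-operative scan, recover the flap, and measure it three ways:

```r
library(flapmetrics)

spec  <- shell_spec()                    # 75 mm vault, 5 mm thick, 1 mm voxels
shell <- make_skull_shell(spec)
patch <- patch_spec(azimuth_center_rad = 0.4, azimuth_halfwidth_rad = 0.7,
                    polar_min_rad = 0.8, polar_max_rad = 1.7)
rp <- remove_patch(shell, spec, patch)
rp$true_outer_area_cm2
#> [1] 65.01216

post <- perturb_rigid(rp$post_mask, c(2, -1, 3), c(3, -2, 1))  # repositioning
ex   <- extract_flap(shell, post)        # register + subtract + clean
dice(ex$flap, rp$true_flap)
#> [1] 0.9360537

flap <- crop_mask(ex$flap)
mc_area(flap, pre_bone = shell)
#> <area_estimate [mc]> 71.29 cm^2
#>    n_kept = 78547, n_total = 148592, n_degenerate = 0, total_area_cm2 = 132.556, ...
qmc_area(flap)
#> <area_estimate [qmc]> 65.67 cm^2
#>    n = 11658, n_b = 40000, S_b_cm2 = 450.65, radius_mm = 59.8845, ...
ac_area(ex$flap, shell)
#> <area_estimate [ac]> 57.15 cm^2
#>    A_cm = 9.52575, C_cm = 6, slice_index_of_A = 77, n_slices = 60
```

The analytic truth is 65.0 cm²: the Crofton estimate lands within a
percent, the mesh estimate reads high (it keeps part of the cut rim — the
small-flap bias this method is known for), and the AC product reads low on
dome-shaped defects. Cohort-level comparisons chain with the pipe:

```r
simulate_cohort(cohort_spec(n_cases = 118, seed = 1)) |>
  estimate_areas() |>
  agreement_report() |>
  tidy()
# one row per method pair: RMSD, Pearson r, Bland-Altman bias and limits
# of agreement, mean percentage deviation, paired-t p
```

A thin command-line wrapper over these functions is included for shell
use: see `inst/cli/flapmetrics.R` (`phantom`, `extract`, `area`, `compare`
and `geom` subcommands).

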