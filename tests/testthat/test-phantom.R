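test_that("digitized shell voxel count matches the analytic shell volume", {
  shell <- shell50()
  analytic <- 4 * pi / 3 * (50^3 - 45^3)
  expect_rel_error(mask_count(shell) * 1, analytic, 0.03)
})

test_that("a shell with thickness equal to the radius is a solid ball", {
  spec <- shell_spec(outer_radius_mm = 30, thickness_mm = 30,
                     base_features = FALSE)
  expect_rel_error(mask_count(make_skull_shell(spec)), 4 * pi / 3 * 30^3, 0.03)
})

test_that("a shell that does not fit in the grid is rejected", {
  expect_error(shell_spec(outer_radius_mm = 50, thickness_mm = 5,
                          grid_shape = c(80, 120, 120)),
               "exceeds grid bounds")
  expect_error(shell_spec(outer_radius_mm = 50, thickness_mm = 0.5),
               "watertight")
})

test_that("the skull phantom is a single 6-connected component", {
  lab <- label_components(shell75(), connectivity = 6L)
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("remove_patch returns the exact analytic patch area", {
  shell <- shell50()
  # near-hemisphere: full azimuthal coverage is approached with theta -> pi
  rp <- remove_patch(shell, shell50_spec(),
                     patch_spec(0, pi - 1e-9, 1e-9, pi / 2))
  expect_equal(rp$true_outer_area_cm2, 2 * pi * 25, tolerance = 1e-6)
  skip_if_not_installed("pracma")
  rp2 <- split50()
  q <- pracma::integral2(function(az, pol) 50^2 * sin(pol),
                         -0.5, 0.5, 0.8, 1.8, reltol = 1e-10)$Q / 100
  expect_equal(rp2$true_outer_area_cm2, q, tolerance = 1e-6)
})

test_that("post mask and flap partition the shell", {
  rp <- split50()
  shell <- shell50()
  expect_identical(mask_count(rp$post_mask) + mask_count(rp$true_flap),
                   mask_count(shell))
  expect_identical(sum(rp$post_mask$grid & rp$true_flap$grid), 0L)
  expect_identical(rp$post_mask$grid | rp$true_flap$grid, shell$grid)
})

test_that("a patch that misses the shell errors", {
  expect_error(remove_patch(shell50(), shell50_spec(),
                            patch_spec(0, 0.01, 1.0, 1.0001)),
               "empty flap")
})

test_that("analytic patch area agrees with Monte-Carlo surface sampling", {
  # sample 1e6 uniform points on the 50 mm sphere; the fraction landing in
  # the patch window times the sphere area is an independent area estimate
  p <- patch_ref()
  set.seed(101)
  z <- runif(1e6, -1, 1)
  az <- runif(1e6, -pi, pi)
  polar <- acos(z)
  inside <- polar >= p$polar_min_rad & polar <= p$polar_max_rad &
    abs(az) <= p$azimuth_halfwidth_rad
  mc <- mean(inside) * 4 * pi * 50^2 / 100
  expect_rel_error(mc, split50()$true_outer_area_cm2, 0.005)
})

test_that("rigid perturbation moves the centroid as prescribed", {
  blob <- blob_mask()
  expect_identical(perturb_rigid(blob, c(0, 0, 0), c(0, 0, 0))$grid, blob$grid)
  shifted <- perturb_rigid(blob, c(0, 0, 0), c(3, 0, 0))
  expect_equal(mask_centroid(shifted) - mask_centroid(blob), c(3, 0, 0),
               tolerance = 0.5)
  # 5 degree rotation about z about an off-mask centre rotates the centroid
  ctr <- c(10, 10, 30)
  rot <- perturb_rigid(blob, c(0, 0, 5), c(0, 0, 0), center_mm = ctr)
  a <- 5 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  expected <- as.numeric(R %*% (mask_centroid(blob) - ctr)) + ctr
  expect_lt(sqrt(sum((mask_centroid(rot) - expected)^2)), 1)
})

test_that("perturbation pushing content out of the grid errors", {
  expect_error(perturb_rigid(blob_mask(), c(0, 0, 0), c(50, 0, 0)),
               "outside the grid")
})

test_that("artifact noise is seeded, bounded and severity-proportional", {
  shell <- shell50()
  expect_identical(add_artifacts(shell, 0)$grid, shell$grid)
  a1 <- add_artifacts(shell, 0.5, seed = 9)
  a2 <- add_artifacts(shell, 0.5, seed = 9)
  expect_identical(a1$grid, a2$grid)
  a3 <- add_artifacts(shell, 0.5, seed = 10)
  expect_false(identical(a1$grid, a3$grid))
  flipped <- sum(a1$grid != shell$grid)
  surf <- sum(shell$grid & !flapmetrics:::erode6(shell$grid)) +
    sum(flapmetrics:::dilate6(shell$grid) & !shell$grid)
  expect_rel_error(flipped, 0.5 * 0.25 * surf, 0.2)
  heavy <- add_artifacts(shell, 1, rate = 1)
  expect_lte(sum(heavy$grid != shell$grid), 0.1 * mask_count(shell) + 1)
})

test_that("simulated cohorts span the requested area range uniformly", {
  cohort <- fixture("cohort118", function()
    simulate_cohort(cohort_spec(n_cases = 118, seed = 1)))
  expect_identical(nrow(cohort), 118L)
  expect_true(all(cohort$true_area_cm2 >= 9.46 & cohort$true_area_cm2 <= 205.32))
  ks <- suppressWarnings(
    ks.test(cohort$true_area_cm2, "punif", 9.46, 205.32))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort simulation is reproducible and a single case is complete", {
  s <- cohort_spec(n_cases = 3, seed = 77, outer_radius_mm = 50)
  c1 <- simulate_cohort(s)
  c2 <- simulate_cohort(s)
  expect_identical(c1$true_area_cm2, c2$true_area_cm2)
  expect_identical(lapply(c1$flap_truth, function(m) m$grid),
                   lapply(c2$flap_truth, function(m) m$grid))
  cm <- case_masks(c1, 2)
  expect_s3_class(cm$pre_mask, "voxel_mask")
  expect_identical(sum(cm$post_mask$grid & cm$true_flap$grid), 0L)
  expect_identical(cm$post_mask$grid | cm$true_flap$grid, cm$pre_mask$grid)
  expect_equal(cm$true_outer_area_cm2, c1$true_area_cm2[2])
})

test_that("misaligned cohort cases carry their applied transform", {
  s <- cohort_spec(n_cases = 2, seed = 5, outer_radius_mm = 50,
                   misalignment = list(max_rotation_deg = 3,
                                       max_translation_mm = 3))
  cohort <- simulate_cohort(s)
  cm <- case_masks(cohort, 1)
  expect_s3_class(cm$applied_transform, "rigid_transform")
  expect_false(identical(cm$post_mask$grid,
                         cm$pre_mask$grid & !cm$true_flap$grid))
})

test_that("an infeasible area range is rejected with the feasible bound", {
  expect_error(cohort_spec(area_range_cm2 = c(10, 1e4)), "feasible range")
})

test_that("phantom cases round-trip through NIfTI output", {
  s <- cohort_spec(n_cases = 1, seed = 3, outer_radius_mm = 50)
  cohort <- simulate_cohort(s)
  dir <- withr::local_tempdir()
  write_case(cohort, 1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pre.nii.gz", "post.nii.gz", "flap_truth.nii.gz", "case.json")))))
  back <- read_mask(file.path(dir, "flap_truth.nii.gz"))
  expect_identical(back$grid, case_masks(cohort, 1)$true_flap$grid)
  expect_equal(back$spacing, c(1, 1, 1))
  truth <- jsonlite::read_json(file.path(dir, "case.json"))
  expect_equal(truth$true_outer_area_cm2, cohort$true_area_cm2[1])
})
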