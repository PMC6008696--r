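test_that("bone segmentation thresholds CT-like volumes", {
  shell <- shell50()
  ct <- as_pseudo_ct(shell)
  seg <- segment_bone(ct, 300)
  expect_identical(seg$grid, shell$grid)
  expect_equal(seg$spacing, shell$spacing)
  expect_warning(seg0 <- segment_bone(array(0, c(4, 4, 4)), 300), "empty")
  expect_identical(mask_count(seg0), 0L)
  full <- segment_bone(array(7, c(3, 3, 3)), 7)
  expect_identical(mask_count(full), 27L)
  expect_error(segment_bone(array(NA_real_, c(2, 2, 2))), "finite")
})

test_that("rigid transforms apply, invert and compose as expected", {
  blob <- blob_mask()
  id <- rigid_transform()
  expect_identical(apply_transform(blob, id)$grid, blob$grid)
  expect_identical(apply_transform(blob, id, "linear")$grid, blob$grid)
  # exact voxel-multiple translation is an exact lattice shift
  t3 <- rigid_transform(c(0, 0, 0), c(3, 0, 0))
  shifted <- apply_transform(blob, t3)
  expect_identical(sum(shifted$grid), sum(blob$grid))
  expect_equal(mask_centroid(shifted)[1], mask_centroid(blob)[1] + 3)
  # round trip through a generic transform keeps Dice high
  t <- rigid_transform(c(4, -2, 3), c(1.3, -2.1, 0.7), mask_centroid(blob))
  back <- apply_transform(apply_transform(blob, t), invert_transform(t))
  expect_gte(dice(back, blob), 0.98)
})

test_that("registration recovers identity, translations and rotations", {
  blob <- blob_mask()
  t_id <- register_rigid(blob, blob)
  expect_equal(attr(t_id, "dice"), 1)
  moved <- apply_transform(blob, rigid_transform(c(0, 0, 0), c(3, 0, 0),
                                                 mask_centroid(blob)))
  t_tr <- register_rigid(blob, moved)
  expect_lt(max(abs(t_tr$translation_mm - c(-3, 0, 0))), 1)
  rotated <- apply_transform(blob, rigid_transform(c(0, 0, 5), c(0, 0, 0),
                                                   mask_centroid(blob)))
  t_rot <- register_rigid(blob, rotated)
  expect_lt(abs(t_rot$rotation_deg[3] + 5), 1)
  expect_gte(attr(t_rot, "dice"), 0.95)
  expect_error(register_rigid(blob, voxel_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("subtraction recovers the flap and filters specks", {
  shell <- shell50()
  rp <- split50()
  expect_error(subtract_flap(shell, shell), "no craniectomy")
  flap <- subtract_flap(shell, rp$post_mask)
  expect_gte(dice(flap, rp$true_flap), 0.99)
  expect_true(all(shell$grid[flap$grid]))  # flap is a subset of pre
  # sprinkle 50 background specks into the post mask: the single-voxel
  # components they create in the difference must be filtered out
  post <- rp$post_mask
  set.seed(12)
  bg <- which(!shell$grid)
  specks <- sample(bg, 50)
  pre2 <- shell
  pre2$grid[specks] <- TRUE   # extra pre-op bone absent post-op
  flap2 <- subtract_flap(pre2, post, min_component_cm3 = 0.1)
  expect_identical(sum(flap2$grid[specks]), 0L)
  expect_gte(dice(flap2, rp$true_flap), 0.99)
})

test_that("unregistered extraction of an aligned pair is lossless", {
  rp <- split50()
  ex <- extract_flap(shell50(), rp$post_mask, register = FALSE)
  expect_gte(dice(ex$flap, rp$true_flap), 0.99)
  expect_null(ex$transform)
})

test_that("full pipeline recovers a misaligned phantom flap", {
  shell <- shell75()
  spec <- shell75_spec()
  rp <- remove_patch(shell, spec, patch_spec(0.3, 0.8, 0.7, 1.7))
  post_p <- perturb_rigid(rp$post_mask, c(2, -3, 4), c(3, -4, 2))
  ex <- extract_flap(shell, post_p)
  expect_gte(dice(ex$flap, rp$true_flap), 0.9)
  expect_s3_class(ex$transform, "rigid_transform")
  expect_gte(ex$registration_dice, 0.9)
})
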