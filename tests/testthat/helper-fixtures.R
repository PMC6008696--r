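# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# digitized solid ball, 1 mm spacing, centred on the grid
ball_mask <- function(radius_mm, n = 2 * radius_mm + 12, spacing = 1) {
  ax <- ((seq_len(n) - 1) - (n - 1) / 2) * spacing
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  voxel_mask(array(r2 <= radius_mm^2, c(n, n, n)), rep(spacing, 3))
}

ball30 <- function() fixture("ball30", function() ball_mask(30))

# 50 mm plain shell (no basal features) and a reference patch on it
shell50_spec <- function() {
  shell_spec(outer_radius_mm = 50, thickness_mm = 5, base_features = FALSE)
}
shell50 <- function() fixture("shell50", function() make_skull_shell(shell50_spec()))

patch_ref <- function() patch_spec(0, 0.5, 0.8, 1.8)
split50 <- function() {
  fixture("split50", function() remove_patch(shell50(), shell50_spec(), patch_ref()))
}

# asymmetric two-box blob for registration tests
blob_mask <- function() {
  fixture("blob", function() {
    g <- array(FALSE, c(60, 60, 60))
    g[20:35, 18:30, 25:40] <- TRUE
    g[30:42, 28:40, 20:30] <- TRUE
    voxel_mask(g)
  })
}

# default 75 mm skull phantom (with basal features) shared by the
# extraction and acceptance tests
shell75_spec <- function() shell_spec(outer_radius_mm = 75, thickness_mm = 5)
shell75 <- function() fixture("shell75", function() make_skull_shell(shell75_spec()))

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
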