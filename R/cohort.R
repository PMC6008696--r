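#' Estimate flap areas across a phantom cohort
#'
#' Runs the three estimators over every case of a simulated cohort and
#' appends their results as columns, yielding the per-case area table that
#' [agreement_report()] consumes.  By default the estimators see the
#' ground-truth flap masks (`source = "truth"`); with `source = "extracted"`
#' each case is first pushed through the full preprocessing chain
#' ([extract_flap()]), including registration when the cohort was simulated
#' with misalignment.
#'
#' @param cohort A `flap_cohort` from [simulate_cohort()].
#' @param methods Subset of `c("mc", "qmc", "ac")`.
#' @param n_lines,skip Chord budget for the quasi-Monte Carlo estimator.
#' @param smooth_sigma Mesh pre-smoothing (voxels) for the marching
#'   estimator.
#' @param source `"truth"` or `"extracted"`.
#' @param min_component_cm3 Cleanup threshold for extraction.
#' @return The cohort tibble with numeric columns `mc`, `qmc`, `ac`
#'   (cm^2, as requested) added.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_cases = 2, seed = 1))
#' areas <- estimate_areas(cohort)
#' areas[, c("case_id", "true_area_cm2", "mc", "qmc", "ac")]
#' }
#' @export
estimate_areas <- function(cohort, methods = c("mc", "qmc", "ac"),
                           n_lines = 20000L, skip = 1L, smooth_sigma = 1,
                           source = c("truth", "extracted"),
                           min_component_cm3 = 0.5) {
  stopifnot(inherits(cohort, "flap_cohort"))
  source <- match.arg(source)
  methods <- match.arg(methods, several.ok = TRUE)
  shell <- attr(cohort, "shell")
  center <- mask_centroid(shell)
  flap_lin <- attr(cohort, "flap_lin")
  n <- nrow(cohort)
  res <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("mc", "qmc", "ac")))
  for (i in seq_len(n)) {
    if (source == "truth") {
      flap_small <- cohort$flap_truth[[i]]
      flap_full <- NULL
      if ("ac" %in% methods) {
        g <- array(FALSE, dim(shell$grid))
        g[flap_lin[[i]]] <- TRUE
        flap_full <- voxel_mask(g, shell$spacing, shell$origin)
      }
    } else {
      cm <- case_masks(cohort, cohort$case_id[i])
      ex <- extract_flap(cm$pre_mask, cm$post_mask, min_component_cm3,
                         register = !is.null(cm$applied_transform))
      flap_full <- ex$flap
      flap_small <- crop_mask(flap_full, pad = 2L)
    }
    digital <- intersect(c("mc", "qmc"), methods)
    of <- if (length(digital)) occupancy_field(flap_small, smooth_sigma)
    if ("mc" %in% methods) {
      raw <- cpp_marching_tetra(of$field, dim(of$field), of$spacing,
                                of$origin, 0.5)
      mesh <- structure(list(vertices = raw$vertices, faces = raw$faces,
                             smooth_sigma = of$sigma, level = 0.5),
                        class = "triangle_mesh")
      res[i, "mc"] <- outer_area_mc(mesh, center)$area_cm2
    }
    if ("qmc" %in% methods) {
      ball <- enclosing_ball(flap_small)
      chords <- generate_chords(ball, n_lines, skip)
      n_cross <- sum(count_crossings(flap_small, chords, field = of))
      res[i, "qmc"] <- (n_cross / (2 * n_lines)) * ball$surface_area_cm2 / 2
    }
    if ("ac" %in% methods) {
      res[i, "ac"] <- ac_area(flap_full, shell,
                              center_xy = center[1:2])$area_cm2
    }
  }
  out <- cohort
  for (m in methods) out[[m]] <- res[, m]
  out
}
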