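#' Root-mean-square deviation between paired measurements
#'
#' @param x,y Equal-length numeric vectors (cm^2).
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmsd <- function(x, y) {
  check_pair(x, y, min_n = 1L)
  sqrt(mean((x - y)^2))
}

#' Pearson correlation between paired measurements
#'
#' @param x,y Equal-length numeric vectors with `n >= 3` and non-zero
#'   variance.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y, min_n = 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)` (sample standard deviation).
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`.
#' @return List with `bias`, `loa_low`, `loa_high`, and `points` -- a tibble
#'   of per-case `(mean, difference)` pairs for plotting.
#' @export
bland_altman <- function(x, y) {
  check_pair(x, y, min_n = 2L)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    points = tibble::tibble(mean = (x + y) / 2, difference = d)
  )
}

#' Mean percentage deviation between paired measurements
#'
#' Mean over cases of `|x - y| / denom * 100`.  The default denominator is
#' the pairwise mean `(x + y) / 2` (symmetric in the two methods); the
#' hematoma-estimation literature instead divides by the reference method,
#' selectable with `denominator = "reference"` (the reference is `y`).
#'
#' @param x,y Equal-length numeric vectors.
#' @param denominator `"pair_mean"` or `"reference"`.
#' @return Percentage.
#' @export
mean_deviation_pct <- function(x, y, denominator = c("pair_mean", "reference")) {
  check_pair(x, y, min_n = 1L)
  denominator <- match.arg(denominator)
  denom <- if (denominator == "pair_mean") (x + y) / 2 else y
  if (any(denom <= 0)) {
    stop("non-positive denominator in mean deviation", call. = FALSE)
  }
  mean(abs(x - y) / denom) * 100
}

#' Paired t-test p value
#'
#' Two-sided p value of `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom, `d = x - y`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`, with non-degenerate
#'   differences.
#' @return Two-sided p value.
#' @export
paired_t <- function(x, y) {
  check_pair(x, y, min_n = 2L)
  d <- x - y
  if (sd(d) == 0) {
    stop("paired t-test undefined: zero-variance differences", call. = FALSE)
  }
  t.test(x, y, paired = TRUE)$p.value
}

check_pair <- function(x, y, min_n) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Pairwise agreement report over a case cohort
#'
#' Assembles all pairwise agreement statistics -- RMSD, Pearson r,
#' Bland-Altman bias and limits of agreement, mean percentage deviation and
#' the paired-t p value -- between every pair of method columns, together
#' with per-method summaries and the per-case metaestimate (the mean of the
#' methods).  Degenerate statistics (zero variance) are returned as `NA`
#' and flagged in the `note` column rather than erroring, so fully agreeing
#' method pairs still produce a report.
#'
#' @param results A data frame with a `case_id` column and one numeric
#'   column per method (e.g. the output of [estimate_areas()]), or a long
#'   table with columns `case_id`, `method`, `area_cm2`.
#' @param methods Method columns to compare; defaults to the intersection of
#'   `c("mc", "qmc", "ac")` with the available columns, or all methods of a
#'   long table.
#' @param denominator Passed to [mean_deviation_pct()].
#' @return An `agreement_report`: list of tibbles `pairs`, `methods`,
#'   `cases`.
#' @examples
#' results <- tibble::tibble(
#'   case_id = 1:5,
#'   mc = c(100, 120, 80, 150, 90),
#'   qmc = c(98, 123, 79, 148, 93),
#'   ac = c(110, 115, 70, 160, 85)
#' )
#' rep <- agreement_report(results)
#' tidy(rep)
#' @export
agreement_report <- function(results, methods = NULL,
                             denominator = c("pair_mean", "reference")) {
  denominator <- match.arg(denominator)
  results <- tibble::as_tibble(as.data.frame(results)[
    , setdiff(names(results), c("patch", "rotation_deg", "translation_mm",
                                "flap_truth")), drop = FALSE])
  if (all(c("method", "area_cm2") %in% names(results))) {
    results <- tidyr::pivot_wider(results[, c("case_id", "method", "area_cm2")],
                                  names_from = "method",
                                  values_from = "area_cm2")
  }
  if (!"case_id" %in% names(results)) {
    results$case_id <- seq_len(nrow(results))
  }
  if (is.null(methods)) {
    known <- intersect(c("mc", "qmc", "ac"), names(results))
    methods <- if (length(known) >= 2) known else
      setdiff(names(results)[vapply(results, is.numeric, logical(1))],
              c("case_id", "true_area_cm2", "artifact_severity",
                "artifact_seed"))
  }
  if (length(methods) < 2) stop("need at least two method columns", call. = FALSE)
  if (nrow(results) < 3) stop("need at least 3 cases", call. = FALSE)
  vals <- results[methods]
  if (any(!vapply(vals, is.numeric, logical(1)))) {
    stop("method columns must be numeric", call. = FALSE)
  }
  if (any(is.na(vals))) stop("missing values in method columns", call. = FALSE)

  pair_idx <- utils::combn(methods, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(pair_idx, function(p) {
    x <- vals[[p[1]]]
    y <- vals[[p[2]]]
    ba <- bland_altman(x, y)
    zero_var <- sd(x - y) == 0
    const <- sd(x) == 0 || sd(y) == 0
    tibble::tibble(
      method_x = p[1], method_y = p[2], n = length(x),
      rmsd_cm2 = rmsd(x, y),
      pearson_r = if (const) NA_real_ else pearson_r(x, y),
      bias_cm2 = ba$bias, loa_low_cm2 = ba$loa_low, loa_high_cm2 = ba$loa_high,
      mean_deviation_pct = mean_deviation_pct(x, y, denominator),
      paired_t_p = if (zero_var) NA_real_ else paired_t(x, y),
      note = dplyr::case_when(
        const ~ "zero variance: r undefined",
        zero_var ~ "zero-variance differences: t undefined",
        .default = NA_character_
      )
    )
  })

  method_summary <- purrr::map_dfr(methods, function(m) {
    v <- vals[[m]]
    tibble::tibble(method = m, min_cm2 = min(v), max_cm2 = max(v),
                   median_cm2 = median(v), mean_cm2 = mean(v), sd_cm2 = sd(v))
  })

  cases <- dplyr::bind_cols(
    results["case_id"], vals,
    tibble::tibble(metaestimate_cm2 = rowMeans(vals))
  )
  if ("true_area_cm2" %in% names(results)) {
    cases$true_area_cm2 <- results$true_area_cm2
  }
  structure(list(pairs = pairs, methods = method_summary, cases = cases),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d cases, methods: %s\n",
              nrow(x$cases), paste(x$methods$method, collapse = ", ")))
  print(as.data.frame(x$pairs), digits = 4)
  invisible(x)
}

#' @describeIn agreement_report Pairwise statistics, one row per method pair.
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) x$pairs

#' @describeIn agreement_report One-row cohort summary: case count, method
#'   count and the range/median of the per-case metaestimate.
#' @export
glance.agreement_report <- function(x, ...) {
  meta <- x$cases$metaestimate_cm2
  tibble::tibble(
    n_cases = nrow(x$cases),
    n_methods = nrow(x$methods),
    meta_min_cm2 = min(meta), meta_max_cm2 = max(meta),
    meta_median_cm2 = median(meta), meta_mean_cm2 = mean(meta),
    meta_sd_cm2 = sd(meta)
  )
}

#' @describeIn agreement_report Bland-Altman panels (`type = "bland_altman"`)
#'   or scatter against the line of equality (`type = "equality"`), faceted
#'   by method pair.
#' @param object An `agreement_report`.
#' @param type Plot flavour.
#' @export
autoplot.agreement_report <- function(object,
                                      type = c("bland_altman", "equality"),
                                      ...) {
  type <- match.arg(type)
  long <- purrr::map_dfr(seq_len(nrow(object$pairs)), function(i) {
    p <- object$pairs[i, ]
    x <- object$cases[[p$method_x]]
    y <- object$cases[[p$method_y]]
    tibble::tibble(
      pair = sprintf("%s vs %s", p$method_x, p$method_y),
      x = x, y = y, mean = (x + y) / 2, difference = x - y,
      bias = p$bias_cm2, loa_low = p$loa_low_cm2, loa_high = p$loa_high_cm2
    )
  })
  if (type == "bland_altman") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$difference)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$bias),
                          linetype = "solid") +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_low),
                          linetype = "dashed") +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_high),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~pair) +
      ggplot2::labs(x = "pair mean (cm^2)", y = "difference (cm^2)")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::facet_wrap(~pair) +
      ggplot2::labs(x = "first method (cm^2)", y = "second method (cm^2)")
  }
}

#' Serialize an agreement report
#'
#' `write_report()` writes the three report tables to one JSON file;
#' `read_report()` restores the report object from it.  Round-trips are
#' lossless to the numeric precision of the JSON encoding (full double
#' precision by default).
#'
#' @param report An [agreement_report()].
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   restored report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(
    list(pairs = report$pairs, methods = report$methods, cases = report$cases),
    path, auto_unbox = FALSE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = tibble::as_tibble(raw$pairs),
                 methods = tibble::as_tibble(raw$methods),
                 cases = tibble::as_tibble(raw$cases)),
            class = "agreement_report")
}
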