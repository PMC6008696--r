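test_that("rmsd matches hand-computed values and is symmetric", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2))
  x <- c(10, 20, 30, 40)
  y <- c(12, 18, 33, 39)
  expect_equal(rmsd(x, y), rmsd(rev(x), rev(y)))
  expect_equal(rmsd(x, y), rmsd(y, x))
  expect_error(rmsd(1:3, 1:4), "equal length")
})

test_that("pearson_r reproduces exact correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(2, 4)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("Bland-Altman statistics match hand computation", {
  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  bac <- bland_altman(c(5, 6, 7), c(3, 4, 5))
  expect_equal(c(bac$bias, bac$loa_low, bac$loa_high), c(2, 2, 2))
  ba <- bland_altman(c(10, 12, 14), c(9, 13, 12))
  # differences (1, -1, 2): mean 2/3, sd 1.527525
  expect_equal(ba$bias, 2 / 3, tolerance = 1e-6)
  expect_equal(ba$loa_low, 2 / 3 - 1.96 * sd(c(1, -1, 2)), tolerance = 1e-6)
  expect_equal(ba$loa_high, 2 / 3 + 1.96 * sd(c(1, -1, 2)), tolerance = 1e-6)
  expect_equal(ba$points$mean, c(9.5, 12.5, 13))
  expect_equal(ba$points$difference, c(1, -1, 2))
})

test_that("mean percentage deviation supports both denominators", {
  expect_equal(mean_deviation_pct(c(5, 6), c(5, 6)), 0)
  expect_equal(mean_deviation_pct(100, 90), 10 / 95 * 100, tolerance = 1e-10)
  expect_equal(mean_deviation_pct(100, 90), mean_deviation_pct(90, 100))
  expect_equal(mean_deviation_pct(100, 90, denominator = "reference"),
               100 / 9, tolerance = 1e-10)
  expect_error(mean_deviation_pct(1, -1), "denominator")
})

test_that("paired t p values agree with the t-distribution oracle", {
  x <- c(10, 12, 14, 16)
  y <- c(9, 13, 12, 18)
  d <- x - y
  t_stat <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(paired_t(x, y), 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-10)
  # symmetric differences with exact zero mean give p = 1
  expect_equal(paired_t(c(1, 3), c(2, 2)), 1)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
})

test_that("rmsd decomposes into bias and spread", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    x <- runif(n, 50, 150)
    y <- x + rnorm(n, sd = 8) + runif(1, -10, 10)
    d <- x - y
    expect_equal(rmsd(x, y)^2,
                 mean(d)^2 + (n - 1) / n * sd(d)^2, tolerance = 1e-10)
  }
})

test_that("agreement reports assemble pairwise statistics", {
  results <- tibble::tibble(
    case_id = 1:5,
    mc = c(100, 120, 80, 150, 90),
    qmc = c(98, 123, 79, 148, 93),
    ac = c(110, 115, 70, 160, 85)
  )
  rep <- agreement_report(results)
  expect_identical(nrow(rep$pairs), 3L)
  row <- rep$pairs[rep$pairs$method_x == "mc" & rep$pairs$method_y == "qmc", ]
  expect_equal(row$rmsd_cm2, rmsd(results$mc, results$qmc))
  expect_equal(row$pearson_r, cor(results$mc, results$qmc))
  expect_equal(row$mean_deviation_pct,
               mean_deviation_pct(results$mc, results$qmc))
  expect_equal(rep$cases$metaestimate_cm2,
               rowMeans(results[, c("mc", "qmc", "ac")]))
  expect_true(all(rep$pairs$loa_low_cm2 <= rep$pairs$bias_cm2 &
                    rep$pairs$bias_cm2 <= rep$pairs$loa_high_cm2))
  expect_true(all(rep$pairs$rmsd_cm2 >= abs(rep$pairs$bias_cm2)))
  g <- glance(rep)
  expect_identical(g$n_cases, 5L)
  expect_equal(g$meta_median_cm2, median(rep$cases$metaestimate_cm2))
})

test_that("statistics are invariant under joint case reordering", {
  set.seed(8)
  results <- tibble::tibble(case_id = 1:20,
                            mc = runif(20, 50, 200))
  results$qmc <- results$mc + rnorm(20, sd = 5)
  results$ac <- results$mc * 0.9 + rnorm(20, sd = 10)
  perm <- sample(20)
  rep1 <- agreement_report(results)
  rep2 <- agreement_report(results[perm, ])
  expect_equal(rep1$pairs[, -ncol(rep1$pairs)], rep2$pairs[, -ncol(rep2$pairs)])
})

test_that("degenerate cohorts are flagged rather than fatal", {
  same <- tibble::tibble(case_id = 1:4, mc = c(5, 6, 7, 8),
                         qmc = c(5, 6, 7, 8), ac = c(5, 6, 7, 8))
  rep <- agreement_report(same)
  expect_true(all(rep$pairs$rmsd_cm2 == 0))
  expect_true(all(is.na(rep$pairs$paired_t_p)))
  expect_true(all(!is.na(rep$pairs$note)))
})

test_that("long-format method tables are accepted", {
  long <- tidyr::expand_grid(case_id = 1:4, method = c("mc", "qmc"))
  set.seed(2)
  long$area_cm2 <- runif(8, 50, 150)
  rep <- agreement_report(long)
  expect_identical(nrow(rep$pairs), 1L)
  expect_identical(rep$pairs$n, 4L)
})

test_that("noise injection is recovered through the RMSD", {
  set.seed(99)
  x <- runif(118, 9.46, 205.32)
  y <- x + rnorm(118, sd = 7.5)
  expect_rel_error(rmsd(x, y), 7.5, 0.15)
})

test_that("reports round-trip through JSON", {
  set.seed(4)
  results <- tibble::tibble(case_id = 1:6, mc = runif(6, 50, 150))
  results$qmc <- results$mc + rnorm(6)
  results$ac <- results$mc + rnorm(6, sd = 3)
  rep <- agreement_report(results)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$pairs$rmsd_cm2, rep$pairs$rmsd_cm2, tolerance = 1e-12)
  expect_equal(back$cases$metaestimate_cm2, rep$cases$metaestimate_cm2,
               tolerance = 1e-12)
  expect_equal(back$methods$median_cm2, rep$methods$median_cm2,
               tolerance = 1e-12)
})

test_that("Bland-Altman and equality plots build", {
  results <- tibble::tibble(case_id = 1:5, mc = c(100, 120, 80, 150, 90),
                            qmc = c(98, 123, 79, 148, 93))
  rep <- agreement_report(results)
  p1 <- autoplot(rep)
  p2 <- autoplot(rep, type = "equality")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
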