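make_records <- function(diffs, axis = "x", truth = 0) {
  data.frame(followup_id = sprintf("f%03d", seq_along(diffs)), axis = axis,
             truth_mm = truth, measured_mm = truth - diffs, diff_mm = diffs,
             generating_axes = "y", quantity = "translation",
             stringsAsFactors = FALSE)
}

test_that("difference summaries use the sample SD and flag singletons", {
  s <- summarize_differences(make_records(c(-0.1, 0.1)))
  expect_equal(s$mean, 0)
  expect_equal(s$sd, sqrt(sum(c(-0.1, 0.1)^2) / 1))  # two-point n-1 SD
  expect_equal(s$sd, 0.1414214, tolerance = 1e-6)
  expect_equal(c(s$min, s$max), c(-0.1, 0.1))
  z <- summarize_differences(make_records(rep(0, 5)))
  expect_equal(c(z$mean, z$sd, z$min, z$max), c(0, 0, 0, 0))
  one <- summarize_differences(make_records(0.3))
  expect_true(one$flagged)
  expect_identical(one$sd, 0)
  expect_error(summarize_differences(make_records(1), axis = "z"),
               "empty selection")
})

test_that("summary n is additive over disjoint subsets", {
  rec <- make_records(rnorm(40))
  idx <- rep(c(TRUE, FALSE), 20)
  n1 <- summarize_differences(rec, subset = idx)$n
  n2 <- summarize_differences(rec, subset = !idx)$n
  expect_identical(n1 + n2, summarize_differences(rec)$n)
})

test_that("zero-migration precision reproduces the 1.96 x SD definition", {
  # two-point samples constructed to have exact SDs
  for (case in list(c(0.024, 0.047), c(0.025, 0.049), c(0.073, 0.143))) {
    d <- c(-1, 1) * case[1] / sqrt(2)  # sample SD is exactly case[1]
    p <- precision_zero(make_records(d), "x")
    expect_equal(p$sd, case[1])
    expect_equal(p$precision, 1.96 * case[1])
    expect_equal(round(p$precision, 3), case[2])
  }
  allz <- precision_zero(make_records(rep(0, 10)), "x")
  expect_identical(allz$precision, 0)
  bad <- make_records(c(0.1, -0.1), truth = 0.45)
  expect_error(precision_zero(bad, "x"), "contract violation")
})

test_that("precision is absolutely scale equivariant", {
  set.seed(5)
  d <- rnorm(50, 0, 0.03)
  p1 <- precision_zero(make_records(d), "x")$precision
  for (c in c(2.5, -3, 0.1)) {
    pc <- precision_zero(make_records(c * d), "x")$precision
    expect_equal(pc, abs(c) * p1)
  }
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD with the standard CIs", {
  t0 <- seq(-3, 3, length.out = 10)
  ba <- bland_altman(t0, t0)
  expect_equal(c(ba$mean_diff, ba$loa_low, ba$loa_high), c(0, 0, 0))
  bc <- bland_altman(t0, t0 - 0.2)  # constant difference 0.2
  expect_equal(bc$mean_diff, 0.2)
  expect_equal(c(bc$loa_low, bc$loa_high), c(0.2, 0.2))
  d <- rep(c(-0.05, 0.05), 50)
  bd <- bland_altman(d, rep(0, 100))
  sd_exact <- sqrt(sum((d - mean(d))^2) / 99)
  expect_equal(bd$loa_high, 1.96 * sd_exact)
  expect_equal(bd$loa_high, 0.0985, tolerance = 5e-4)
  expect_equal(bd$ci_mean[2] - bd$mean_diff, 1.96 * sd_exact / 10)
  expect_equal(bd$ci_loa_high[2] - bd$loa_high,
               1.96 * sd_exact * sqrt(3 / 100))
  # plot-ready arrays put the migration amount on the abscissa
  expect_identical(bd$plot$migration, d)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Bland-Altman is antisymmetric under swapping truth and measured", {
  set.seed(21)
  a <- rnorm(30); b <- a + rnorm(30, 0.02, 0.05)
  f <- bland_altman(a, b)
  r <- bland_altman(b, a)
  expect_equal(r$mean_diff, -f$mean_diff)
  expect_equal(r$loa_low, -f$loa_high)
  expect_equal(r$loa_high, -f$loa_low)
})

test_that("Q-Q data pair ordered samples with (i-0.5)/n normal quantiles", {
  q <- qq_data(c(-1, 0, 1))
  expect_equal(q$sample, c(-1, 0, 1))
  expect_equal(q$theoretical, -rev(q$theoretical))  # symmetric about 0
  set.seed(31)
  d <- rnorm(500, 0, 0.03)
  qn <- qq_data(d)
  expect_gt(cor(qn$theoretical, qn$sample), 0.99)
  qc <- qq_data(rep(0.5, 4))
  expect_true(qc$degenerate)
  expect_error(qq_data(c(1, 2)), "at least 3")
})

test_that("report tables mirror the study layout with exact pool sizes", {
  man <- build_manifest(sprintf("P%02d", 1:10), full_protocol(),
                        c(0.7812, 0.45, 0.7812))
  # a perfect instrument: measured equals truth
  measured <- data.frame(followup_id = man$followup_id,
                         mx_mm = man$truth_x_mm, my_mm = man$truth_y_mm,
                         mz_mm = man$truth_z_mm, stringsAsFactors = FALSE)
  tabs <- report_tables(man, measured)
  expect_named(tabs, c("one_axis_x", "one_axis_y", "one_axis_z", "two_axis",
                       "combined", "zero_precision"))
  expect_identical(tabs$one_axis_x$n, rep(90L, 3))
  expect_identical(tabs$one_axis_y$n, rep(110L, 3))
  expect_identical(tabs$two_axis$n, rep(490L, 3))
  expect_identical(tabs$combined$n, rep(780L, 3))
  expect_identical(tabs$zero_precision$n, c(200L, 180L, 200L))
  expect_true(all(tabs$combined$mean == 0))
  expect_true(all(tabs$zero_precision$precision == 0))
  expect_match(tabs$zero_precision$value[1], "290 follow-up CTs")
  # rotation table from externally supplied differences
  rot <- do.call(rbind, lapply(c("x", "y", "z"), function(a)
    data.frame(followup_id = man$followup_id, axis = a,
               diff_deg = 0.01, stringsAsFactors = FALSE)))
  tabs2 <- report_tables(man, measured, rotation = rot)
  expect_identical(tabs2$rotation_precision$n, rep(780L, 3))
  # join failures are loud and name the offenders
  expect_error(report_tables(man, measured[-1, ]), "unmatched")
  d <- withr::local_tempdir()
  paths <- write_report_tables(tabs, d)
  expect_length(list.files(d, pattern = "csv$"), 6L)
  back <- read.csv(file.path(d, "zero_precision.csv"))
  expect_identical(back$n, c(200L, 180L, 200L))
})
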