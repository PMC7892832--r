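make_plate <- function(slope = 0.40, intercept = 0.10, blank = 0.05,
                       standards = c(100, 50, 20, 10, 5, 2, 0)) {
  purrr::map_dfr(standards, function(conc) {
    a <- if (conc > 0) intercept + slope * log10(conc) + blank else blank
    tibble::tibble(row = "R01", col = 1, content = "standard",
                   analyte = sprintf("ng_per_ml:%g", conc),
                   replicate = 1:3, sample_id = "", a650 = a)
  })
}

test_that("the log-linear standard curve is recovered from its standards", {
  curve <- fit_standard_curve(make_plate())
  expect_equal(curve$slope, 0.40, tolerance = 1e-6)
  expect_equal(curve$intercept, 0.10, tolerance = 1e-6)
  expect_equal(curve$blank, 0.05)
  expect_equal(curve$fit_r2, 1.0)
  # flat standards are an invalid assay
  flat <- make_plate()
  flat$a650 <- 0.3
  expect_error(fit_standard_curve(flat), "invalid assay")
})

test_that("quantification inverts the curve with unit conversions", {
  curve <- fit_standard_curve(make_plate())
  a <- 0.10 + 0.40 * log10(2.112) + 0.05
  q <- quantify_specific_ige(curve, rep(a, 3), serum_dilution = 2,
                             iu_ng = 2.4)
  expect_equal(q$kU_L, 2.112 * 2 / 2.4, tolerance = 1e-6)
  expect_equal(q$status, "ok")
  # blank-level absorbance reports below-detection, never negative
  q0 <- quantify_specific_ige(curve, rep(0.05, 3))
  expect_equal(q0$status, "below_detection")
  expect_true(is.na(q0$kU_L))
  # above the top standard extrapolates with a flag
  ahi <- 0.10 + 0.40 * log10(500) + 0.05
  expect_equal(quantify_specific_ige(curve, rep(ahi, 3))$status,
               "extrapolated_high")
})

test_that("forward-then-invert is the identity across the assay range", {
  # intercept chosen so the whole 0.5-200 ng/mL range sits above blank
  curve <- fit_standard_curve(make_plate(intercept = 0.25))
  for (conc in c(0.5, 2, 9.7, 55, 200)) {
    a <- 0.25 + 0.40 * log10(conc) + 0.05
    q <- quantify_specific_ige(curve, rep(a, 3), serum_dilution = 1,
                               iu_ng = 1)
    expect_equal(q$kU_L, conc, tolerance = 1e-3)
  }
})

test_that("cohort summaries report box-plot statistics", {
  v <- tibble::tibble(isoform = "0401", kU_L = c(1, 2, 3))
  s <- cohort_summary(v)
  expect_equal(s$median, 2)
  expect_equal(c(s$min, s$max), c(1, 3))
  s1 <- cohort_summary(tibble::tibble(isoform = "x", kU_L = 5))
  expect_equal(c(s1$median, s1$min, s1$max), c(5, 5, 5))
  # quartile ordering invariant on random inputs
  set.seed(9)
  for (i in 1:10) {
    s <- cohort_summary(tibble::tibble(isoform = "x",
                                       kU_L = rlnorm(22, 0, 1)))
    expect_true(s$min <= s$q25 && s$q25 <= s$median &&
                  s$median <= s$q75 && s$q75 <= s$max)
    expect_gte(s$whisker_low, s$q25 - 1.5 * (s$q75 - s$q25))
    expect_lte(s$whisker_high, s$q75 + 1.5 * (s$q75 - s$q25))
  }
})

test_that("Friedman analysis flags rank-structured cohorts", {
  # identical within-patient ordering: the statistic reaches n(k-1)
  m <- t(replicate(22, c(4, 3, 2, 1))) * runif(22, 0.5, 2)
  colnames(m) <- c("0401", "0402", "0403", "0404")
  cmp <- compare_isoforms(m)
  expect_equal(cmp$friedman$statistic, 66)
  expect_lt(cmp$friedman$p_value, 1e-3)
  # constant matrix: statistic 0, p 1
  mc <- matrix(5, 10, 4, dimnames = list(NULL, colnames(m)))
  cmp0 <- compare_isoforms(mc)
  expect_equal(cmp0$friedman$statistic, 0)
  expect_equal(cmp0$friedman$p_value, 1)
  # invariance under a strictly monotone within-patient transformation
  set.seed(10)
  m2 <- matrix(rlnorm(88), 22, 4, dimnames = list(NULL, colnames(m)))
  expect_equal(compare_isoforms(exp(m2))$friedman$statistic,
               compare_isoforms(m2)$friedman$statistic)
  expect_error(compare_isoforms(cbind(m[, 1, drop = FALSE])), ">= 2")
  m_na <- m; m_na[3, 2] <- NA
  expect_error(compare_isoforms(m_na), "complete")
})

test_that("Spearman correlation handles signs and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_vs_reference(x, x * 3 + 1)$rho, 1)
  expect_equal(spearman_vs_reference(x, rev(x))$rho, -1)
  expect_equal(spearman_vs_reference(x, rep(1, 5))$status, "undefined")
  set.seed(12)
  r <- spearman_vs_reference(x, x + rnorm(5, 0, 0.1))
  expect_gt(r$rho, 0.8)
})

test_that("plate quantification reproduces the synthetic cohort", {
  spec <- synth_spec(seed = 21)
  e <- gen_elisa_plate(spec)
  q <- quantify_plate(e$plate)
  expect_equal(nrow(q), 88)
  j <- dplyr::inner_join(q, e$truth, by = c("sample_id", "isoform"),
                         suffix = c("", "_true"))
  expect_lt(median(abs(j$kU_L - j$kU_L_true) / j$kU_L_true), 0.05)
  expect_s3_class(plot_cohort_ige(q), "ggplot")
})
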