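test_that("paired signed-rank p is exact for untied small samples", {
  # all 16 differences of one sign: the most extreme two-sided outcome
  x <- 10 + seq_len(16) / 7
  y <- x - seq_len(16) / 100
  res <- paired_wilcoxon(x, y)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / 65536, tolerance = 1e-15)
  expect_equal(res$p_value, signed_rank_enum_p(x, y), tolerance = 1e-12)
  # mixed signs, n = 6: matches full enumeration and stats::wilcox.test
  x6 <- c(3.1, 4.5, 2.2, 6.7, 5.9, 4.0)
  y6 <- c(2.8, 5.1, 2.0, 5.2, 6.3, 3.1)
  res6 <- paired_wilcoxon(x6, y6)
  expect_equal(res6$p_value, signed_rank_enum_p(x6, y6), tolerance = 1e-12)
  expect_equal(res6$p_value,
               stats::wilcox.test(x6, y6, paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("degenerate and tied paired samples are handled", {
  x <- c(1, 2, 3, 4, 5)
  expect_warning(res <- paired_wilcoxon(x, x), "zero")
  expect_equal(res$p_value, 1)
  expect_error(paired_wilcoxon(1:3, 3:1), "n >= 5")
  # tied absolute differences force the corrected normal approximation,
  # which must agree with the reference implementation
  xt <- c(5, 6, 7, 8, 9, 10, 11, 12)
  yt <- xt - c(1, 1, 2, 2, 3, 3, -1, -2)
  res_t <- paired_wilcoxon(xt, yt)
  expect_identical(res_t$method, "normal_approx")
  ref <- suppressWarnings(
    stats::wilcox.test(xt, yt, paired = TRUE, exact = FALSE,
                       correct = TRUE))
  expect_equal(res_t$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("exact and approximate signed-rank p agree for n = 16 shifts", {
  # the worst disagreement between the exact two-sided p and the
  # continuity-corrected normal approximation over all attainable W at
  # n = 16 is 0.01036 (at W = 53); simulated shifts must stay under it
  set.seed(31)
  for (rep in 1:25) {
    x <- stats::rnorm(16)
    y <- x - stats::rnorm(16, mean = 0.3)
    p_exact <- paired_wilcoxon(x, y)$p_value
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.0104)
  }
})

test_that("rank-sum p is exact for small untied samples", {
  # completely separated groups of 8: p = 2 / choose(16, 8)
  x <- 1:8
  y <- 100 + 1:8 * 1.5
  res <- unpaired_wilcoxon(x + 0.1, y)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / choose(16, 8), tolerance = 1e-15)
  expect_equal(res$p_value, rank_sum_enum_p(x + 0.1, y), tolerance = 1e-12)
  # overlapping samples still match enumeration and wilcox.test
  x2 <- c(1.2, 3.4, 2.2, 5.1)
  y2 <- c(2.0, 4.4, 0.9, 6.1, 3.3)
  expect_equal(unpaired_wilcoxon(x2, y2)$p_value, rank_sum_enum_p(x2, y2),
               tolerance = 1e-12)
  expect_equal(unpaired_wilcoxon(x2, y2)$p_value,
               stats::wilcox.test(x2, y2)$p.value, tolerance = 1e-12)
  # identical tied groups -> p = 1 under the approximation
  z <- c(1, 1, 2, 2, 3)
  expect_equal(unpaired_wilcoxon(z, z)$p_value, 1)
  expect_error(unpaired_wilcoxon(numeric(0), 1), "non-empty")
})

test_that("rank-sum p is approximately uniform under the null", {
  set.seed(37)
  ps <- replicate(500, {
    unpaired_wilcoxon(stats::rnorm(16), stats::rnorm(16))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 1e-3)
})

test_that("metric summaries use median and range", {
  expect_equal(summarize_metric(c(1, 2, 3)), c(median = 2, min = 1, max = 3))
  expect_equal(summarize_metric(c(1, 2, 3, 4)),
               c(median = 2.5, min = 1, max = 4))
  set.seed(41)
  s <- summarize_metric(stats::rnorm(11))
  expect_true(s[["min"]] <= s[["median"]] && s[["median"]] <= s[["max"]])
})

test_that("cohort report reproduces hand-computed metrics", {
  # two patients with uniform-dose hearts: every metric is checkable by hand
  cohort <- list(toy_pair("A", 10, 4), toy_pair("B", 30, 6))
  report <- build_cohort_report(cohort)
  row <- function(m) report[report$metric == m, ]
  dm <- row("D_mean,heart (Gy)")
  expect_equal(dm$median_fb, 20)   # median of 10 and 30
  expect_equal(dm$median_eig, 5)   # median of 4 and 6
  expect_equal(c(dm$min_fb, dm$max_fb), c(10, 30))
  v25 <- row("V_25Gy,heart (%)")
  expect_equal(c(v25$median_fb, v25$median_eig), c(50, 0))  # only 30 Gy > 25
  d2 <- row("D_2%,heart (Gy)")
  expect_equal(d2$min_fb, 9.975 + 0.98 * 0.05, tolerance = 1e-9)
  expect_true(all(is.na(row("NTCP cardiac mortality (%)")$p_value)))  # n < 5
  expect_equal(row("V_heart (cm3)")$median_fb, 600)
})

test_that("identical FB and EIG plans give p = 1 everywhere", {
  cohort <- lapply(1:5, function(i) {
    dose <- 5 + 2 * i
    toy_pair(sprintf("P%d", i), dose, dose)
  })
  report <- suppressWarnings(build_cohort_report(cohort))
  expect_true(all(report$p_value == 1))
  expect_false(any(report$significant))
})

test_that("patients missing an organ are dropped from that paired test", {
  cohort <- list(toy_pair("A", 10, 4), toy_pair("B", 30, 6),
                 toy_pair("C", 20, 5))
  cohort[[3]]$eig$heart <- NULL
  w <- capture_warnings(report <- build_cohort_report(cohort))
  expect_true(any(grepl("dropping patient", w)))
  expect_equal(unique(report$n_pairs), 2L)
})

test_that("the default synthetic cohort separates heart V25Gy", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  report <- build_cohort_report(cohort)
  v25 <- report[report$metric == "V_25Gy,heart (%)", ]
  expect_lt(v25$p_value, 0.01)
  expect_true(v25$significant)
  # report construction is deterministic given the seed
  report2 <- build_cohort_report(generate_cohort(cohort_config(seed = 1)))
  expect_identical(report, report2)
})
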