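test_that("ccc is 1 on identity and -1 on reversal", {
  x <- c(1, 2, 3, 4, 7)
  expect_equal(concordance_correlation(x, x)$ccc, 1)
  z <- x - mean(x)
  expect_equal(concordance_correlation(z, -z)$ccc, -1)
})

test_that("ccc equals the hand-computed moment formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 10)
  # direct evaluation with population moments
  n <- 5
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  expected <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  got <- concordance_correlation(x, y)
  expect_equal(got$ccc, expected, tolerance = 1e-12)
  expect_true(got$ci[1] <= got$ccc && got$ccc <= got$ci[2])
})

test_that("|ccc| never exceeds |Pearson| and ccc is symmetric/shift-scale invariant", {
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    cc <- concordance_correlation(x, y)$ccc
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
  }
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(concordance_correlation(x, y)$ccc,
               concordance_correlation(y, x)$ccc)
  expect_equal(concordance_correlation(2 * x + 3, 2 * y + 3)$ccc,
               concordance_correlation(x, y)$ccc, tolerance = 1e-12)
})

test_that("ccc rejects degenerate input", {
  expect_error(concordance_correlation(1:5, 1:4))
  expect_error(concordance_correlation(c(1, 1, 1), c(2, 2, 2)), "constant")
  expect_error(concordance_correlation(1:2, 1:2), "at least 3")
})

test_that("percent deviation keeps the sign convention", {
  expect_equal(percent_deviation(100, 90), 10)
  expect_equal(percent_deviation(100, 110), -10)   # automated larger -> negative
  expect_equal(percent_deviation(25, 16), 36)
  expect_equal(percent_deviation(50, 50), 0)
  expect_error(percent_deviation(0, 5), "0")
})

test_that("object agreement implements the stated count ratios", {
  a <- object_agreement(9, 1, 0)
  expect_equal(a$sensitivity_pct, 90)
  expect_equal(a$specificity_pct, 100)
  b <- object_agreement(91, 8, 9)
  expect_equal(b$sensitivity_pct, 91 / 99 * 100)
  expect_equal(b$specificity_pct, 91)
  # aliases under the conventional names
  expect_equal(b$precision_pct, b$sensitivity_pct)
  expect_equal(b$recall_pct, b$specificity_pct)
  expect_error(object_agreement(0, 0, 5), "denominator")
})

test_that("agreement_report summarizes a paired table per feature", {
  tab <- data.frame(
    nmj_id = rep(sprintf("n%02d", 1:6), 2),
    feature = rep(c("area", "boutons"), each = 6),
    manual = c(10, 12, 9, 14, 11, 13, 25, 22, 28, 24, 26, 21),
    macro = c(10.5, 11.8, 9.2, 13.6, 11.1, 13.2, 16, 15, 19, 17, 18, 13))
  rep_ <- agreement_report(tab)
  expect_setequal(rep_$feature, c("area", "boutons"))
  expect_gt(rep_$ccc[rep_$feature == "area"], 0.9)
  expect_lt(rep_$ccc[rep_$feature == "boutons"],
            rep_$ccc[rep_$feature == "area"])
  expect_gt(rep_$mean_pct_deviation[rep_$feature == "boutons"], 20)
  # round-trips through a tab-separated file
  path <- file.path(withr::local_tempdir(), "paired.tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(agreement_report(path), rep_)
})
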