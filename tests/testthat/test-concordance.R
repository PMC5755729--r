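test_that("pearson_r reproduces exact and brute-force values", {
  d <- tibble::tibble(x = 1:10, y = 1:10)
  expect_equal(pearson_r(d, x, y)$r, 1)
  d2 <- tibble::tibble(x = 1:10, y = -2 * (1:10) + 7)
  expect_equal(pearson_r(d2, x, y)$r, -1)
  d3 <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 6))
  res <- pearson_r(d3, x, y)
  expect_equal(res$r, brute_pearson(d3$x, d3$y), tolerance = 1e-12)
  # p-value from the t transform with n - 2 df
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), res$n - 2), tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(pearson_r(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(pearson_r(tibble::tibble(x = 1:2, y = 1:2), x, y), "3 pairs")
  expect_error(lins_ccc(tibble::tibble(x = c(2, 2, 2), y = c(2, 2, 2)), x, y),
               "undefined")
})

test_that("lins_ccc equals the brute-force formula and penalizes shifts", {
  d <- tibble::tibble(x = as.numeric(1:20), y = as.numeric(1:20))
  expect_equal(lins_ccc(d, x, y)$ccc, 1)
  shifted <- dplyr::mutate(d, y = x + 5)
  expect_lt(lins_ccc(shifted, x, y)$ccc, 1)
  expect_equal(pearson_r(shifted, x, y)$r, 1)
  set.seed(21)
  d3 <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  expect_equal(lins_ccc(d3, x, y)$ccc, brute_ccc(d3$x, d3$y),
               tolerance = 1e-12)
})

test_that("|CCC| <= |r|, equal only for matched mean and variance", {
  set.seed(31)
  for (i in 1:50) {
    d <- tibble::tibble(x = rnorm(15, sd = runif(1, 0.5, 3)),
                        y = rnorm(15, mean = runif(1, -2, 2)))
    expect_lte(abs(lins_ccc(d, x, y)$ccc), abs(pearson_r(d, x, y)$r) + 1e-12)
  }
  # equality when y is x standardized back to its own mean/sd
  set.seed(32)
  x <- rnorm(30)
  y <- rev(sort(x))  # same moments, different pairing
  d <- tibble::tibble(x = sort(x), y = y)
  expect_equal(lins_ccc(d, x, y)$ccc, pearson_r(d, x, y)$r, tolerance = 1e-12)
})

test_that("pearson is affine-invariant where the concordance is not", {
  set.seed(41)
  d <- tibble::tibble(x = rnorm(25), y = rnorm(25) + 0.5 * rnorm(25))
  scaled <- dplyr::mutate(d, y = 3 * y + 2)
  expect_equal(pearson_r(d, x, y)$r, pearson_r(scaled, x, y)$r,
               tolerance = 1e-12)
  expect_lt(abs(lins_ccc(scaled, x, y)$ccc), abs(lins_ccc(d, x, y)$ccc))
})

test_that("risk groups follow the standard Recurrence Score cut-points", {
  expect_equal(as.character(assign_risk_group(c(0, 17, 17.9))),
               rep("low", 3))
  expect_equal(as.character(assign_risk_group(c(18, 25, 30, 30.5))),
               rep("intermediate", 4))
  expect_equal(as.character(assign_risk_group(c(31, 50, 100))),
               rep("high", 3))
  expect_error(assign_risk_group(101), "\\[0, 100\\]")
  expect_error(assign_risk_group(-1), "\\[0, 100\\]")
  # the three groups partition the score range
  set.seed(51)
  rs <- runif(500, 0, 100)
  expect_false(anyNA(assign_risk_group(rs)))
})

test_that("confusion summary follows the low-positive conventions", {
  perfect <- tibble::tibble(
    predicted = c("low", "low", "high"), actual = c("low", "low", "high"))
  cs <- confusion_summary(perfect, predicted, actual)
  expect_equal(unlist(cs[c("accuracy", "sensitivity", "specificity",
                           "ppv", "npv")], use.names = FALSE), rep(100, 5))
  # worked example: TP 90, TN 8, FP 2, FN 0
  d <- tibble::tibble(
    actual = rep(c("low", "high", "high"), c(90, 8, 2)),
    predicted = rep(c("low", "high", "low"), c(90, 8, 2)))
  cs2 <- confusion_summary(d, predicted, actual)
  expect_equal(cs2$TP, 90); expect_equal(cs2$TN, 8)
  expect_equal(cs2$FP, 2); expect_equal(cs2$FN, 0)
  expect_equal(cs2$accuracy, 98)
  expect_equal(cs2$sensitivity, 100)
  expect_equal(cs2$specificity, 80)
  expect_equal(cs2$ppv, 100 * 90 / 92, tolerance = 1e-12)
  expect_equal(cs2$npv, 100)
})

test_that("intermediate pairs are excluded; all-intermediate errors", {
  d <- tibble::tibble(predicted = c("low", "intermediate", "low"),
                      actual = c("intermediate", "high", "low"))
  cs <- confusion_summary(d, predicted, actual)
  expect_equal(cs$n_excluded_intermediate, 2)
  expect_equal(cs$TP + cs$TN + cs$FP + cs$FN + cs$n_excluded_intermediate, 3)
  allint <- tibble::tibble(predicted = rep("intermediate", 3),
                           actual = rep("intermediate", 3))
  expect_error(confusion_summary(allint, predicted, actual), "no pairs")
})

test_that("undefined metrics are flagged as missing, not zeroed", {
  d <- tibble::tibble(predicted = c("low", "low", "low"),
                      actual = c("low", "low", "low"))
  cs <- confusion_summary(d, predicted, actual)
  expect_true(is.na(cs$specificity))
  expect_true(is.na(cs$npv))
  expect_match(cs$undefined_metrics, "specificity")
  expect_match(cs$undefined_metrics, "npv")
})

test_that("confusion summary matches a brute-force tally on random labels", {
  set.seed(61)
  lv <- c("low", "intermediate", "high")
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- tibble::tibble(predicted = sample(lv, n, TRUE),
                        actual = sample(lv, n, TRUE))
    ref <- brute_confusion(d$predicted, d$actual)
    if (ref[["TP"]] + ref[["TN"]] + ref[["FP"]] + ref[["FN"]] == 0) {
      expect_error(confusion_summary(d, predicted, actual), "no pairs")
      next
    }
    cs <- confusion_summary(d, predicted, actual)
    expect_equal(c(cs$TP, cs$TN, cs$FP, cs$FN, cs$n_excluded_intermediate),
                 unname(ref))
  }
})

test_that("cohort percentages recompute the printed summary values", {
  rs_groups <- tibble::tibble(group = c("low", "intermediate", "high"),
                              n = c(185, 110, 33))
  out <- cohort_summary(rs_groups, n)
  expect_equal(out$percent[1], 56.4)
  grades <- tibble::tibble(grade = 1:3, n = c(64, 196, 49))
  out2 <- cohort_summary(grades, n, total = 309)
  expect_equal(out2$percent[1], 20.7)
  expect_equal(out2$percent[2], 63.4)
  expect_equal(cohort_summary(tibble::tibble(n = c(0, 5)), n)$percent[1], 0)
  expect_error(cohort_summary(tibble::tibble(n = c(0, 0)), n), "positive")
  # half-away rounding at one decimal: 1/16 = 6.25% -> 6.3, not 6.2
  expect_equal(cohort_summary(tibble::tibble(n = c(1, 15)), n)$percent,
               c(6.3, 93.8))
})
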