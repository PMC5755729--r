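make_cohort <- function(n = 200, seed = 1) {
  simulate_cohort(cohort_spec(n = n, noise_sd = 0, single_signal = TRUE,
                              seed = seed))
}

test_that("a constant target is predicted exactly", {
  co <- make_cohort(100)
  co$rs <- 25
  fit <- suppressWarnings(  # backend warns on a degenerate constant response
    fit_forest(co, predictor_set("hotspot"), forest_params(n_tree = 50),
               seed = 1))
  expect_equal(predict_rs(fit, co), rep(25, 100))
})

test_that("a noise-free Ki67-driven score is recovered to small error", {
  set.seed(17)
  co <- tibble::tibble(ki67 = runif(200, 0, 50))
  co$rs <- 2 * co$ki67
  train <- co[1:100, ]; test <- co[101:200, ]
  fit <- fit_forest(train, "ki67",
                    forest_params(n_tree = 500, m_try = 1, sampsize = 40),
                    seed = 2)
  rmse <- sqrt(mean((predict_rs(fit, test) - test$rs)^2))
  expect_lt(rmse, 5)
})

test_that("fitting is deterministic given the seed", {
  co <- make_cohort(120)
  preds <- predictor_set("hotspot")
  f1 <- fit_forest(co, preds, forest_params(n_tree = 100), seed = 9)
  f2 <- fit_forest(co, preds, forest_params(n_tree = 100), seed = 9)
  expect_identical(predict_rs(f1, co), predict_rs(f2, co))
})

test_that("predictions stay inside the Recurrence Score range", {
  co <- make_cohort(100)
  fit <- fit_forest(co, predictor_set("hotspot"),
                    forest_params(n_tree = 50), seed = 1)
  p <- predict_rs(fit, co)
  expect_true(all(p >= 0 & p <= 100))
  expect_identical(predict_rs(fit, co[0, ]), numeric(0))
  expect_error(predict_rs(fit, co[, 1:3]), "predictor")
})

test_that("missing data are rejected with a clear error", {
  co <- make_cohort(60)
  co$age[5] <- NA
  expect_error(fit_forest(co, predictor_set("hotspot"),
                          forest_params(n_tree = 10)), "complete")
  expect_message(cc <- complete_cases(co, predictor_set("hotspot")),
                 "dropped 1")
  expect_equal(nrow(cc), 59)
})

test_that("m_try defaults to 15 with expression scores and 12 without", {
  co <- make_cohort(100)
  f_chart <- fit_forest(co, predictor_set("hotspot"),
                        forest_params(n_tree = 10), seed = 1)
  expect_equal(f_chart$m_try, 12L)
  f_odx <- fit_forest(co, predictor_set("hotspot", include_odx = TRUE),
                      forest_params(n_tree = 10), seed = 1)
  expect_equal(f_odx$m_try, 15L)
  expect_warning(
    fit_forest(co, c("ki67_hotspot", "age"),
               forest_params(n_tree = 10, m_try = 5), seed = 1),
    "clipped")
})

test_that("permuting the informative predictor dominates importance", {
  co <- make_cohort(200, seed = 5)
  preds <- predictor_set("hotspot")
  fit <- fit_forest(co[1:100, ], preds, forest_params(n_tree = 200), seed = 3)
  imp <- permutation_importance(fit, co[101:200, ], seed = 4)
  expect_equal(imp$predictor[imp$rank == 1], "ki67_hotspot")
  # predictors the forest barely uses sit near zero
  noise <- imp$inc_mse_pct[imp$predictor != "ki67_hotspot"]
  expect_lt(max(abs(noise)), 30)
  expect_false(any(imp$absolute_scale))
})

test_that("zero baseline error switches importance to the absolute scale", {
  co <- make_cohort(80)
  co$rs <- 40
  fit <- suppressWarnings(  # constant response again
    fit_forest(co, predictor_set("hotspot"), forest_params(n_tree = 20),
               seed = 1))
  imp <- permutation_importance(fit, co, seed = 2)
  expect_true(all(imp$absolute_scale))
  expect_equal(imp$inc_mse_pct, rep(0, nrow(imp)))
})

test_that("cross-validation is reproducible and splits correctly", {
  co <- make_cohort(101)
  preds <- predictor_set("hotspot")
  cv1 <- cross_validate(co, preds, forest_params(n_tree = 30),
                        n_rounds = 3, seed = 7)
  cv2 <- cross_validate(co, preds, forest_params(n_tree = 30),
                        n_rounds = 3, seed = 7)
  expect_identical(cv1$rounds, cv2$rounds)
  expect_identical(cv1$importance, cv2$importance)
  # odd cohort: training half gets the extra record
  expect_equal(cv1$settings$n_train, 51)
  expect_equal(cv1$n_rounds, 3)
})

test_that("one cross-validation round equals the composed calls", {
  co <- make_cohort(100)
  preds <- predictor_set("hotspot")
  pars <- forest_params(n_tree = 50)
  cv <- cross_validate(co, preds, pars, n_rounds = 1, seed = 13)
  set.seed(13)
  s <- sample.int(.Machine$integer.max, 3)
  set.seed(s[1])
  idx <- sample.int(100, 50)
  fit <- fit_forest(co[idx, ], preds, pars, seed = s[2])
  prs <- predict_rs(fit, co[-idx, ])
  ref <- confusion_summary(
    tibble::tibble(predicted = assign_risk_group(prs),
                   actual = assign_risk_group(co$rs[-idx])),
    predicted, actual)
  expect_equal(cv$rounds$accuracy, ref$accuracy)
  expect_equal(cv$rounds$TP, ref$TP)
  imp_ref <- permutation_importance(fit, co[-idx, ], seed = s[3])
  expect_equal(cv$importance_rounds$inc_mse_pct, imp_ref$inc_mse_pct)
})

test_that("an uninformative cohort falls to the base accuracy", {
  set.seed(23)
  co <- make_cohort(150, seed = 8)
  co$rs <- sample(co$rs)  # break the Ki67 link
  cv <- cross_validate(co, predictor_set("hotspot"),
                       forest_params(n_tree = 50), n_rounds = 5, seed = 3)
  informative <- cross_validate(make_cohort(150, seed = 8),
                                predictor_set("hotspot"),
                                forest_params(n_tree = 50),
                                n_rounds = 5, seed = 3)
  acc <- cv$metrics$mean[cv$metrics$metric == "accuracy"]
  acc_inf <- informative$metrics$mean[informative$metrics$metric == "accuracy"]
  expect_lt(acc, acc_inf)
})

test_that("tidiers expose rounds and aggregates", {
  co <- make_cohort(100)
  cv <- cross_validate(co, predictor_set("hotspot"),
                       forest_params(n_tree = 20), n_rounds = 2, seed = 1)
  expect_equal(nrow(tidy(cv)), 2)
  g <- glance(cv)
  expect_equal(g$n_rounds, 2)
  expect_true(all(c("accuracy_mean", "accuracy_sd", "top_predictor")
                  %in% names(g)))
})
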