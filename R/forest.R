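#' Random-forest harness parameters
#'
#' The regression-forest settings used to predict Recurrence Scores
#' from clinico-pathological variables: 1000 trees, each grown on a
#' bootstrap draw of 40 records, considering `m_try` candidate
#' predictors per split (15 when the RT-PCR ER/PgR/HER2 expression
#' scores are included among the predictors, 12 otherwise), with the
#' standard regression minimum node size of 5.
#'
#' @param n_tree Number of trees.
#' @param m_try Predictors tried per split; `NULL` picks 15/12 by
#'   whether any predictor name starts with `"odx_"`, clipped (with a
#'   warning) to the number of predictors.
#' @param sampsize Bootstrap sample size per tree (drawn with
#'   replacement).
#' @param node_size Minimum terminal node size.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_tree = 1000, m_try = NULL, sampsize = 40,
                          node_size = 5) {
  stopifnot(n_tree >= 1, sampsize >= 1, node_size >= 1)
  if (!is.null(m_try) && m_try < 1) stop("`m_try` must be >= 1", call. = FALSE)
  structure(list(n_tree = as.integer(n_tree), m_try = m_try,
                 sampsize = as.integer(sampsize),
                 node_size = as.integer(node_size)),
            class = "forest_params")
}

resolve_mtry <- function(m_try, predictors) {
  if (is.null(m_try)) {
    m_try <- if (any(startsWith(predictors, "odx_"))) 15L else 12L
  }
  if (m_try > length(predictors)) {
    warning(sprintf("m_try = %d exceeds the %d predictors; clipped",
                    m_try, length(predictors)), call. = FALSE)
    m_try <- length(predictors)
  }
  as.integer(m_try)
}

check_complete <- function(data, cols) {
  bad <- cols[!cols %in% names(data)]
  if (length(bad)) {
    stop("missing column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[cols])) {
    stop("modeling requires complete data; records with missing values ",
         "must be dropped first (see complete_cases())", call. = FALSE)
  }
}

#' Drop records with missing predictors or response
#'
#' The forest harness does not tolerate missing data, so modeling is
#' restricted to complete cases; the number dropped is reported via a
#' message.
#'
#' @param data Cohort data frame.
#' @param cols Columns that must be complete.
#' @return Filtered tibble.
#' @export
complete_cases <- function(data, cols = names(data)) {
  keep <- stats::complete.cases(data[cols])
  if (any(!keep)) {
    message(sprintf("dropped %d of %d records with incomplete data",
                    sum(!keep), length(keep)))
  }
  tibble::as_tibble(data[keep, , drop = FALSE])
}

#' Fit a regression forest for Recurrence Score
#'
#' Grows a regression random forest of the Recurrence Score on the
#' given predictors, with each tree trained on a bootstrap draw of
#' `sampsize` records. Deterministic given `seed`.
#'
#' @param data Complete-case cohort data frame.
#' @param predictors Character vector of predictor column names.
#' @param params A [forest_params()] bundle.
#' @param response Response column (default `"rs"`).
#' @param seed Optional integer seed set before growing the forest.
#' @return An object of class `ki67_forest`.
#' @export
fit_forest <- function(data, predictors, params = forest_params(),
                       response = "rs", seed = NULL) {
  stopifnot(inherits(params, "forest_params"))
  check_complete(data, c(predictors, response))
  if (nrow(data) < params$sampsize) {
    stop(sprintf("sampsize (%d) exceeds the %d available records",
                 params$sampsize, nrow(data)), call. = FALSE)
  }
  m_try <- resolve_mtry(params$m_try, predictors)
  if (!is.null(seed)) set.seed(seed)
  x <- as.data.frame(data[predictors])
  y <- data[[response]]
  fit <- randomForest::randomForest(
    x = x, y = y,
    ntree = params$n_tree, mtry = m_try,
    sampsize = params$sampsize, replace = TRUE,
    nodesize = params$node_size
  )
  structure(list(fit = fit, predictors = predictors, response = response,
                 m_try = m_try, params = params, n_train = nrow(data)),
            class = "ki67_forest")
}

#' @export
print.ki67_forest <- function(x, ...) {
  cat(sprintf(
    "<ki67_forest> %d trees, m_try = %d, sampsize = %d, %d predictors, n = %d\n",
    x$params$n_tree, x$m_try, x$params$sampsize,
    length(x$predictors), x$n_train))
  invisible(x)
}

#' Predict Recurrence Scores
#'
#' Forest-mean prediction, clipped to the Recurrence Score range
#' `[0, 100]`.
#'
#' @param model A `ki67_forest`.
#' @param data Records carrying all model predictors.
#' @return Numeric vector of predicted Recurrence Scores (pRS).
#' @export
predict_rs <- function(model, data) {
  stopifnot(inherits(model, "ki67_forest"))
  if (nrow(data) == 0L) return(numeric(0))
  bad <- model$predictors[!model$predictors %in% names(data)]
  if (length(bad)) {
    stop("records lack model predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_complete(data, model$predictors)
  p <- as.numeric(stats::predict(model$fit,
                                 as.data.frame(data[model$predictors])))
  pmin(pmax(p, 0), 100)
}

#' Permutation variable importance (%IncMSE), one round
#'
#' For each predictor, the held-out mean squared prediction error is
#' recomputed after randomly permuting that predictor's column;
#' `%IncMSE = 100 * (MSE_perm - MSE_base) / MSE_base`. A higher value
#' means the forest leaned more heavily on that variable. When the
#' baseline MSE is exactly zero the relative form is undefined, and the
#' absolute MSE increase is reported instead with `absolute_scale =
#' TRUE`.
#'
#' @param model A `ki67_forest`.
#' @param data Evaluation records (by default the held-out test half in
#'   cross-validation; disjoint from training).
#' @param seed Integer seed for the permutations.
#' @return Tibble: `predictor`, `inc_mse_pct`, `rank` (1 = most
#'   important), `absolute_scale`.
#' @export
permutation_importance <- function(model, data, seed = NULL) {
  stopifnot(inherits(model, "ki67_forest"))
  if (nrow(data) < 2L) {
    stop("at least 2 records are required for importance", call. = FALSE)
  }
  check_complete(data, c(model$predictors, model$response))
  if (!is.null(seed)) set.seed(seed)
  truth <- data[[model$response]]
  mse_base <- mean((predict_rs(model, data) - truth)^2)
  inc <- vapply(model$predictors, function(v) {
    perm <- data
    perm[[v]] <- sample(perm[[v]])
    mse_v <- mean((predict_rs(model, perm) - truth)^2)
    if (mse_base == 0) mse_v - mse_base else
      100 * (mse_v - mse_base) / mse_base
  }, numeric(1))
  tibble::tibble(
    predictor = model$predictors,
    inc_mse_pct = unname(inc),
    rank = rank(-inc, ties.method = "first"),
    absolute_scale = mse_base == 0
  )
}

#' Cross-validated risk-group prediction
#'
#' Repeats, `n_rounds` times: split the cohort 50/50 at random
#' (training half gets the extra record when n is odd), fit the
#' regression forest on the training half, predict Recurrence Scores
#' for the held-out half, convert predicted and actual scores to risk
#' groups, and evaluate the low-versus-high confusion summary
#' ([confusion_summary()]) together with one round of permutation
#' importance on the held-out half. Rounds whose evaluation is empty
#' (no low/high pairs survive the intermediate exclusion) are recorded
#' and excluded from aggregates; metrics undefined in a round (zero
#' denominator) are excluded from that metric's mean and sd only.
#'
#' @param data Complete-case cohort.
#' @param predictors Predictor column names.
#' @param params A [forest_params()] bundle.
#' @param n_rounds Number of cross-validation rounds.
#' @param train_frac Fraction of records in the training half.
#' @param seed Master seed; every per-round split, forest and
#'   permutation derives from it, so identical seeds give identical
#'   reports.
#' @param response Response column.
#' @return An object of class `ki67_cv`: `rounds` (per-round metrics),
#'   `metrics` (mean, sd, n_defined per metric), `importance`
#'   (per-predictor mean, sd, rank, and how often ranked first),
#'   `importance_rounds`, `n_rounds`, `n_empty_rounds`, `settings`.
#' @export
cross_validate <- function(data, predictors, params = forest_params(),
                           n_rounds = 1000, train_frac = 0.5, seed = 1,
                           response = "rs") {
  stopifnot(n_rounds >= 1, train_frac > 0, train_frac < 1)
  check_complete(data, c(predictors, response))
  n <- nrow(data)
  n_train <- ceiling(n * train_frac)
  if (n - n_train < 2L) stop("cohort too small to split", call. = FALSE)
  if (n_train < params$sampsize) {
    stop(sprintf(
      "training half (%d) smaller than sampsize (%d); use a smaller sampsize",
      n_train, params$sampsize), call. = FALSE)
  }
  set.seed(seed)
  round_seeds <- sample.int(.Machine$integer.max, 3L * n_rounds)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  rounds <- vector("list", n_rounds)
  imp_rounds <- vector("list", n_rounds)
  for (i in seq_len(n_rounds)) {
    s <- round_seeds[(3L * (i - 1L) + 1L):(3L * i)]
    set.seed(s[1])
    train_idx <- sample.int(n, n_train)
    train <- data[train_idx, , drop = FALSE]
    test <- data[-train_idx, , drop = FALSE]
    model <- fit_forest(train, predictors, params, response, seed = s[2])
    prs <- predict_rs(model, test)
    eval_df <- tibble::tibble(predicted = assign_risk_group(prs),
                              actual = assign_risk_group(test[[response]]))
    cs <- tryCatch(
      confusion_summary(eval_df, .data$predicted, .data$actual),
      error = function(e) NULL
    )
    if (is.null(cs)) {
      rounds[[i]] <- tibble::tibble(
        round = i, TP = NA_integer_, TN = NA_integer_, FP = NA_integer_,
        FN = NA_integer_, accuracy = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
        n_excluded_intermediate = NA_integer_, empty_round = TRUE
      )
    } else {
      rounds[[i]] <- dplyr::mutate(
        dplyr::select(cs, -"undefined_metrics"),
        round = i, empty_round = FALSE, .before = 1
      )
    }
    imp_rounds[[i]] <- dplyr::mutate(
      permutation_importance(model, test, seed = s[3]),
      round = i, .before = 1
    )
  }
  rounds <- dplyr::bind_rows(rounds)
  imp_rounds <- dplyr::bind_rows(imp_rounds)
  metrics <- rounds |>
    dplyr::filter(!.data$empty_round) |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(metric = factor(.data$metric, levels = metric_names)) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_defined = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  importance <- imp_rounds |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(
      mean_inc_mse_pct = mean(.data$inc_mse_pct),
      sd_inc_mse_pct = stats::sd(.data$inc_mse_pct),
      frac_ranked_first = mean(.data$rank == 1L),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_inc_mse_pct)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(
    rounds = rounds, metrics = metrics, importance = importance,
    importance_rounds = imp_rounds,
    n_rounds = n_rounds, n_empty_rounds = sum(rounds$empty_round),
    settings = list(predictors = predictors, params = unclass(params),
                    n_rounds = n_rounds, train_frac = train_frac,
                    seed = seed, n = n, n_train = n_train,
                    response = response)
  ), class = "ki67_cv")
}

#' @export
print.ki67_cv <- function(x, ...) {
  cat(sprintf("<ki67_cv> %d rounds (%d empty), n = %d, %d predictors\n",
              x$n_rounds, x$n_empty_rounds, x$settings$n,
              length(x$settings$predictors)))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %5.1f +/- %.1f  (defined in %d rounds)\n",
                m$metric[i], m$mean[i], m$sd[i], m$n_defined[i]))
  }
  top <- x$importance$predictor[1]
  cat(sprintf("  top variable by %%IncMSE: %s (%.1f%%)\n",
              top, x$importance$mean_inc_mse_pct[1]))
  invisible(x)
}

#' Tidiers for cross-validation reports
#'
#' `tidy()` returns the per-round confusion metrics; `glance()` a
#' one-row summary with `<metric>_mean` / `<metric>_sd` columns.
#'
#' @param x A `ki67_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ki67_cv
#' @export
tidy.ki67_cv <- function(x, ...) x$rounds

#' @rdname tidy.ki67_cv
#' @method glance ki67_cv
#' @export
glance.ki67_cv <- function(x, ...) {
  wide <- x$metrics |>
    tidyr::pivot_wider(id_cols = NULL,
                       names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  dplyr::mutate(wide, n_rounds = x$n_rounds,
                n_empty_rounds = x$n_empty_rounds,
                top_predictor = x$importance$predictor[1])
}
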