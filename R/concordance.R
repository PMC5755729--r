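check_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 pairs are required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("all values must be finite", call. = FALSE)
  }
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation between two paired measurement series,
#' with the two-tailed p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param data Data frame holding the paired series.
#' @param x,y Unquoted column names.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  check_pairs(xv, yv)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(xv))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, penalizing departures from
#' the identity line as well as loss of correlation:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. `|CCC| <= |r|` always, with equality
#' only when the two series share mean and variance; a pure location
#' shift leaves Pearson's r at 1 but pulls the CCC below 1.
#'
#' @inheritParams pearson_r
#' @return One-row tibble: `ccc`, `n`.
#' @export
lins_ccc <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  check_pairs(xv, yv)
  n <- length(xv)
  mx <- mean(xv); my <- mean(yv)
  sx2 <- mean((xv - mx)^2)
  sy2 <- mean((yv - my)^2)
  sxy <- mean((xv - mx) * (yv - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop("concordance undefined: both series constant and equal", call. = FALSE)
  }
  tibble::tibble(ccc = 2 * sxy / denom, n = n)
}

#' Agreement summary for two paired series
#'
#' Convenience wrapper returning Pearson's r, its two-tailed p-value,
#' and Lin's concordance correlation coefficient in one row.
#'
#' @inheritParams pearson_r
#' @return One-row tibble: `r`, `p_value`, `ccc`, `n`.
#' @export
concordance <- function(data, x, y) {
  dplyr::bind_cols(
    pearson_r(data, {{ x }}, {{ y }}),
    dplyr::select(lins_ccc(data, {{ x }}, {{ y }}), "ccc")
  )[, c("r", "p_value", "ccc", "n")]
}

#' Assign Oncotype DX risk-of-recurrence groups
#'
#' Recurrence Scores (0-100) map to the standard groups: low (< 18),
#' intermediate (18-30), high (>= 31). Non-integer scores falling in
#' the open interval (30, 31) are assigned to the intermediate group,
#' so the three groups partition the whole range.
#'
#' @param rs Numeric vector of Recurrence Scores in `[0, 100]`.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
assign_risk_group <- function(rs) {
  if (any(!is.finite(rs)) || any(rs < 0 | rs > 100)) {
    stop("Recurrence Scores must lie in [0, 100]", call. = FALSE)
  }
  out <- ifelse(rs < 18, "low", ifelse(rs < 31, "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Confusion summary for risk-group prediction
#'
#' Tallies predicted against actual risk groups using the conventions
#' of low-versus-high evaluation: a correct low-risk call is a true
#' positive, a correct high-risk call a true negative, calling a
#' high-risk patient low is a false positive, and calling a low-risk
#' patient high is a false negative. Pairs where either the actual or
#' the predicted group is intermediate are excluded before tallying.
#' Metrics with a zero denominator are reported as `NA` and named in
#' the `undefined_metrics` column, never silently zeroed.
#'
#' @param data Data frame with predicted and actual groups (factors or
#'   strings with levels low/intermediate/high, or numeric Recurrence
#'   Scores which are converted via [assign_risk_group()]).
#' @param predicted,actual Unquoted column names.
#' @return One-row tibble: `TP`, `TN`, `FP`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percent),
#'   `n_excluded_intermediate`, `undefined_metrics`.
#' @export
confusion_summary <- function(data, predicted, actual) {
  pv <- dplyr::pull(data, {{ predicted }})
  av <- dplyr::pull(data, {{ actual }})
  if (length(pv) != length(av)) stop("unequal lengths", call. = FALSE)
  as_group <- function(v) {
    if (is.numeric(v)) return(assign_risk_group(v))
    v <- as.character(v)
    bad <- !v %in% c("low", "intermediate", "high")
    if (any(bad)) stop("unknown risk-group label(s): ",
                       paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    factor(v, levels = c("low", "intermediate", "high"))
  }
  pv <- as_group(pv); av <- as_group(av)
  excl <- pv == "intermediate" | av == "intermediate"
  p <- pv[!excl]; a <- av[!excl]
  if (length(p) == 0L) {
    stop("no pairs left to evaluate after excluding intermediate risk",
         call. = FALSE)
  }
  tp <- sum(a == "low" & p == "low")
  tn <- sum(a == "high" & p == "high")
  fp <- sum(a == "high" & p == "low")
  fn <- sum(a == "low" & p == "high")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble::tibble(
    TP = tp, TN = tn, FP = fp, FN = fn,
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    n_excluded_intermediate = sum(excl)
  )
  metr <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  out$undefined_metrics <- paste(metr[vapply(out[metr], is.na, logical(1))],
                                 collapse = ",")
  out
}

# round half away from zero, the convention used for reported percentages
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage summary of a cohort characteristics table
#'
#' Computes `100 * count / total` per category, reported to one decimal
#' with halves rounded away from zero (the convention of printed
#' clinico-pathological tables).
#'
#' @param data Data frame of per-category counts.
#' @param count Unquoted column of counts.
#' @param total Category total; defaults to the sum of counts.
#' @return `data` with a `percent` column added.
#' @export
cohort_summary <- function(data, count, total = NULL) {
  cv <- dplyr::pull(data, {{ count }})
  if (any(cv < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- if (is.null(total)) sum(cv) else total
  if (length(tot) != 1L || tot <= 0) {
    stop("`total` must be a single positive count", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                percent = round_half_away(100 * {{ count }} / tot, 1))
}
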