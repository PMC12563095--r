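#' Paired experimental/predicted series
#'
#' Container for paired reference (experimental) and predicted values.
#' Pairs with either side missing are excluded and counted.
#'
#' @param y_exp numeric vector of experimental/reference values.
#' @param y_pred numeric vector of predicted values, same length.
#' @param labels optional compound ids.
#' @return object of class `paired_series`: list with `labels`, `y_exp`,
#'   `y_pred` (complete pairs only), `n`, `n_excluded`.
#' @export
paired_series <- function(y_exp, y_pred, labels = NULL) {
  y_exp <- as.numeric(y_exp); y_pred <- as.numeric(y_pred)
  if (length(y_exp) != length(y_pred))
    stop("y_exp and y_pred must have equal length")
  if (is.null(labels)) labels <- as.character(seq_along(y_exp))
  keep <- !is.na(y_exp) & !is.na(y_pred)
  structure(list(labels = labels[keep], y_exp = y_exp[keep],
                 y_pred = y_pred[keep], n = sum(keep),
                 n_excluded = sum(!keep)),
            class = "paired_series")
}

#' Paired regression evaluation metrics
#'
#' Error and agreement metrics between predicted and experimental values:
#' \deqn{RMSE = \sqrt{\frac{1}{N}\sum_i (y_i - \hat y_i)^2}, \quad
#'       MAE = \frac{1}{N}\sum_i |y_i - \hat y_i|}
#' together with the coefficient of determination
#' \eqn{R^2 = 1 - \sum (y_i-\hat y_i)^2 / \sum (y_i-\bar y)^2} (which can
#' be negative and is distinct from the squared Pearson correlation, also
#' reported), and the baseline RMSE of the mean-only predictor
#' \eqn{RMSE_{baseline} = \sqrt{\frac{1}{N}\sum_i (y_i-\bar y)^2}}.  The
#' improvement fraction is `1 - rmse/rmse_baseline`.
#'
#' @param series a [paired_series()] (or anything [paired_series()]
#'   accepts via `y_exp`/`y_pred`).
#' @param y_pred optional; when given, `series` is taken as `y_exp`.
#' @param divisor `"n"` (as defined above, default) or `"n-1"` (the
#'   sample-variance variant some statistics packages use).
#' @return object of class `regression_metrics`: list with `n`,
#'   `n_excluded`, `rmse`, `mae`, `r2`, `pearson_r`, `rmse_baseline`,
#'   `improvement_fraction`.
#' @examples
#' t11 <- load_fixture("table11_fda_descriptors")
#' paired_metrics(paired_series(t11$mw_exp, t11$mw_pred))$rmse  # 0.230
#' @export
paired_metrics <- function(series, y_pred = NULL, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (!inherits(series, "paired_series"))
    series <- paired_series(series, y_pred)
  if (series$n < 2L) stop("need at least 2 complete pairs, have ", series$n)
  e <- series$y_exp - series$y_pred
  nn <- if (divisor == "n") series$n else series$n - 1L
  rmse <- sqrt(sum(e^2) / nn)
  mae <- sum(abs(e)) / series$n
  dev <- series$y_exp - mean(series$y_exp)
  rmse_base <- sqrt(sum(dev^2) / nn)
  r2 <- if (sum(dev^2) > 0) 1 - sum(e^2) / sum(dev^2) else NA_real_
  r <- if (sd(series$y_exp) > 0 && sd(series$y_pred) > 0)
    cor(series$y_exp, series$y_pred) else NA_real_
  impr <- if (rmse_base > 0) 1 - rmse / rmse_base else NA_real_
  structure(list(n = series$n, n_excluded = series$n_excluded, rmse = rmse,
                 mae = mae, r2 = r2, pearson_r = r,
                 rmse_baseline = rmse_base, improvement_fraction = impr),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat("<regression_metrics> n =", x$n,
      if (x$n_excluded) paste0("(", x$n_excluded, " pairs excluded)"), "\n")
  cat(sprintf("  RMSE %.3f  MAE %.3f  r %.3f  R2 %.3f\n",
              x$rmse, x$mae, x$pearson_r, x$r2))
  cat(sprintf("  baseline RMSE %.3f  improvement %.2f%%\n",
              x$rmse_baseline, 100 * x$improvement_fraction))
  invisible(x)
}

#' Ordinary least-squares fit with coefficient confidence intervals
#'
#' Simple linear regression between the experimental and predicted sides
#' of a paired series, with 95% coefficient confidence intervals from the
#' t distribution on n-2 degrees of freedom.  The regression direction is
#' selectable: the validation study regressed reference-on-predicted for
#' MW/TPSA/MR but predicted-on-experimental for LogP.
#'
#' @param series a [paired_series()].
#' @param direction `"exp_on_pred"` (reference values as dependent
#'   variable, default) or `"pred_on_exp"`.
#' @param level confidence level (default 0.95).
#' @return object of class `regression_report`: list with `direction`,
#'   `n`, `slope`, `intercept`, `ci_slope`, `ci_intercept`, `pearson_r`,
#'   `r_squared` (the squared correlation), and the [paired_metrics()]
#'   fields `rmse`, `mae`, `rmse_baseline`, `improvement_fraction`.
#' @examples
#' t11 <- load_fixture("table11_fda_descriptors")
#' linear_fit(paired_series(t11$tpsa_exp, t11$tpsa_pred))$slope  # 1.012
#' @export
linear_fit <- function(series, direction = c("exp_on_pred", "pred_on_exp"),
                       level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(inherits(series, "paired_series"))
  if (series$n < 3L) stop("need at least 3 complete pairs, have ", series$n)
  if (direction == "exp_on_pred") {
    y <- series$y_exp; x <- series$y_pred
  } else {
    y <- series$y_pred; x <- series$y_exp
  }
  if (sd(x) == 0) stop("degenerate regressor: zero variance")
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, level = level))
  m <- paired_metrics(series)
  structure(list(direction = direction, n = series$n,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 ci_slope = unname(ci[2L, ]), ci_intercept = unname(ci[1L, ]),
                 pearson_r = cor(x, y), r_squared = cor(x, y)^2,
                 rmse = m$rmse, mae = m$mae,
                 rmse_baseline = m$rmse_baseline,
                 improvement_fraction = m$improvement_fraction,
                 fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report> n =", x$n, " (", x$direction, ")\n")
  cat(sprintf("  y = %.3f x + %.3f   [slope CI %.3f, %.3f]\n",
              x$slope, x$intercept, x$ci_slope[1], x$ci_slope[2]))
  cat(sprintf("  r %.3f  R2 %.3f  RMSE %.3f  MAE %.3f\n",
              x$pearson_r, x$r_squared, x$rmse, x$mae))
  invisible(x)
}

#' Confusion-matrix classification metrics
#'
#' Tallies predicted against experimental categorical calls after
#' collapsing to a binary positive-vs-rest problem, excluding rows whose
#' experimental value is missing, and reports
#' \deqn{SE = \frac{TP}{TP+FN}, \quad SP = \frac{TN}{TN+FP}, \quad
#'       ACC = \frac{TP+TN}{TP+TN+FP+FN}.}
#'
#' @param exp character vector of experimental calls (`NA` = no
#'   experimental data; the row is excluded and counted).
#' @param pred character vector of predicted calls, same length, no `NA`
#'   among retained rows.
#' @param positive_label the category treated as positive (e.g. `"high"`
#'   for bioavailability/PPB, `"positive"` for Ames, `"active"` for
#'   hERG).
#' @return object of class `classification_report`: list with `tp`, `fp`,
#'   `tn`, `fn`, `se`, `sp`, `acc`, `n`, `n_excluded`.  When the positive
#'   class is absent from the experimental data, `se` is `NA` (not 0/0);
#'   likewise `sp` when the negative class is absent.
#' @examples
#' t14 <- load_fixture("table14_admet_expvspred")
#' confusion(t14$herg_exp, t14$herg_pred, "positive")$se  # 0.833
#' @export
confusion <- function(exp, pred, positive_label) {
  exp <- clean_cell(exp); pred <- clean_cell(pred)
  if (length(exp) != length(pred)) stop("exp and pred must have equal length")
  keep <- !is.na(exp)
  n_excluded <- sum(!keep)
  exp <- exp[keep]; pred <- pred[keep]
  if (length(exp) == 0L) stop("no rows with experimental data")
  if (anyNA(pred)) stop("missing predicted call among retained rows")
  ep <- exp == positive_label
  pp <- pred == positive_label
  tp <- sum(ep & pp); fn <- sum(ep & !pp)
  tn <- sum(!ep & !pp); fp <- sum(!ep & pp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 acc = (tp + tn) / length(exp),
                 n = length(exp), n_excluded = n_excluded),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> n =", x$n,
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded, no exp. data)"),
      "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  SE %.3f  SP %.3f  ACC %.3f\n", x$se, x$sp, x$acc))
  invisible(x)
}
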