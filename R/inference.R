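#' Confidence interval of a descriptor mean
#'
#' Student-t confidence interval for the population mean of a molecular
#' descriptor: `mean +/- t(1-alpha/2, n-1) * s / sqrt(n)` with the
#' sample (n-1) standard deviation.
#'
#' @param values numeric vector (missing values dropped).
#' @param alpha significance level; default 0.05 for a 95% interval.
#' @param name optional descriptor name carried in the report.
#' @return object of class `ci_report`: list with `name`, `n`, `mean`,
#'   `lower`, `upper`, `alpha`.
#' @examples
#' mean_ci(c(1, 2, 3))  # 2 +/- 4.303/sqrt(3)
#' @export
mean_ci <- function(values, alpha = 0.05, name = NULL) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values, have ", n)
  m <- mean(values)
  half <- qt(1 - alpha / 2, df = n - 1) * sd(values) / sqrt(n)
  structure(list(name = name, n = n, mean = m, lower = m - half,
                 upper = m + half, alpha = alpha),
            class = "ci_report")
}

#' @export
print.ci_report <- function(x, ...) {
  cat(sprintf("<ci_report>%s n = %d: mean %.3f, %d%% CI [%.3f, %.3f]\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "", x$n,
              x$mean, round(100 * (1 - x$alpha)), x$lower, x$upper))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Two-sided t test for equality of means without assuming equal
#' variances (Welch-Satterthwaite fractional degrees of freedom), with
#' the 95% confidence interval of the mean difference.  When both
#' samples are constant and equal the test is degenerate; by convention
#' t = 0 and p = 1 are reported.
#'
#' @param a,b numeric vectors (missing values dropped), each of length
#'   two or more.
#' @return object of class `ttest_report`: list with `t`, `df`,
#'   `p_two_sided`, `mean_difference` (mean(a) - mean(b)),
#'   `se_difference`, `ci_difference`.
#' @export
welch_ttest <- function(a, b) {
  a <- as.numeric(a)[!is.na(a)]; b <- as.numeric(b)[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = length(a) + length(b) - 2,
                            p_two_sided = 1,
                            mean_difference = 0, se_difference = 0,
                            ci_difference = c(0, 0)),
                       class = "ttest_report"))
    stop("both samples constant with different means: t undefined")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_two_sided = ht$p.value,
                 mean_difference = unname(diff(rev(ht$estimate))),
                 se_difference = unname(ht$stderr),
                 ci_difference = unname(ht$conf.int)),
            class = "ttest_report")
}

#' @export
print.ttest_report <- function(x, ...) {
  cat(sprintf("<ttest_report> t = %.3f, df = %.3f, p = %.4g\n",
              x$t, x$df, x$p_two_sided))
  cat(sprintf("  mean difference %.3f (SE %.3f), 95%% CI [%.3f, %.3f]\n",
              x$mean_difference, x$se_difference,
              x$ci_difference[1], x$ci_difference[2]))
  invisible(x)
}

# asymptotic Kolmogorov distribution tail: P(sqrt(n_eff) D > t)
kolmogorov_p <- function(t) {
  if (t < 1e-10) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Signed suprema of the difference between the two empirical CDFs
#' (`d_plus` = sup of ECDF(a) - ECDF(b), `d_minus` = inf) and their
#' absolute maximum D, with the asymptotic two-sided p value from the
#' Kolmogorov distribution at effective sample size
#' `n_eff = n_a n_b / (n_a + n_b)`, clipped to \[0, 1\].  D is invariant
#' under any strictly increasing transform applied to both samples.
#'
#' @param a,b numeric vectors (missing values dropped), each non-empty.
#' @return object of class `ks_report`: list with `d_abs`, `d_plus`,
#'   `d_minus`, `p_two_sided`, `n_a`, `n_b`.
#' @examples
#' ks_2sample(1:10, 1:10)$d_abs  # 0
#' @export
ks_2sample <- function(a, b) {
  a <- sort(as.numeric(a)[!is.na(a)]); b <- sort(as.numeric(b)[!is.na(b)])
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  d_plus <- max(c(fa - fb, 0))
  d_minus <- min(c(fa - fb, 0))
  d_abs <- max(d_plus, abs(d_minus))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  structure(list(d_abs = d_abs, d_plus = d_plus, d_minus = d_minus,
                 p_two_sided = kolmogorov_p(sqrt(n_eff) * d_abs),
                 n_a = length(a), n_b = length(b)),
            class = "ks_report")
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("<ks_report> D = %.3f (D+ %.3f, D- %.3f), p = %.4g\n",
              x$d_abs, x$d_plus, x$d_minus, x$p_two_sided))
  invisible(x)
}
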