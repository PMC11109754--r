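# Correlation, risk standardisation and risk trade-off statistics.

#' Pearson correlation with linear regression
#'
#' Pearson correlation coefficient with its two-sided p-value from the
#' t transform on n - 2 degrees of freedom, the coefficient of
#' determination (identically r^2 for a simple linear regression), and
#' the least-squares regression line of `y` on `x`.
#'
#' @param x,y Numeric series of equal length, n >= 3, each with nonzero
#'   variance.
#' @return An object of class `correlation_result`: list with `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pearson_with_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("at least 3 observations are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  r2 <- r^2
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(
    list(r = r, r_squared = r2, p_value = p,
         slope = slope, intercept = mean(y) - slope * mean(x), n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (R^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  cat(sprintf("  regression line: y = %.4g + %.4g x\n", x$intercept, x$slope))
  invisible(x)
}

#' Min-max risk standardisation
#'
#' Rescales a risk marker (e.g. peak ACL force or peak ankle inversion
#' angle) to \[0, 1\] over the cohort: the cohort maximum is taken as
#' the maximum likelihood of injury (1) and the minimum as the minimum
#' likelihood (0), i.e. \eqn{(v - \min v) / (\max v - \min v)}.
#'
#' @param values Numeric series with `max > min`.
#' @return Standardised series in \[0, 1\].
#' @export
standardize_risk <- function(values) {
  rng <- range(values)
  if (!all(is.finite(rng)) || rng[2] <= rng[1]) {
    stop("degenerate range: risk standardisation needs max > min", call. = FALSE)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Intersection of two fitted risk lines
#'
#' Fits each standardised risk linearly on the predictor and solves for
#' the predictor value where the two fitted lines cross.  With an
#' ACL-risk line decreasing in the predictor and a sprain-risk line
#' increasing, the crossing marks the trade-off point between the two
#' risks.
#'
#' @param predictor Predictor values (e.g. AICA or AROM, deg).
#' @param risk_acl,risk_las Standardised risk series (same length as
#'   `predictor`).
#' @return An object of class `risk_intersection`: list with `crossing`
#'   (predictor value), `line_acl` and `line_las`
#'   (`c(intercept, slope)`), and `extrapolated` (TRUE when the
#'   crossing falls outside the observed predictor range).
#' @export
risk_intersection <- function(predictor, risk_acl, risk_las) {
  f1 <- pearson_with_regression(predictor, risk_acl)
  f2 <- pearson_with_regression(predictor, risk_las)
  dslope <- f1$slope - f2$slope
  scale <- max(abs(f1$slope), abs(f2$slope), 1e-12)
  if (abs(dslope) < 1e-10 * scale) {
    stop("fitted risk lines are parallel: no intersection", call. = FALSE)
  }
  crossing <- (f2$intercept - f1$intercept) / dslope
  structure(
    list(crossing = crossing,
         line_acl = c(intercept = f1$intercept, slope = f1$slope),
         line_las = c(intercept = f2$intercept, slope = f2$slope),
         extrapolated = crossing < min(predictor) || crossing > max(predictor)),
    class = "risk_intersection"
  )
}

#' @export
print.risk_intersection <- function(x, ...) {
  cat(sprintf("<risk_intersection> crossing at predictor = %.2f%s\n",
              x$crossing, if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Balanced-risk predictor interval
#'
#' Interval of predictor values around the risk crossing on which the
#' two fitted standardised risks differ by at most `tolerance`:
#' crossing +/- tolerance / |slope difference|.  The default tolerance
#' 0.25 (a quarter of the standardised risk scale) yields bands of
#' roughly 10 degrees for ankle initial contact angle and 20 degrees for
#' ankle range of motion on cohorts with the calibrated summary
#' statistics.
#'
#' @inheritParams risk_intersection
#' @param tolerance Maximum admissible absolute difference between the
#'   standardised risks (default 0.25).
#' @return An object of class `balanced_range`: list with `lower`,
#'   `upper`, `crossing` and `tolerance`.
#' @export
balanced_range <- function(predictor, risk_acl, risk_las, tolerance = 0.25) {
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  inter <- risk_intersection(predictor, risk_acl, risk_las)
  dslope <- abs(inter$line_acl["slope"] - inter$line_las["slope"])
  half <- tolerance / dslope
  structure(
    list(lower = unname(inter$crossing - half),
         upper = unname(inter$crossing + half),
         crossing = inter$crossing, tolerance = tolerance),
    class = "balanced_range"
  )
}

#' @export
print.balanced_range <- function(x, ...) {
  cat(sprintf("<balanced_range> [%.2f, %.2f] about crossing %.2f (tol %.2f)\n",
              x$lower, x$upper, x$crossing, x$tolerance))
  invisible(x)
}

#' Cohort correlation table
#'
#' Summarises a cohort of subject-level summaries: mean and SD of each
#' variable plus Pearson r, R^2 and p against the two ankle motion
#' pattern variables (AICA and AROM).  Zero-variance variables are kept
#' in the table with `NA` correlations and flagged through the
#' `degenerate` column.
#'
#' @param summaries A data frame of subject-level (typically
#'   within-subject trial-mean) summary variables; must contain `AICA`
#'   and `AROM` columns.
#' @param variables Variables to tabulate; defaults to every column
#'   except `AICA`/`AROM` and any `subject` id column.
#' @return A data frame with one row per variable.
#' @export
cohort_correlation_table <- function(summaries, variables = NULL) {
  if (!all(c("AICA", "AROM") %in% names(summaries))) {
    stop("summaries must contain AICA and AROM columns", call. = FALSE)
  }
  if (nrow(summaries) < 3L) {
    stop("at least 3 subjects are required", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(summaries), c("subject", "trial", "AICA", "AROM"))
  }
  one <- function(v) {
    x <- summaries[[v]]
    degen <- stats::sd(x) == 0 || stats::sd(summaries$AICA) == 0 ||
      stats::sd(summaries$AROM) == 0
    if (degen) {
      return(data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
                        r_AICA = NA_real_, r2_AICA = NA_real_, p_AICA = NA_real_,
                        r_AROM = NA_real_, r2_AROM = NA_real_, p_AROM = NA_real_,
                        degenerate = TRUE))
    }
    ca <- pearson_with_regression(summaries$AICA, x)
    cr <- pearson_with_regression(summaries$AROM, x)
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               r_AICA = ca$r, r2_AICA = ca$r_squared, p_AICA = ca$p_value,
               r_AROM = cr$r, r2_AROM = cr$r_squared, p_AROM = cr$p_value,
               degenerate = FALSE)
  }
  out <- do.call(rbind, lapply(variables, one))
  rownames(out) <- NULL
  out
}
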