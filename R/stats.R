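# Cohort-level statistics: descriptives, subgroup comparisons, Pearson
# correlation, multivariate regression with partial correlations, ICC and
# Bland-Altman agreement. Standard fits go through base R (lm, t.test,
# chisq.test, cor.test); the derived quantities (partial r, ICC variant,
# limits of agreement) are computed here.

# internal: pull a column, complete cases only
.get_var <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stop("no such variable: ", variable)
  x <- cohort[[variable]]
  x[!is.na(x)]
}

#' Descriptive summary of one cohort variable
#'
#' Reports mean with sample SD (\eqn{n-1} denominator) and median with
#' interquartile range (25th/75th percentiles).
#'
#' @param cohort data frame with one row per patient.
#' @param variable column name of a numeric variable.
#' @return Named list: `mean`, `sd`, `median`, `iqr_low`, `iqr_high`, `n`.
#' @export
cohort_describe <- function(cohort, variable) {
  x <- .get_var(cohort, variable)
  if (!is.numeric(x)) stop("'", variable, "' is not numeric")
  if (length(x) < 2) stop("need at least 2 non-missing values")
  q <- unname(quantile(x, c(0.25, 0.75)))
  list(mean = mean(x), sd = sd(x), median = median(x),
       iqr_low = q[1], iqr_high = q[2], n = length(x))
}

#' Compare a variable between two patient groups
#'
#' Continuous variables are compared with the two-sample pooled-variance
#' t test; categorical (logical/factor/character) variables with the
#' chi-squared test on the 2 x 2 table (no continuity correction unless
#' requested).
#'
#' @param cohort data frame.
#' @param variable column to compare.
#' @param group column defining the two groups (e.g. disease subtype).
#' @param correct apply Yates continuity correction to the chi-squared
#'   test.
#' @return Named list: `statistic`, `p_value`, `test` (`"t"` or `"chi2"`),
#'   `n`.
#' @export
compare_groups <- function(cohort, variable, group = "subtype",
                           correct = FALSE) {
  if (!group %in% names(cohort)) stop("no such variable: ", group)
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2) stop("'", group, "' must define exactly two groups")
  x <- cohort[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) != 2 || any(table(g) == 0)) stop("both groups must be non-empty")
  if (is.numeric(x)) {
    if (sd(x[g == levels(g)[1]]) == 0 && sd(x[g == levels(g)[2]]) == 0)
      stop("zero variance in both groups")
    tt <- t.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         test = "t", n = length(x))
  } else {
    tab <- table(factor(x), g)
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         test = "chi2", n = length(x))
  }
}

#' Pearson product-moment correlation
#'
#' @param cohort data frame.
#' @param x,y column names of numeric variables.
#' @return Named list: `r`, `n` (complete pairs), `p_two_sided` (from the
#'   t transform with `n - 2` degrees of freedom).
#' @export
cohort_pearson <- function(cohort, x, y) {
  xv <- cohort[[x]]; yv <- cohort[[y]]
  if (is.null(xv) || is.null(yv)) stop("no such variable")
  ok <- !is.na(xv) & !is.na(yv)
  xv <- as.numeric(xv[ok]); yv <- as.numeric(yv[ok])
  if (length(xv) < 3) stop("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) stop("zero variance")
  ct <- cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), n = length(xv), p_two_sided = ct$p.value)
}

#' Multivariate linear regression with partial correlations
#'
#' Ordinary least squares with intercept. For each covariate the partial
#' correlation with the outcome, adjusted for all other covariates, is
#' derived from its t statistic: \eqn{r_{partial} = t / \sqrt{t^2 + df}}
#' with \eqn{df = n - k - 1}, carrying the sign of \eqn{t}.
#'
#' @param cohort data frame; logical and two-level factor covariates are
#'   coded 0/1.
#' @param outcome column name of the dependent variable.
#' @param covariates character vector of covariate column names.
#' @return A `fibro_regression`: `coefficients` data frame (`name`,
#'   `coefficient`, `std_error`, `t`, `r_partial`, `p`) and `model` list
#'   (`r_multiple`, `r2_adjusted`, `n`, `k`, `df`).
#' @details Rank-deficient designs are refused with an error naming the
#'   collinear columns, mirroring how a collinear covariate (e.g. a visual
#'   analogue dyspnea scale duplicating the Borg score) must be excluded
#'   by the analyst rather than dropped silently.
#' @export
fit_multivariate <- function(cohort, outcome, covariates) {
  cols <- c(outcome, covariates)
  miss <- setdiff(cols, names(cohort))
  if (length(miss) > 0) stop("no such variable: ", paste(miss, collapse = ", "))
  d <- cohort[cols]
  for (nm in names(d)) {
    v <- d[[nm]]
    if (is.logical(v)) d[[nm]] <- as.numeric(v)
    else if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(v) != 2) stop("'", nm, "' must be numeric or two-level")
      d[[nm]] <- as.numeric(v == levels(v)[2])
    }
  }
  d <- d[complete.cases(d), ]
  n <- nrow(d); k <- length(covariates)
  if (n <= k + 1) stop("need n > k + 1 observations")

  X <- as.matrix(cbind(`(Intercept)` = 1, d[covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(aliased, collapse = ", "))
  }

  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  df <- n - k - 1
  ctab <- sm$coefficients[-1, , drop = FALSE]
  tval <- ctab[, "t value"]
  res <- data.frame(name = covariates,
                    coefficient = unname(ctab[, "Estimate"]),
                    std_error = unname(ctab[, "Std. Error"]),
                    t = unname(tval),
                    r_partial = unname(tval / sqrt(tval^2 + df)),
                    p = unname(ctab[, "Pr(>|t|)"]),
                    row.names = NULL)
  structure(list(coefficients = res,
                 model = list(r_multiple = sqrt(sm$r.squared),
                              r2_adjusted = sm$adj.r.squared,
                              r2 = sm$r.squared, n = n, k = k, df = df),
                 fit = fit),
            class = "fibro_regression")
}

#' @export
print.fibro_regression <- function(x, digits = 4, ...) {
  cat(sprintf("<fibro_regression> n = %d, k = %d, multiple R = %.3f, adjusted R2 = %.3f\n",
              x$model$n, x$model$k, x$model$r_multiple, x$model$r2_adjusted))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single
#' measure
#'
#' ICC(2,1) from the two-way ANOVA mean squares of a complete
#' subjects-by-raters grid:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares. When the rater columns are identical and the
#' subjects vary, the ICC is exactly 1.
#'
#' @param measurements numeric matrix, one row per subject, one column per
#'   rater (or repeated measurement); complete, at least 2 x 2.
#' @return An `agreement_result` with field `icc` (its limits-of-agreement
#'   fields are `NA`; see [bland_altman]).
#' @export
icc_absolute_agreement <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(m)) stop("grid must be complete")
  n <- nrow(m); k <- ncol(m)
  if (all(m == m[1, 1])) stop("no between-subject variance")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- sum((m - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
  structure(list(icc = icc, mean_diff = NA_real_,
                 loa_low = NA_real_, loa_high = NA_real_, n = n, k = k),
            class = "agreement_result")
}

#' Bland-Altman 95% limits of agreement
#'
#' @param a,b paired measurement vectors (same length, at least 2 pairs).
#' @return An `agreement_result` with `mean_diff` = mean of `a - b` and
#'   `loa_low`/`loa_high` = `mean_diff` -/+ 1.96 times the SD of the
#'   differences (its `icc` field is `NA`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  md <- mean(d); s <- sd(d)
  structure(list(icc = NA_real_, mean_diff = md,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 n = length(d), k = 2L),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (!is.na(x$icc))
    cat(sprintf("<agreement_result> ICC(2,1) = %.4f over %d subjects x %d raters\n",
                x$icc, x$n, x$k))
  if (!is.na(x$mean_diff))
    cat(sprintf("<agreement_result> mean difference %.4f, 95%% limits of agreement [%.4f, %.4f] (n = %d)\n",
                x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
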