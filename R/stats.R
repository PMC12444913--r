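#' Two-sample t test from summary statistics
#'
#' Classical pooled-variance two-sample t test computed directly from group
#' means, SDs and sizes, so printed "mean +/- SD, n" tables can be tested
#' without raw data. `var_equal = FALSE` gives the Welch form.
#'
#' Degenerate inputs (zero pooled variance) return `t = 0, p = 1` when the
#' means are equal and `p = 0` flagged `degenerate = TRUE` otherwise.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics (`sd >= 0`,
#'   `n >= 2`).
#' @param var_equal pooled (default) or Welch variance.
#' @return A `test_result` list: `statistic, df, p, test, means, sds, ns,
#'   degenerate`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    kind <- "unpaired pooled"
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    kind <- "unpaired welch"
  }
  degenerate <- FALSE
  if (se == 0) {
    if (mean1 == mean2) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean1 - mean2) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(statistic = t, df = df, p = p, test = kind,
                 means = c(mean1, mean2), sds = c(sd1, sd2), ns = c(n1, n2),
                 degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> t = %.4g, df = %.4g, p = %.4g%s%s\n", x$test,
              x$statistic, x$df, x$p,
              if (!is.null(x$p_adj)) sprintf(", p_adj = %.4g", x$p_adj) else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Unpaired two-sample t test (pooled variance, two-tailed)
#'
#' The group-comparison test used throughout: classical pooled two-sample t
#' with `df = n1 + n2 - 2`, operating on subject means.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param var_equal pooled (default) or Welch.
#' @return A `test_result`.
#' @export
t_unpaired <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  t_from_summary(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b), var_equal = var_equal)
}

#' Paired t test
#'
#' One-sample t test on within-subject differences `a - b`.
#'
#' @param a,b numeric samples of equal length `n >= 2`, paired by subject.
#' @return A `test_result`.
#' @export
t_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  degenerate <- FALSE
  if (s == 0) {
    if (all(d == 0)) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  structure(list(statistic = t, df = n - 1, p = p, test = "paired",
                 means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)),
                 ns = c(n, n), degenerate = degenerate),
            class = "test_result")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error correction: sorted p values are multiplied by
#' `m, m-1, ...`, monotonicity is enforced, results capped at 1 and returned
#' in input order.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @export
holm_bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with a
#' two-tailed p value from the large-sample t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric samples, `n >= 3`.
#' @return A `correlation_result` list: `r_s, p, n` (`r_s = NA`, flagged,
#'   for constant input).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("spearman_cor: constant input, correlation undefined")
    return(structure(list(r_s = NA_real_, p = NA_real_, n = n),
                     class = "correlation_result"))
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(r_s = r, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<spearman> r_s = %.4g, p = %.4g, n = %d\n", x$r_s, x$p, x$n))
  invisible(x)
}

#' Normality tests
#'
#' Shapiro-Wilk (Royston approximation, for small samples, `n >= 3`) or a
#' Kolmogorov-Smirnov test against the fitted normal with the Lilliefors
#' correction for estimated parameters (for large samples, `n >= 8`), so the
#' null rejection rate is calibrated at the nominal level.
#'
#' @param x numeric sample.
#' @param method `"SW"` or `"KS"`.
#' @return Two-tailed p value.
#' @export
normality_test <- function(x, method = c("SW", "KS")) {
  method <- match.arg(method)
  if (stats::sd(x) == 0) stop("normality_test: constant sample")
  if (method == "SW") {
    if (length(x) < 3) stop("normality_test: SW needs n >= 3")
    stats::shapiro.test(x)$p.value
  } else {
    if (length(x) < 8) stop("normality_test: KS needs n >= 8")
    nortest::lillie.test(x)$p.value
  }
}

#' Covariate regression of a subject-level measure
#'
#' Ordinary least squares of a per-subject measure on condition, age, gender
#' (binary indicator) and postmortem interval, with t-based coefficient
#' p values -- the check that group differences are not explained by
#' demographics.
#'
#' @param data data.frame with the response and covariate columns.
#' @param response response column name.
#' @param covariates covariate column names (default
#'   `c("condition", "age_years", "gender", "pmi_hours")`).
#' @return data.frame `term, estimate, se, t, p`, with `r_squared` attribute.
#' @export
covariate_regression <- function(data, response,
                                 covariates = c("condition", "age_years",
                                                "gender", "pmi_hours")) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  df <- data
  for (cv in covariates)
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  form <- stats::reformulate(covariates, response)
  X <- stats::model.matrix(form, df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate_regression: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) <= ncol(X))
    stop("covariate_regression: need more subjects than coefficients")
  fit <- stats::lm(form, df)
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p = cf[, 4], row.names = NULL)
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}

#' Percent reduction of a group mean
#'
#' `100 * (mean_control - mean_case) / mean_control`, rounded to the nearest
#' integer percent by default (the convention for reporting, e.g. a "30%
#' lower" somatic intensity).
#'
#' @param mean_control,mean_case group means (`mean_control > 0`).
#' @param round round to nearest integer percent (default `TRUE`).
#' @return Percent reduction.
#' @export
percent_reduction <- function(mean_control, mean_case, round = TRUE) {
  if (mean_control <= 0) stop("percent_reduction: control mean must be > 0")
  pct <- 100 * (mean_control - mean_case) / mean_control
  if (round) round(pct) else pct
}

#' Group comparison of subject-level measures with Holm correction
#'
#' For each measure, compares subject means between the two conditions with
#' the pooled unpaired t test, then applies the Holm-Bonferroni correction
#' within each declared comparison family (measures reported together in one
#' figure form one family; unassigned measures form singleton families).
#'
#' @param summaries subject-level data.frame with columns `subject_id`,
#'   `condition`, and one column per measure.
#' @param measures character vector of measure columns.
#' @param families optional named list mapping family name -> measure names.
#' @param conditions length-2 character vector giving the order (control
#'   first) of conditions.
#' @return data.frame with one row per measure: group means/SDs/ns, `t`,
#'   `df`, `p`, `p_adj`, `family`.
#' @export
compare_groups <- function(summaries, measures, families = NULL,
                           conditions = c("control", "schizophrenia")) {
  stopifnot(all(c("subject_id", "condition") %in% names(summaries)),
            all(measures %in% names(summaries)))
  fam_of <- stats::setNames(measures, measures)
  if (!is.null(families)) {
    for (fn in names(families)) fam_of[families[[fn]]] <- fn
  }
  rows <- lapply(measures, function(m) {
    a <- summaries[[m]][summaries$condition == conditions[1]]
    b <- summaries[[m]][summaries$condition == conditions[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tr <- t_unpaired(a, b)
    data.frame(measure = m, family = fam_of[[m]],
               mean_control = mean(a), sd_control = stats::sd(a),
               n_control = length(a),
               mean_case = mean(b), sd_case = stats::sd(b),
               n_case = length(b),
               t = tr$statistic, df = tr$df, p = tr$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (fn in unique(out$family)) {
    in_fam <- out$family == fn
    out$p_adj[in_fam] <- holm_bonferroni(out$p[in_fam])
  }
  rownames(out) <- NULL
  out
}
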