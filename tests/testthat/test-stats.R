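test_that("pooled t test handles identical samples, degenerate variance, and matches t.test", {
  a <- c(1, 2, 3, 4)
  r <- t_unpaired(a, a)
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)

  # zero variance, unequal means: degenerate flag
  r2 <- t_unpaired(c(5, 5, 5), c(7, 7, 7))
  expect_true(r2$degenerate); expect_equal(r2$p, 0)

  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(8, 10, 2); y <- rnorm(6, 11, 3)
    mine <- t_unpaired(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
    welch <- t_unpaired(x, y, var_equal = FALSE)
    refw <- t.test(x, y)
    expect_equal(welch$p, refw$p.value, tolerance = 1e-12)
  }
})

test_that("t tests are invariant to affine rescaling of both groups", {
  set.seed(52)
  x <- rnorm(7); y <- rnorm(6, 0.5)
  p0 <- t_unpaired(x, y)$p
  expect_equal(t_unpaired(3 * x + 10, 3 * y + 10)$p, p0, tolerance = 1e-12)
})

test_that("summary-statistic t reproduces printed worked examples", {
  # somatic PV intensities: 1,362 +/- 151 (n = 8) vs 955 +/- 265 (n = 6)
  r <- t_from_summary(1362, 151, 8, 955, 265, 6)
  expect_equal(r$df, 12)
  expect_equal(r$p, 0.0033, tolerance = 0.1)
  # Holm over the two somatic PV comparisons doubles the smaller p: ~0.007
  expect_equal(holm_bonferroni(c(r$p, 0.38))[1], 0.007, tolerance = 0.05)

  # GluN1 density on PV dendrites: 1.60 +/- 0.15 (n = 7) vs 1.30 +/- 0.19 (n = 6)
  r2 <- t_from_summary(1.60, 0.15, 7, 1.30, 0.19, 6)
  expect_equal(r2$statistic, 3.18, tolerance = 0.01)
  expect_equal(r2$df, 11)

  expect_equal(t_from_summary(2, 1, 5, 2, 1, 5)$p, 1)

  # agrees with t_unpaired on a moment-matched sample
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 6)
  expect_equal(t_from_summary(mean(x), sd(x), 5, mean(y), sd(y), 3)$p,
               t_unpaired(x, y)$p, tolerance = 1e-12)
})

test_that("paired t matches the one-sample oracle on differences", {
  a <- c(1, 2, 3, 4, 5)
  r <- t_paired(a, a)
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)

  r2 <- t_paired(a, a + 2)
  expect_true(r2$degenerate); expect_equal(r2$p, 0)

  set.seed(53)
  x <- rnorm(10); y <- x + rnorm(10, 0.3, 0.5)
  mine <- t_paired(x, y)
  ref <- t.test(x - y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("Holm step-down matches the hand computation and its invariances", {
  expect_equal(holm_bonferroni(0.02), 0.02)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)),
               oracle_holm(c(0.01, 0.04, 0.03)))
  expect_equal(holm_bonferroni(rep(0.3, 4)), rep(min(4 * 0.3, 1), 4))

  set.seed(54)
  p <- runif(7)
  adj <- holm_bonferroni(p)
  expect_equal(adj, oracle_holm(p))
  expect_true(all(adj >= p))                       # dominates unadjusted
  perm <- sample(7)
  expect_equal(holm_bonferroni(p[perm]), adj[perm])  # permutation-equivariant
})

test_that("Spearman correlation handles monotone data, ties, and monotone-transform invariance", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$r_s, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$r_s, -1)

  set.seed(55)
  a <- sample(1:5, 30, replace = TRUE)   # heavy ties
  b <- a + sample(0:3, 30, replace = TRUE)
  r <- spearman_cor(a, b)
  expect_equal(r$r_s, oracle_spearman(a, b), tolerance = 1e-12)
  expect_equal(r$r_s, unname(cor(a, b, method = "spearman")), tolerance = 1e-12)

  # invariant under strictly monotone transforms
  expect_equal(spearman_cor(exp(a), b)$r_s, r$r_s)

  expect_warning(cc <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(cc$r_s))
})

test_that("normality tests reject non-normal data and enforce sample-size bounds", {
  set.seed(56)
  # exponential data, small n: Shapiro-Wilk power > 80%
  rej <- mean(replicate(100, normality_test(rexp(50), "SW") < 0.05))
  expect_gt(rej, 0.8)

  # null calibration of the Lilliefors-corrected KS at moderate n
  rej_null <- mean(replicate(200, normality_test(rnorm(300), "KS") < 0.05))
  expect_lt(abs(rej_null - 0.05), 0.045)

  expect_error(normality_test(rnorm(5), "KS"), "n >= 8")
  expect_error(normality_test(c(1, 2), "SW"), "n >= 3")
  expect_error(normality_test(rep(2, 20), "SW"), "constant")
})

test_that("covariate regression matches the normal-equations oracle and flags collinearity", {
  set.seed(57)
  n <- 14
  df <- data.frame(condition = rep(c("control", "scz"), each = 7),
                   age_years = runif(n, 55, 85),
                   gender = sample(c("m", "f"), n, replace = TRUE),
                   pmi_hours = rnorm(n, 3.3, 0.7))
  df$y <- 2 + 0.5 * df$age_years + rnorm(n, 0, 0.3)
  fit <- covariate_regression(df, "y")
  X <- model.matrix(~ condition + age_years + gender + pmi_hours,
                    transform(df, condition = factor(condition),
                              gender = factor(gender)))
  expect_equal(fit$estimate, oracle_ols(X, df$y), tolerance = 1e-8)
  expect_lt(fit$p[fit$term == "age_years"], 1e-6)

  # exact linear response: R^2 = 1, age p ~ 0
  df2 <- df; df2$y <- 1 + 2 * df2$age_years
  fit2 <- suppressWarnings(covariate_regression(df2, "y"))  # perfect-fit note
  expect_equal(attr(fit2, "r_squared"), 1)

  # collinear column is named in the error
  df3 <- df; df3$pmi_hours <- df3$age_years * 2
  expect_error(covariate_regression(df3, "y"), "pmi_hours")
})

test_that("covariate-regression p values are calibrated under the null", {
  set.seed(58)
  ps <- replicate(300, {
    n <- 15
    df <- data.frame(condition = rep(c("a", "b"), length.out = n),
                     age_years = runif(n, 55, 85),
                     gender = sample(c("m", "f"), n, replace = TRUE),
                     pmi_hours = rnorm(n, 3.3, 0.7),
                     y = rnorm(n))
    fit <- covariate_regression(df, "y")
    fit$p[fit$term == "age_years"]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("percent reduction reproduces the printed reductions", {
  expect_equal(percent_reduction(1362, 955), 30)
  expect_equal(percent_reduction(1.72, 1.43), 17)
  expect_equal(percent_reduction(5, 5), 0)
  expect_equal(percent_reduction(200, 150, round = FALSE), 25)
  expect_error(percent_reduction(0, 1), "> 0")
})

test_that("group comparison applies Holm within declared families on subject means", {
  set.seed(59)
  sm <- simulate_subject_summaries(
    list(m1 = list(mean_control = 10, sd_control = 1, mean_case = 7, sd_case = 1),
         m2 = list(mean_control = 5, sd_control = 1, mean_case = 5, sd_case = 1),
         m3 = list(mean_control = 3, sd_control = 1, mean_case = 3, sd_case = 1)),
    n_control = 8, n_case = 6, seed = 59)
  res <- compare_groups(sm, c("m1", "m2", "m3"),
                        families = list(fam = c("m1", "m2")))
  expect_equal(res$family, c("fam", "fam", "m3"))
  # within-family Holm equals the hand rule
  fam_p <- res$p[1:2]
  expect_equal(res$p_adj[1:2], oracle_holm(fam_p))
  expect_equal(res$p_adj[3], res$p[3])
  expect_lt(res$p_adj[1], 0.05)
  # group means and ns are faithful
  expect_equal(res$n_control, rep(8L, 3))
  expect_equal(res$mean_control[1],
               mean(sm$m1[sm$condition == "control"]))
})
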