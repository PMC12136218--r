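test_that("Spearman correlation is exactly 1 under a monotone transform", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  tab <- data.frame(x = x, y = 2 * x + 1)
  cm <- correlation_matrix(tab, method = "spearman")
  expect_equal(cm$rho["x", "y"], 1)
  # invariance of the whole matrix under strictly monotone transforms
  tab2 <- data.frame(x = exp(x), y = (2 * x + 1)^3)
  cm2 <- correlation_matrix(tab2, method = "spearman")
  expect_equal(cm2$rho, cm$rho, ignore_attr = TRUE)
})

test_that("correlation cells agree with the reference implementation to 1e-10", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    if (i %% 3 == 0) x <- round(x, 1)  # inject ties
    for (method in c("pearson", "spearman")) {
      cm <- correlation_matrix(data.frame(x = x, y = y), method = method)
      ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
      expect_lt(abs(cm$rho["x", "y"] - unname(ct$estimate)), 1e-10)
      expect_lt(abs(cm$p["x", "y"] - ct$p.value), 1e-10)
    }
  }
})

test_that("correlation matrix is symmetric with unit diagonal and honest n accounting", {
  tab <- generate_cohort(cohort_spec(seed = 2))
  tab$csf_ab42[c(2, 5)] <- NA
  cm <- correlation_matrix(tab)
  expect_identical(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, ncol(cm$rho)))
  expect_equal(unname(cm$n["csf_ab42", "age_years"]), 14)
  # a cell with fewer than 4 complete pairs is missing, not zero
  tab$csf_ab40[1:13] <- NA
  cm2 <- correlation_matrix(tab)
  expect_true(is.na(cm2$rho["csf_ab40", "age_years"]))
})

test_that("independent columns rarely exceed |rho| = 0.05 at n = 5000", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    r <- cor(rank(rnorm(5000)), rank(rnorm(5000)))
    if (abs(r) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("partial correlation routes agree with each other and the matrix-inverse reference", {
  set.seed(66)
  for (i in 1:100) {
    z <- rnorm(16)
    x <- 0.5 * z + rnorm(16)
    y <- -0.3 * z + 0.4 * x + rnorm(16)
    tab <- data.frame(x = x, y = y, z = z)
    pc <- partial_correlation(tab, "x", "y", "z", method = "pearson")
    expect_lt(abs(pc$rho_closed_form - pc$rho_residual), 1e-10)
    expect_lt(abs(pc$rho_partial - ref_partial_inverse(x, y, z)), 1e-10)
    # Spearman mode: same identity on mid-ranks
    ps <- partial_correlation(tab, "x", "y", "z", method = "spearman")
    expect_lt(abs(ps$rho_partial -
                  ref_partial_inverse(rank(x), rank(y), rank(z))), 1e-10)
  }
})

test_that("an irrelevant covariate leaves the marginal correlation intact", {
  set.seed(9)
  n <- 5000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
  tab <- data.frame(x = x, y = y, z = z)
  pc <- partial_correlation(tab, "x", "y", "z", method = "pearson")
  expect_lt(abs(pc$rho_partial - cor(x, y)), 0.02)
})

test_that("degenerate collinearity with the control is an error, not a number", {
  z <- rnorm(16)
  tab <- data.frame(x = z, y = z, z = z)
  expect_error(partial_correlation(tab, "x", "y", "z"), "collinear")
  expect_error(partial_correlation(data.frame(x = 1:3, y = 3:1, z = rnorm(3)),
                                   "x", "y", "z"), "at least 4")
})

test_that("residualization recovers a noiseless linear effect exactly", {
  set.seed(14)
  age <- runif(16, 10, 27)
  metric <- 40 - age + rnorm(16)
  res <- residuals(lm(metric ~ age))
  d <- 0.0031
  tab <- data.frame(age_years = age, m = metric, b = 0.2 + d * res)
  rf <- residualization_fit(tab, "m", "b")
  expect_equal(rf$estimate, d, tolerance = 1e-9)
  expect_lt(rf$p_value, 1e-12)
})

test_that("the residualization t equals the Pearson partial-correlation t", {
  set.seed(15)
  for (i in 1:100) {
    tab <- data.frame(age_years = runif(16, 10, 27))
    tab$m <- 40 - tab$age_years + rnorm(16, 0, 4)
    tab$b <- 0.1 - 0.001 * tab$age_years + 0.002 * tab$m + rnorm(16, 0, 0.01)
    rf <- residualization_fit(tab, "m", "b")
    pc <- partial_correlation(tab, "m", "b", "age_years", method = "pearson")
    expect_lt(abs(rf$t_value - pc$t_value), 1e-8)
    expect_lt(abs(rf$p_value - pc$p_value), 1e-10)
    expect_equal(rf$df, pc$df)
    expect_equal(rf$t_value, rf$estimate / rf$std_error, tolerance = 1e-12)
    # the simple-regression variant differs only through its df convention
    rf2 <- residualization_fit(tab, "m", "b", age_covariate = FALSE)
    expect_equal(rf2$df, 14)
  }
})

test_that("residualization p-values are null-uniform when the effect is absent", {
  ps <- vapply(1:300, function(s) {
    tab <- generate_cohort(cohort_spec(beta_flow_ratio = 0, seed = s))
    residualization_fit(tab, "peak_flow", "csf_ab42_40_ratio")$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("zero-variance residuals are rejected", {
  tab <- data.frame(age_years = 1:16, m = 2 * (1:16) + 3, b = rnorm(16))
  expect_error(residualization_fit(tab, "m", "b"), "zero-variance")
})

test_that("the association report is row-order invariant and handles empty biomarkers", {
  tab <- generate_cohort(cohort_spec(seed = 20))
  r1 <- run_association_report(tab)
  set.seed(1)
  r2 <- run_association_report(tab[sample(nrow(tab)), ])
  expect_equal(r1$correlations$rho, r2$correlations$rho)
  expect_equal(r1$correlations$p, r2$correlations$p)
  expect_equal(r1$age_adjusted, r2$age_adjusted)
  expect_equal(r1$scatter, r2$scatter)

  small <- tab[, c("subject_id", "age_years", flow_metric_columns())]
  r3 <- run_association_report(small)
  expect_null(r3$age_adjusted)
  expect_setequal(colnames(r3$correlations$rho),
                  c("age_years", flow_metric_columns()))
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  tab <- generate_cohort(cohort_spec(seed = 30))
  cm <- correlation_matrix(tab, vars = c("age_years", "peak_flow", "csf_nfl"))
  cmb <- correlation_matrix(tab, vars = c("age_years", "peak_flow", "csf_nfl"),
                            p_adjust = "BH")
  expect_true(all(cmb$pairs$p_value >= cm$pairs$p_value - 1e-15))
})
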