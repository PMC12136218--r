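# Association stage: correlation matrix with significance masking,
# age-controlled partial correlation (two cross-checked routes), and the
# residualization regression.

midrank <- function(x) rank(x, ties.method = "average", na.last = "keep")

# Pearson r and two-sided p via the t approximation with n - 2 df.
# For method = "spearman", callers pass mid-ranks.
cor_t_test <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r)) return(list(rho = NA_real_, p = NA_real_, n = n))
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(list(rho = r, p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

# one pairwise-complete correlation cell
cor_cell <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  x <- x[ok]; y <- y[ok]
  if (method == "spearman") { x <- midrank(x); y <- midrank(y) }
  cor_t_test(x, y)
}

#' Correlation matrix with significance masking
#'
#' All pairwise correlations among the numeric columns of a cohort table,
#' with pairwise complete-case deletion. Spearman (default) correlates
#' mid-ranks (ties averaged); p-values use the two-sided t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#' Cells with fewer than 4 complete pairs are reported as missing. No
#' multiple-testing correction is applied by default; `p_adjust = "BH"`
#' applies Benjamini-Hochberg across the lower triangle.
#'
#' @param table Data frame (e.g. from [generate_cohort()]).
#' @param vars Columns to include; default all numeric columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Two-sided significance threshold for the mask (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Object of class `correlation_matrix`: list with matrices `rho`,
#'   `p`, `n`, logical `significant`, and a long-format data.frame `pairs`
#'   (columns `var_x`, `var_y`, `rho`, `p_value`, `n_used`, `method`).
#' @export
correlation_matrix <- function(table, vars = NULL,
                               method = c("spearman", "pearson"),
                               alpha = 0.05, p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  k <- length(vars)
  if (k < 2) stop("need at least two numeric columns")
  rho <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  diag(nm) <- vapply(vars, function(v) sum(is.finite(table[[v]])), numeric(1))
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cell <- cor_cell(table[[vars[i]]], table[[vars[j]]], method)
    rho[i, j] <- rho[j, i] <- cell$rho
    p[i, j] <- p[j, i] <- cell$p
    nm[i, j] <- nm[j, i] <- cell$n
    pairs[[length(pairs) + 1]] <- data.frame(
      var_x = vars[i], var_y = vars[j], rho = cell$rho, p_value = cell$p,
      n_used = cell$n, method = method, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (p_adjust == "BH") {
    pairs$p_value <- stats::p.adjust(pairs$p_value, "BH")
    for (r in seq_len(nrow(pairs)))
      p[pairs$var_x[r], pairs$var_y[r]] <-
        p[pairs$var_y[r], pairs$var_x[r]] <- pairs$p_value[r]
  }
  structure(list(rho = rho, p = p, n = nm,
                 significant = !is.na(p) & p < alpha,
                 pairs = pairs, method = method, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("%s correlation matrix (%d variables); '.' = p >= %g or n < 4\n",
              x$method, ncol(x$rho), x$alpha))
  out <- formatC(x$rho, digits = digits, format = "f")
  out[!x$significant] <- "."
  diag(out) <- "1"
  print(noquote(out))
  invisible(x)
}

# closed-form first-order partial correlation from three pairwise r's
partial_from_marginals <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation between `var_x` and `var_y` given
#' `control`, computed by two independent routes that are asserted to agree
#' to 1e-10: (a) the closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` and (b) the Pearson
#' correlation of the OLS residuals of x on the control and y on the
#' control. For `method = "spearman"` both routes operate on mid-ranks.
#' The two-sided p-value uses `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 3`.
#'
#' @param table Data frame with the three columns.
#' @param var_x,var_y,control Column names.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `partial_correlation`: list with `rho_partial`,
#'   `p_value`, `df`, `n_used`, `t_value`, the route values
#'   (`rho_closed_form`, `rho_residual`) and metadata.
#' @export
partial_correlation <- function(table, var_x, var_y, control,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- table[[var_x]]; y <- table[[var_y]]; z <- table[[control]]
  if (is.null(x) || is.null(y) || is.null(z))
    stop("var_x, var_y and control must name columns of the table")
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  n <- sum(ok)
  if (n < 4)
    stop(sprintf("only %d complete triples; at least 4 are required", n))
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (method == "spearman") {
    x <- midrank(x); y <- midrank(y); z <- midrank(z)
  }
  rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (!is.finite(rxz) || !is.finite(ryz) ||
      abs(abs(rxz) - 1) < 1e-12 || abs(abs(ryz) - 1) < 1e-12)
    stop("partial correlation undefined: a variable is collinear with the control")
  r_a <- partial_from_marginals(stats::cor(x, y), rxz, ryz)

  Z <- cbind(1, z)
  ex <- stats::lm.fit(Z, x)$residuals
  ey <- stats::lm.fit(Z, y)$residuals
  r_b <- stats::cor(ex, ey)

  if (abs(r_a - r_b) > 1e-10)
    stop(sprintf("internal cross-check failed: closed-form %.15g vs residual route %.15g",
                 r_a, r_b))
  r <- max(min(r_a, 1), -1)
  df <- n - 3
  tt <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df = df)
  structure(list(var_x = var_x, var_y = var_y, control = control,
                 rho_partial = r, p_value = p, df = df, n_used = n,
                 t_value = tt, rho_closed_form = r_a, rho_residual = r_b,
                 method = method), class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("partial %s correlation of %s and %s given %s:\n  rho = %.4f, t(%d) = %.3f, p = %.4g (n = %d)\n",
              x$method, x$var_x, x$var_y, x$control, x$rho_partial, x$df,
              x$t_value, x$p_value, x$n_used))
  invisible(x)
}

#' Residualization regression of a biomarker on an age-adjusted flow metric
#'
#' Two-stage age adjustment: (1) OLS of the flow metric on age; keep the
#' residuals as the age-adjusted component. (2) OLS of the biomarker on that
#' component. By default age is retained as a covariate in stage 2
#' (`biomarker ~ age + residual`), so the reported slope isolates the
#' age-independent contribution of the flow metric and its t statistic is
#' algebraically identical to the Pearson partial-correlation t
#' (`df = n - 3`). With `age_covariate = FALSE`, stage 2 is the simple
#' regression `biomarker ~ residual` (`df = n - 2`), whose p-value
#' approaches but does not exactly equal the partial-correlation p.
#'
#' @param table Data frame.
#' @param metric,biomarker Column names of the flow metric and the biomarker.
#' @param age_col Name of the age column (default `"age_years"`).
#' @param age_covariate Keep age in the stage-2 model (default `TRUE`).
#' @return Object of class `residualization_fit`: list with `estimate`
#'   (stage-2 slope on the residualized metric), `std_error`, `t_value`,
#'   `p_value`, `df`, `n` and metadata.
#' @export
residualization_fit <- function(table, metric, biomarker,
                                age_col = "age_years", age_covariate = TRUE) {
  x <- table[[metric]]; y <- table[[biomarker]]; z <- table[[age_col]]
  if (is.null(x) || is.null(y) || is.null(z))
    stop("metric, biomarker and age_col must name columns of the table")
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  n <- sum(ok)
  if (n < 4)
    stop(sprintf("only %d complete triples; at least 4 are required", n))
  x <- x[ok]; y <- y[ok]; z <- z[ok]

  res <- stats::lm.fit(cbind(1, z), x)$residuals
  if (stats::sd(res) < 1e-12 * max(stats::sd(x), 1))
    stop("metric is (numerically) perfectly explained by age: zero-variance residuals")

  X2 <- if (age_covariate) cbind(`(Intercept)` = 1, age = z, resid = res)
        else cbind(`(Intercept)` = 1, resid = res)
  fit <- stats::lm.fit(X2, y)
  df <- n - ncol(X2)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X2)))
  se <- sqrt(rss / df * diag(XtXinv))
  est <- fit$coefficients["resid"]
  sde <- se[ncol(X2)]
  tt <- est / sde
  structure(list(metric = metric, biomarker = biomarker, age_col = age_col,
                 age_covariate = age_covariate,
                 estimate = unname(est), std_error = unname(sde),
                 t_value = unname(tt),
                 p_value = unname(2 * stats::pt(-abs(tt), df = df)),
                 df = df, n = n, residuals_stage1 = res),
            class = "residualization_fit")
}

#' @export
print.residualization_fit <- function(x, ...) {
  cat(sprintf("residualization: %s ~ %sage-adjusted %s\n",
              x$biomarker, if (x$age_covariate) "age + " else "", x$metric))
  cat(sprintf("  estimate %.4g, SE %.4g, t(%d) = %.3f, p = %.4g (n = %d)\n",
              x$estimate, x$std_error, x$df, x$t_value, x$p_value, x$n))
  invisible(x)
}

#' Full association report
#'
#' Assembles the association analysis of a cohort table: the full
#' correlation matrix with p-values and significance mask, a per-metric
#' partial-correlation / residualization table against a primary biomarker
#' (age-adjusted), and per-pair scatter data (age vs metric, metric vs
#' biomarker, and the age-residual scatter). Cells that cannot be computed
#' (too few complete cases, collinearity) are reported as missing with the
#' failure message attached, not dropped silently. The report is invariant
#' under row permutation of the input table.
#'
#' @param table Cohort data frame.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @param age_col Age column name.
#' @param metrics Flow-metric columns (default the six standard columns
#'   present in the table).
#' @param biomarkers Biomarker columns (default all recognised biomarker
#'   columns present; may be empty, restricting the matrix to age + metrics).
#' @param primary_biomarker Biomarker for the age-adjusted table (default
#'   `"csf_ab42_40_ratio"` when present).
#' @return Object of class `csf_assoc_report`: list with `correlations`
#'   ([correlation_matrix]), `age_adjusted` (data.frame, one row per metric:
#'   partial rho/p and residualization estimate/SE/t/p), `scatter` (named
#'   list of data.frames), `failures` (named character), and the settings.
#' @export
run_association_report <- function(table, method = c("spearman", "pearson"),
                                   alpha = 0.05, age_col = "age_years",
                                   metrics = NULL, biomarkers = NULL,
                                   primary_biomarker = NULL) {
  method <- match.arg(method)
  if (is.null(metrics))
    metrics <- intersect(flow_metric_columns(), names(table))
  if (is.null(biomarkers))
    biomarkers <- intersect(c("csf_ab42_40_ratio", null_biomarker_columns()),
                            names(table))
  if (is.null(primary_biomarker))
    primary_biomarker <- if ("csf_ab42_40_ratio" %in% biomarkers)
      "csf_ab42_40_ratio" else if (length(biomarkers)) biomarkers[1] else NULL
  if (length(metrics) == 0) stop("no flow-metric columns found in the table")

  vars <- c(age_col, metrics, biomarkers)
  cm <- correlation_matrix(table, vars = vars, method = method, alpha = alpha)

  failures <- character(0)
  age_adjusted <- NULL
  if (!is.null(primary_biomarker)) {
    rows <- lapply(metrics, function(m) {
      pc <- tryCatch(partial_correlation(table, m, primary_biomarker,
                                         age_col, method = method),
                     error = function(e) e)
      rf <- tryCatch(residualization_fit(table, m, primary_biomarker, age_col),
                     error = function(e) e)
      if (inherits(pc, "error") || inherits(rf, "error")) {
        failures[[m]] <<- conditionMessage(if (inherits(pc, "error")) pc else rf)
        return(data.frame(metric = m, partial_rho = NA, partial_p = NA,
                          estimate = NA, std_error = NA, t_value = NA,
                          resid_p = NA, n = NA))
      }
      data.frame(metric = m, partial_rho = pc$rho_partial,
                 partial_p = pc$p_value, estimate = rf$estimate,
                 std_error = rf$std_error, t_value = rf$t_value,
                 resid_p = rf$p_value, n = rf$n)
    })
    age_adjusted <- do.call(rbind, rows)
  }

  scatter <- list()
  ord <- order(table[[age_col]])
  for (m in metrics) {
    sc0 <- data.frame(age = table[[age_col]], metric = table[[m]])[ord, ]
    rownames(sc0) <- NULL
    scatter[[paste0("age_vs_", m)]] <- sc0
    if (!is.null(primary_biomarker)) {
      rf <- tryCatch(residualization_fit(table, m, primary_biomarker, age_col),
                     error = function(e) NULL)
      if (!is.null(rf)) {
        ok <- is.finite(table[[m]]) & is.finite(table[[primary_biomarker]]) &
          is.finite(table[[age_col]])
        sc <- data.frame(metric_age_residual = rf$residuals_stage1,
                         biomarker = table[[primary_biomarker]][ok])
        sc <- sc[order(sc$metric_age_residual), ]
        rownames(sc) <- NULL
        scatter[[paste0(m, "_resid_vs_", primary_biomarker)]] <- sc
      }
    }
  }

  structure(list(correlations = cm, age_adjusted = age_adjusted,
                 scatter = scatter, failures = failures, method = method,
                 alpha = alpha, age_col = age_col, metrics = metrics,
                 biomarkers = biomarkers,
                 primary_biomarker = primary_biomarker),
            class = "csf_assoc_report")
}

#' @export
print.csf_assoc_report <- function(x, ...) {
  print(x$correlations)
  if (!is.null(x$age_adjusted)) {
    cat(sprintf("\nAge-adjusted association with %s (partial %s correlation / residualization):\n",
                x$primary_biomarker, x$method))
    print(x$age_adjusted, digits = 3, row.names = FALSE)
  }
  if (length(x$failures))
    cat("\nfailed cells:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
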