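#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardises the values by their sample mean and SD and compares the
#' empirical CDF against the standard normal; the p-value comes from the
#' asymptotic Kolmogorov distribution.  (The Lilliefors correction for
#' estimated parameters is deliberately not applied; the plain KS test is
#' the gate used for choosing between t and Mann-Whitney tests here.)
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return List with `statistic` (D) and `p_value`.
#' @examples
#' ks_normality(c(-1, 0, 1)) # D ~ 0.1747
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("`values` must have n >= 3.")
  if (sd(values) == 0) abort("`values` must not be constant.")
  z <- (values - mean(values)) / sd(values)
  res <- suppressWarnings(ks.test(z, "pnorm", exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value (full permutation distribution) when both groups have at
#' most 10 observations and no ties are present; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return List with `statistic` (U of `a`), `p_value` and `exact`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("inputs must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Without continuity correction, df = 1, two-sided.  The table is
#' `rbind(c(a, b), c(c, d))`, i.e. rows are groups and columns category
#' levels.
#'
#' @param a,b,c,d Non-negative counts; both margins must be positive.
#' @return List with `statistic` (chi-squared) and `p_value`.
#' @examples
#' chi_square_2x2(18, 2, 16, 4) # p ~ 0.376
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative.")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("both margins of the 2x2 table must be positive.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' KS-gated two-group comparison
#'
#' Runs [ks_normality()] on each group; when both p-values exceed
#' `alpha_normality` the groups are compared by a pooled-variance
#' Student's t-test (summaries reported as mean +/- SD), otherwise by the
#' Mann-Whitney U test (summaries as median (min-max)).  Welch's t is
#' available via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, `n >= 3` each.
#' @param variable Label carried into the result.
#' @param alpha_normality Normality gate level.
#' @param var_equal Pooled (TRUE, Student) or Welch (FALSE) t-test.
#' @return Object of class `repdiv_comparison`; see [tidy()] /
#'   [glance()].
#' @export
compare_groups <- function(a, b, variable = "value",
                           alpha_normality = 0.05, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) abort("need n >= 3 per group.")
  ks_a <- ks_normality(a); ks_b <- ks_normality(b)
  normal <- ks_a$p_value > alpha_normality && ks_b$p_value > alpha_normality

  if (normal) {
    res <- t.test(a, b, var.equal = var_equal)
    test_used <- "t"
    statistic <- unname(res$statistic)
    p_value <- res$p.value
    summary_a <- sprintf("%.4g±%.4g", mean(a), sd(a))
    summary_b <- sprintf("%.4g±%.4g", mean(b), sd(b))
  } else {
    res <- mann_whitney(a, b)
    test_used <- "mwu"
    statistic <- res$statistic
    p_value <- res$p_value
    summary_a <- sprintf("%.4g(%.4g-%.4g)", median(a), min(a), max(a))
    summary_b <- sprintf("%.4g(%.4g-%.4g)", median(b), min(b), max(b))
  }
  structure(list(variable = variable, n_a = length(a), n_b = length(b),
                 test_used = test_used, statistic = statistic,
                 p_value = p_value,
                 normality_p_a = ks_a$p_value,
                 normality_p_b = ks_b$p_value,
                 summary_a = summary_a, summary_b = summary_b),
            class = "repdiv_comparison")
}

#' @export
print.repdiv_comparison <- function(x, ...) {
  cat(sprintf("<repdiv_comparison> %s: %s vs %s, %s test, p = %.4g\n",
              x$variable, x$summary_a, x$summary_b, x$test_used,
              x$p_value))
  invisible(x)
}

#' @method tidy repdiv_comparison
#' @export
tidy.repdiv_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, n_a = x$n_a, n_b = x$n_b,
                 summary_a = x$summary_a, summary_b = x$summary_b,
                 test_used = x$test_used, statistic = x$statistic,
                 p_value = x$p_value)
}

#' @method glance repdiv_comparison
#' @export
glance.repdiv_comparison <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, statistic = x$statistic,
                 p_value = x$p_value, normality_p_a = x$normality_p_a,
                 normality_p_b = x$normality_p_b)
}

#' Compare several cohort variables between two groups
#'
#' Data-frame-first wrapper over [compare_groups()]: for each variable
#' column, splits the rows by the two levels of `group` and returns the
#' tidied comparisons.
#'
#' @param data A data frame.
#' @param group Column (tidy-eval) with exactly two distinct values;
#'   the first level (factor order, else order of appearance) is group A.
#' @param ... Variable columns (tidy-select) to compare.
#' @param alpha_normality Normality gate level.
#' @return Tibble with one row per variable.
#' @export
compare_cohort <- function(data, group, ..., alpha_normality = 0.05) {
  grp <- dplyr::pull(data, {{ group }})
  lev <- if (is.factor(grp)) levels(grp) else unique(grp)
  if (length(lev) != 2) abort("`group` must have exactly two levels.")
  vars <- names(dplyr::select(data, ...))
  purrr::map(vars, function(v) {
    tidy(compare_groups(data[[v]][grp == lev[1]],
                        data[[v]][grp == lev[2]],
                        variable = v,
                        alpha_normality = alpha_normality))
  }) |> dplyr::bind_rows()
}

#' Pearson correlation with linear fit and Fisher-z interval
#'
#' Pearson's r with the two-sided t-based p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))`), least-squares slope and
#' intercept, the 95% Fisher-z confidence interval for r, and the 95%
#' mean-response band at each x for plotting.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @param label Optional label (e.g. a gene id).
#' @return Object of class `repdiv_correlation`; see [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' fit <- pearson_regression(1:4, c(2, 1, 4, 3))
#' tidy(fit) # r = 0.6
#' @export
pearson_regression <- function(x, y, label = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need n >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("`x` and `y` must be non-constant.")

  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  if (!is.null(ct$conf.int) && abs(r) < 1) {
    ci <- as.numeric(ct$conf.int)
  } else if (n > 3 && abs(r) < 1) {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  fit <- lm(y ~ x)
  grid <- sort(unique(x))
  band <- predict(fit, newdata = data.frame(x = grid),
                  interval = "confidence", level = 0.95)
  structure(list(label = label, n = n, r = r, p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci_low = ci[1], ci_high = ci[2],
                 conf_band = tibble::tibble(x = grid,
                                            fit = band[, "fit"],
                                            lwr = band[, "lwr"],
                                            upr = band[, "upr"]),
                 data = tibble::tibble(x = x, y = y)),
            class = "repdiv_correlation")
}

#' @export
print.repdiv_correlation <- function(x, ...) {
  cat(sprintf("<repdiv_correlation>%s r = %.3f [%.3f, %.3f], p = %.4g, n = %d\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' @method tidy repdiv_correlation
#' @export
tidy.repdiv_correlation <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, n = x$n, r = x$r,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 slope = x$slope, intercept = x$intercept,
                 p_value = x$p_value)
}

#' @method glance repdiv_correlation
#' @export
glance.repdiv_correlation <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, slope = x$slope,
                 intercept = x$intercept, p_value = x$p_value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in input order.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.5)) # 0.02, 0.5
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Fold-change / FDR expression screen between two groups
#'
#' A transparent per-gene screen (not a negative-binomial model fit):
#' `log2fc = log2((mean_A + 1) / (mean_B + 1))` with a pseudocount of 1,
#' a Mann-Whitney p-value per gene, BH adjustment, and the significance
#' rule `|log2fc| > 1 & fdr < 0.05`.
#'
#' @param expression Tibble with `gene_id` plus one numeric column per
#'   sample (non-negative), or a numeric matrix with gene rownames.
#' @param groups Tibble (`sample_id`, `group`) or named character vector
#'   mapping sample ids to two group labels; >= 3 samples per group.
#' @param group_a Level treated as group A (numerator); defaults to the
#'   first level encountered.
#' @param fc_threshold_log2,fdr_threshold Significance thresholds.
#' @return Tibble with `gene_id`, `log2fc`, `p_value`, `fdr`, `passes`.
#' @export
expression_group_screen <- function(expression, groups, group_a = NULL,
                                    fc_threshold_log2 = 1,
                                    fdr_threshold = 0.05) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  mat <- expression_to_matrix(expression)
  if (any(mat < 0)) abort("expression values must be non-negative.")
  groups <- groups[colnames(mat)]
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2) abort("`groups` must define exactly two groups.")
  if (!is.null(group_a)) lev <- c(group_a, setdiff(lev, group_a))
  in_a <- which(groups == lev[1]); in_b <- which(groups == lev[2])
  if (length(in_a) < 3 || length(in_b) < 3) {
    abort("need >= 3 samples per group.")
  }

  log2fc <- log2((rowMeans(mat[, in_a, drop = FALSE]) + 1) /
                   (rowMeans(mat[, in_b, drop = FALSE]) + 1))
  p <- apply(mat, 1, function(v) mann_whitney(v[in_a], v[in_b])$p_value)
  p[!is.finite(p)] <- 1 # fully tied genes carry no evidence
  fdr <- bh_adjust(p)
  tibble::tibble(gene_id = rownames(mat), log2fc = unname(log2fc),
                 p_value = unname(p), fdr = fdr,
                 passes = abs(log2fc) > fc_threshold_log2 &
                   fdr < fdr_threshold)
}

# accept gene_id-tibble or matrix expression input
expression_to_matrix <- function(expression) {
  if (is.matrix(expression)) return(expression)
  if (!is.data.frame(expression) || !"gene_id" %in% names(expression)) {
    abort("`expression` must be a matrix or a tibble with `gene_id`.")
  }
  mat <- as.matrix(expression[, setdiff(names(expression), "gene_id")])
  rownames(mat) <- expression$gene_id
  mat
}

#' Correlate repertoire diversity with gene expression
#'
#' Pearson regression ([pearson_regression()]) of per-sample Shannon
#' entropy against each named gene's expression across the samples
#' shared between the diversity summaries and the expression matrix.
#'
#' @param summaries Diversity summary tibble (needs `sample_id`,
#'   `entropy`), e.g. from [summarize_repertoire()].
#' @param expression Expression tibble/matrix (see
#'   [expression_group_screen()]).
#' @param gene_ids Genes to test.
#' @param log2_expr Correlate against `log2(expression + 1)` instead of
#'   raw values.
#' @return Tibble sorted by p-value with one row per gene (`r`, Fisher-z
#'   CI, slope, intercept, `p_value`) and a `fit` list-column of
#'   `repdiv_correlation` objects (`NULL` and NA statistics for unknown
#'   genes, which are reported via a message and do not stop the run).
#' @export
correlate_diversity_expression <- function(summaries, expression,
                                           gene_ids, log2_expr = FALSE) {
  mat <- expression_to_matrix(expression)
  shared <- intersect(summaries$sample_id, colnames(mat))
  if (length(shared) < 3) abort("need >= 3 overlapping samples.")
  entropy <- summaries$entropy[match(shared, summaries$sample_id)]

  rows <- purrr::map(gene_ids, function(g) {
    if (!g %in% rownames(mat)) {
      message(sprintf("gene `%s` not found in expression matrix", g))
      return(tibble::tibble(gene_id = g, n = NA_integer_, r = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            slope = NA_real_, intercept = NA_real_,
                            p_value = NA_real_, fit = list(NULL)))
    }
    y <- mat[g, shared]
    if (log2_expr) y <- log2(y + 1)
    fit <- pearson_regression(entropy, y, label = g)
    dplyr::mutate(dplyr::rename(tidy(fit), gene_id = "label"),
                  fit = list(fit))
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p_value)
}
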