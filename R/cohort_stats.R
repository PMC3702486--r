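#' Pooled two-sample Student t-test from printed summaries
#'
#' The classical pooled-variance two-sided t-test computed directly from
#' group means, SDs, and sizes, as needed to re-check published
#' mean-plus-SD tables. With zero pooled variance the test degenerates:
#' equal means give t = 0, p = 1; unequal means give p = 0 and the
#' `degenerate` flag is set.
#'
#' @param mean1,sd1,n1 Summary of group 1 (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return A one-row tibble: `estimate` (mean1 - mean2), `statistic` (t),
#'   `df`, `p_value`, `method`, `degenerate`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) abort("sds must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  degenerate <- FALSE
  if (sp2 == 0) {
    if (diff == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(diff) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- diff / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble(estimate = diff, statistic = t, df = df, p_value = p,
         method = "pooled two-sample t", degenerate = degenerate)
}

#' Pooled two-sample Student t-test from raw values
#'
#' Identical to [t_test_summary()] applied to the groups' computed mean,
#' SD (ddof = 1), and size.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return As [t_test_summary()].
#' @export
t_test_subjects <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y))
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided exact test on a 2 x 2 contingency table using the
#' probability-mass convention: the p-value sums the hypergeometric
#' probabilities (margins fixed) of every table no more probable than the
#' observed one. A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return A one-row tibble with the four counts (`a`, `b`, `c`, `d`,
#'   row-wise) and `p_value`.
#' @export
fisher_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!identical(dim(tb), c(2L, 2L))) abort("a 2 x 2 table is required")
  if (any(tb < 0) || any(tb != round(tb))) {
    abort("counts must be non-negative integers")
  }
  p <- if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    1
  } else {
    stats::fisher.test(tb)$p.value
  }
  tibble(a = tb[1, 1], b = tb[1, 2], c = tb[2, 1], d = tb[2, 2],
         p_value = min(p, 1))
}

#' Two-group cohort report
#'
#' Mean-plus-SD comparison table in the style of a clinical baseline table:
#' each continuous variable is summarized per group and compared with the
#' pooled two-sided Student t-test; each logical/categorical variable is
#' summarized as count (percent) and compared with the Fisher exact test.
#' Missing values are dropped per variable with a message.
#'
#' @param cohort Data frame with one row per subject.
#' @param group Name of the logical grouping column (`TRUE` = group 1).
#' @param continuous Character vector of continuous variable names;
#'   defaults to all numeric columns except the group.
#' @param categorical Character vector of logical variable names (optional).
#' @return A tibble with one row per variable: per-group `mean`/`sd`/`n`
#'   (or `count`/`pct`), formatted `group1` / `group2` strings, `test`, and
#'   `p_value`.
#' @export
build_report <- function(cohort, group = "icd_therapy",
                         continuous = NULL, categorical = NULL) {
  if (!group %in% names(cohort)) abort(sprintf("no column '%s'", group))
  g <- as.logical(cohort[[group]])
  if (length(unique(g[!is.na(g)])) != 2L) abort("two groups are required")
  if (is.null(continuous)) {
    continuous <- setdiff(
      names(cohort)[vapply(cohort, is.numeric, logical(1))],
      c(group, "id"))
  }

  cont <- purrr::map_dfr(continuous, function(v) {
    x <- cohort[[v]][g]; y <- cohort[[v]][!g]
    n_na <- sum(is.na(x)) + sum(is.na(y))
    if (n_na > 0) {
      message(sprintf("%s: dropping %d missing values", v, n_na))
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    tt <- t_test_subjects(x, y)
    tibble(
      variable = v, type = "continuous",
      mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
      mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
      group1 = sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
      group2 = sprintf("%.1f ± %.1f", mean(y), stats::sd(y)),
      test = "pooled t", p_value = tt$p_value
    )
  })

  cat_rows <- purrr::map_dfr(categorical %||% character(0), function(v) {
    x <- as.logical(cohort[[v]][g]); y <- as.logical(cohort[[v]][!g])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    tb <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
    fr <- fisher_2x2(tb)
    tibble(
      variable = v, type = "categorical",
      mean1 = NA_real_, sd1 = NA_real_, n1 = length(x),
      mean2 = NA_real_, sd2 = NA_real_, n2 = length(y),
      group1 = sprintf("%d (%.0f%%)", sum(x), 100 * mean(x)),
      group2 = sprintf("%d (%.0f%%)", sum(y), 100 * mean(y)),
      test = "Fisher exact", p_value = fr$p_value
    )
  })
  dplyr::bind_rows(cont, cat_rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
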