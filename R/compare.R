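#' Lilliefors-type normality test
#'
#' Kolmogorov-Smirnov test of composite normality with mean and SD estimated
#' from the sample (the Lilliefors correction), as implemented by
#' `nortest::lillie.test()`. An option to test against a fully specified
#' normal (parameters supplied, classical KS) is kept because reports rarely
#' state which variant was used.
#'
#' @param x Numeric vector, `n >= 4`, finite, non-constant.
#' @param estimated If `TRUE` (default) parameters are estimated from the
#'   sample (Lilliefors); if `FALSE`, a classical one-sample KS test against
#'   `N(mean(x), sd(x))` is run without the small-sample correction.
#' @return The p-value in (0, 1].
#' @export
ks_normality <- function(x, estimated = TRUE) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("need at least 4 non-missing values", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant sample: normality is undefined for zero variance",
         call. = FALSE)
  }
  if (estimated) {
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x))$p.value)
  }
}

#' Compare one feature between the benign and ALT groups
#'
#' Reproduces the standard two-group test-selection procedure: continuous
#' features are first checked for normality per group (Lilliefors KS at
#' `alpha_normal`); if both groups pass, an unpaired t-test is used (Welch by
#' default given the typical 39-vs-6 imbalance); otherwise, if all values are
#' positive and the log-transformed groups pass, the t-test is run on logs;
#' otherwise the Mann-Whitney U test. Binary and categorical features go to
#' Fisher's exact test (the in-package 2x2 test for two-level features,
#' `stats::fisher.test()` for the r x 2 case). Missing values are dropped
#' listwise for the feature; no imputation is done.
#'
#' @param cohort Cohort `data.frame`.
#' @param feature Feature column name.
#' @param class_col Class column (values `B`/`ALT`).
#' @param alpha_normal Significance level of the normality gate (0.05).
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @param exact_mw Force exact (`TRUE`) or approximate (`FALSE`) Mann-Whitney;
#'   default `NULL` uses exact enumeration below a combined n of 20 when no
#'   ties are present and the tie-corrected normal approximation otherwise.
#' @param estimated_ks Passed to [ks_normality()] as `estimated`.
#' @return An object of class `"comparison_result"`: feature name, `test`
#'   (`"t_test"`, `"mann_whitney"` or `"fisher_exact"`), `transform`
#'   (`"none"`/`"log"`), `statistic`, `p_value` and per-group summaries.
#'   Groups with fewer than 2 usable values yield an `NA` sentinel result.
#' @export
compare_feature <- function(cohort, feature, class_col = "group",
                            alpha_normal = 0.05, var_equal = FALSE,
                            exact_mw = NULL, estimated_ks = TRUE) {
  if (!feature %in% names(cohort)) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  cls <- cohort[[class_col]]
  val <- cohort[[feature]]
  keep <- !is.na(cls) & !is.na(val)
  cls <- cls[keep]
  val <- val[keep]
  is_binary <- all(val %in% c(0, 1))
  is_cat <- is.character(val) || is.factor(val) || is_binary
  res <- list(feature = feature, test = NA_character_, transform = "none",
              statistic = NA_real_, p_value = NA_real_, groups = NULL)
  class(res) <- "comparison_result"

  if (is_cat) {
    tab <- table(factor(cls, levels = c("B", "ALT")), factor(val))
    res$groups <- tab
    res$test <- "fisher_exact"
    if (ncol(tab) < 2L) {            # constant feature: no association testable
      res$p_value <- 1
      return(res)
    }
    if (ncol(tab) == 2L) {
      ct <- contingency_2x2(tab["ALT", 2], tab["ALT", 1],
                            tab["B", 2], tab["B", 1],
                            positive_class = "ALT",
                            test_positive = colnames(tab)[2])
      res$p_value <- fisher_exact_2x2(ct)
    } else {
      res$p_value <- stats::fisher.test(tab)$p.value
    }
    return(res)
  }

  xb <- val[cls == "B"]
  xa <- val[cls == "ALT"]
  res$groups <- data.frame(
    group = c("B", "ALT"), n = c(length(xb), length(xa)),
    mean = c(mean(xb), mean(xa)), sd = c(stats::sd(xb), stats::sd(xa)))
  if (length(xb) < 2L || length(xa) < 2L) return(res)  # NA sentinel

  normal_p <- function(v) {
    if (stats::sd(v) == 0 || length(v) < 4L) return(0)
    ks_normality(v, estimated = estimated_ks)
  }
  both_normal <- function(b, a) {
    normal_p(b) > alpha_normal && normal_p(a) > alpha_normal
  }
  run_t <- function(b, a, transform) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res$test <<- "t_test"
    res$transform <<- transform
    res$statistic <<- unname(tt$statistic)
    res$p_value <<- tt$p.value
  }
  if (both_normal(xb, xa)) {
    run_t(xb, xa, "none")
  } else if (all(val > 0) && both_normal(log(xb), log(xa))) {
    run_t(log(xb), log(xa), "log")
  } else {
    n_comb <- length(val)
    has_ties <- anyDuplicated(val) > 0L
    exact <- exact_mw %||% (n_comb < 20L && !has_ties)
    wt <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = exact, correct = !exact))
    res$test <- "mann_whitney"
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
  }
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s%s, p = %s\n", x$feature,
              if (is.na(x$test)) "insufficient data" else x$test,
              if (identical(x$transform, "log")) " (log scale)" else "",
              format(x$p_value, digits = 4)))
  invisible(x)
}

#' Compare every feature of a cohort between groups
#'
#' @inheritParams compare_feature
#' @param features Feature columns to compare; defaults to every column
#'   except the class column and `patient_id`.
#' @param ... Passed on to [compare_feature()].
#' @return A `data.frame` with one row per feature (`feature`, `test`,
#'   `transform`, `statistic`, `p_value`) carrying the full
#'   `"comparison_result"` objects in the attribute `"results"`.
#' @export
compare_cohort <- function(cohort, features = NULL, class_col = "group", ...) {
  features <- features %||%
    setdiff(names(cohort), c(class_col, "patient_id"))
  results <- lapply(features, function(f)
    compare_feature(cohort, f, class_col = class_col, ...))
  names(results) <- features
  out <- data.frame(
    feature = features,
    test = vapply(results, `[[`, character(1), "test"),
    transform = vapply(results, `[[`, character(1), "transform"),
    statistic = vapply(results, `[[`, numeric(1), "statistic"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    row.names = NULL)
  attr(out, "results") <- results
  out
}
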