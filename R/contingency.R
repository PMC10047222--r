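#' Build a 2x2 contingency table with explicit orientation
#'
#' Cell `a` counts patients who are both class-positive and test-positive,
#' `b` class-positive / test-negative, `c` class-negative / test-positive and
#' `d` class-negative / test-negative. The orientation (which class label
#' counts as "positive" and which feature state as "test-positive") is kept
#' as metadata because published tables use both conventions: a benign-
#' positive orientation with "test-positive = feature absent" treats the
#' absence of a worrying finding as the test for benignity, while score
#' evaluation uses the ALT-positive orientation.
#'
#' @param a,b,c,d Non-negative integer cell counts, `a+b+c+d >= 1`.
#' @param positive_class Class label treated as positive (default `"ALT"`).
#' @param test_positive Free-text description of the test-positive state.
#' @return An object of class `"contingency_2x2"`.
#' @examples
#' contingency_2x2(37, 2, 1, 5, positive_class = "B",
#'                 test_positive = "STIR discrepancy absent")
#' @export
contingency_2x2 <- function(a, b, c, d, positive_class = "ALT",
                            test_positive = "feature present") {
  counts <- c(a = a, b = b, c = c, d = d)
  for (nm in names(counts)) stop_if_not_count(counts[[nm]], paste("cell", nm))
  counts <- vapply(counts, function(x) as.integer(round(x)), integer(1))
  if (sum(counts) < 1L) stop("table must contain at least one count",
                             call. = FALSE)
  structure(list(a = counts[["a"]], b = counts[["b"]], c = counts[["c"]],
                 d = counts[["d"]], positive_class = positive_class,
                 test_positive = test_positive),
            class = "contingency_2x2")
}

#' Cross-tabulate a cohort feature against the class column
#'
#' @param cohort Cohort `data.frame`.
#' @param feature Name of a binary (0/1 or two-level) column.
#' @param class_col Class column name (values `B`/`ALT`).
#' @param positive_class Class treated as positive.
#' @param feature_positive Feature value counted as test-positive (default
#'   `1`).
#' @return A `"contingency_2x2"`. Rows with a missing class or feature value
#'   are dropped.
#' @export
contingency_from_cohort <- function(cohort, feature, class_col = "group",
                                    positive_class = "ALT",
                                    feature_positive = 1) {
  if (!feature %in% names(cohort)) {
    stop("feature '", feature, "' not found", call. = FALSE)
  }
  cls <- cohort[[class_col]]
  val <- cohort[[feature]]
  keep <- !is.na(cls) & !is.na(val)
  cls <- cls[keep]
  val <- val[keep]
  pos_c <- cls == positive_class
  pos_t <- val == feature_positive
  contingency_2x2(sum(pos_c & pos_t), sum(pos_c & !pos_t),
                  sum(!pos_c & pos_t), sum(!pos_c & !pos_t),
                  positive_class = positive_class,
                  test_positive = paste0(feature, " = ", feature_positive))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c(paste0(x$positive_class, "+"),
                                paste0(x$positive_class, "-")),
                              c("test+", "test-")))
  cat("<contingency_2x2> positive class:", x$positive_class,
      "| test-positive:", x$test_positive, "\n")
  print(m)
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value from the hypergeometric distribution
#' under fixed margins, using the sum-of-small-p rule: the p-value is the sum
#' of the point probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a relative
#' slack of 1e-7 to absorb floating-point ties, matching mainstream
#' implementations).
#'
#' @param table A `"contingency_2x2"`.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(contingency_2x2(10, 29, 6, 0))
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b        # positive-class margin
  n <- c + d
  kk <- a + c       # test-positive margin
  support <- max(0L, kk - n):min(kk, m)
  dens <- stats::dhyper(support, m, n, kk)
  d_obs <- stats::dhyper(a, m, n, kk)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Binomial proportion confidence interval
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param method `"wilson"` (score interval, the default) or
#'   `"clopper_pearson"` (exact beta-quantile interval).
#' @param conf_level Two-sided confidence level.
#' @return Numeric vector `c(lower, upper)`, a subset of `[0, 1]` containing
#'   `k / n`.
#' @examples
#' proportion_ci(37, 38, "wilson")
#' proportion_ci(5, 6, "clopper_pearson")
#' @export
proportion_ci <- function(k, n, method = c("wilson", "clopper_pearson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  k <- stop_if_not_count(k, "k")
  n <- stop_if_not_count(n, "n")
  if (n < 1L || k > n) stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  alpha <- 1 - conf_level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    ci <- c(centre - half, centre + half)
  } else {
    lower <- if (k == 0L) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
    ci <- c(lower, upper)
  }
  pmin(pmax(ci, 0), 1)
}

#' Odds ratio with Woolf confidence interval
#'
#' When any cell is zero, the Haldane-Anscombe correction adds 0.5 to every
#' cell before computing both the odds ratio and its interval; otherwise raw
#' counts are used. The interval is the Woolf log-odds-ratio interval,
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table A `"contingency_2x2"`.
#' @param conf_level Two-sided confidence level.
#' @return List with elements `or`, `ci` (length-2 numeric) and `corrected`
#'   (logical, whether the 0.5 correction was applied).
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0L)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), corrected = corrected)
}

#' Positive likelihood ratio
#'
#' `LR+ = sensitivity / (1 - specificity)`; returned as `Inf` when
#' specificity is 1 (a positive test is then never seen in class-negatives).
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return A single number, possibly `Inf`.
#' @examples
#' positive_likelihood_ratio(1.0, 37 / 39)  # 19.5
#' @export
positive_likelihood_ratio <- function(sensitivity, specificity) {
  stopifnot(is.numeric(sensitivity), is.numeric(specificity),
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (specificity >= 1) return(Inf)
  sensitivity / (1 - specificity)
}

#' Full diagnostic metric panel for a 2x2 table
#'
#' Sensitivity `a/(a+b)`, specificity `d/(c+d)`, PPV `a/(a+c)` and NPV
#' `d/(b+d)` with two-sided confidence intervals, the odds ratio with Woolf
#' interval, the positive likelihood ratio and the two-sided Fisher exact
#' p-value. A zero denominator yields `NA` for that metric (and its interval)
#' rather than an error.
#'
#' @param table A `"contingency_2x2"`.
#' @param ci_method Proportion interval method, see [proportion_ci()].
#' @param conf_level Two-sided confidence level.
#' @return An object of class `"diagnostic_metrics"`: a list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv` (each `list(estimate, ci)`),
#'   `odds_ratio`, `lr_positive`, `fisher_p` and the orientation metadata.
#' @examples
#' # benign-positive orientation, test-positive = STIR discrepancy absent
#' tab <- contingency_2x2(37, 2, 1, 5, positive_class = "B",
#'                        test_positive = "STIR discrepancy absent")
#' diagnostic_metrics(tab)
#' @export
diagnostic_metrics <- function(table, ci_method = c("wilson", "clopper_pearson"),
                               conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  ci_method <- match.arg(ci_method)
  prop <- function(k, n) {
    if (n == 0L) return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_)))
    list(estimate = k / n,
         ci = proportion_ci(k, n, ci_method, conf_level))
  }
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  sens <- prop(a, a + b)
  spec <- prop(d, c + d)
  lr <- if (is.na(sens$estimate) || is.na(spec$estimate)) NA_real_ else
    positive_likelihood_ratio(sens$estimate, spec$estimate)
  structure(list(
    sensitivity = sens, specificity = spec,
    ppv = prop(a, a + c), npv = prop(d, b + d),
    odds_ratio = odds_ratio_ci(table, conf_level),
    lr_positive = lr,
    fisher_p = fisher_exact_2x2(table),
    positive_class = table$positive_class,
    test_positive = table$test_positive,
    counts = c(a = a, b = b, c = c, d = d)
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 3, ...) {
  fmt <- function(m) {
    if (is.na(m$estimate)) return("   NA (undefined)")
    sprintf("%5.1f%% [%.1f to %.1f]", 100 * m$estimate,
            100 * m$ci[1], 100 * m$ci[2])
  }
  cat("<diagnostic_metrics> positive class:", x$positive_class,
      "| test-positive:", x$test_positive, "\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat(sprintf("  OR: %.3g [%.3g to %.3g]%s | LR+: %s | Fisher p: %.4g\n",
              x$odds_ratio$or, x$odds_ratio$ci[1], x$odds_ratio$ci[2],
              if (x$odds_ratio$corrected) " (0.5-corrected)" else "",
              if (is.na(x$lr_positive)) "NA" else
                format(x$lr_positive, digits = 3),
              x$fisher_p))
  invisible(x)
}
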