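#' ROC curve, AUC and Youden statistics for a continuous predictor
#'
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' values plus `-Inf`/`+Inf` sentinels. Sensitivity and specificity are
#' reported in the ALT-positive orientation. The direction is chosen so that
#' the AUC is at least 0.5: `"greater"` means larger values call ALT. The
#' AUC is computed by the trapezoid rule over the ROC points and equals the
#' tie-corrected Mann-Whitney rank statistic `U / (n1 * n2)` (both values
#' are kept in the result).
#'
#' @param values Numeric predictor (finite; `NA` pairs are dropped).
#' @param labels Class labels, containing both classes.
#' @param positive Label of the positive class (default `"ALT"`).
#' @return An object of class `"roc_result"`: `thresholds`, `sensitivity`,
#'   `specificity` (parallel vectors), `auc`, `auc_rank`, `youden` (J*),
#'   `cutoff`, `direction` (`"greater"`/`"less"`), `degenerate` flag, plus
#'   the input data for downstream binarization.
#' @examples
#' roc_curve(c(1, 2, 3, 4, 5), c("B", "B", "B", "ALT", "ALT"))
#' @export
roc_curve <- function(values, labels, positive = "ALT") {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present (positive = '", positive, "')",
         call. = FALSE)
  }
  # rank AUC for the greater-is-positive orientation, with tie correction
  r <- rank(values)
  auc_g <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_g >= 0.5) "greater" else "less"
  sv <- sort(unique(values))
  mids <- if (length(sv) > 1L) (sv[-1] + sv[-length(sv)]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  sens <- spec <- numeric(length(thresholds))
  vp <- values[pos]
  vn <- values[!pos]
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    if (direction == "greater") {
      sens[i] <- mean(vp > t)
      spec[i] <- mean(vn <= t)
    } else {
      sens[i] <- mean(vp < t)
      spec[i] <- mean(vn >= t)
    }
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc_trap <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  auc_rank <- if (direction == "greater") auc_g else 1 - auc_g
  j <- sens + spec - 1
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc_trap, auc_rank = auc_rank,
                 youden = max(j), direction = direction,
                 positive = positive, values = values, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (direction: %s is %s), J* = %.3f\n",
              x$auc, x$direction, x$positive, x$youden))
  invisible(x)
}

#' Youden-index optimal dichotomization
#'
#' Picks the threshold maximizing Youden's J = sensitivity + specificity - 1.
#' Ties at the maximum are broken toward the threshold with the higher
#' sensitivity for the positive class (an ALT should not be missed), then
#' toward the smaller absolute threshold value. Degenerate predictors (J* =
#' 0, e.g. all values identical) are flagged and yield an `NA` cut-off.
#'
#' @param roc A `"roc_result"`.
#' @param feature Name to record for the source feature.
#' @return An object of class `"binarized_feature"`: `feature`, `cutoff`,
#'   `direction`, `youden`, `sensitivity`/`specificity` at the cut-off,
#'   `degenerate` flag and the 0/1 `column` obtained by applying the cut-off
#'   to the source values.
#' @export
youden_cutoff <- function(roc, feature = "feature") {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  jmax <- max(j)
  cand <- which(j >= jmax - 1e-12)
  cand <- cand[order(-roc$sensitivity[cand], abs(roc$thresholds[cand]))]
  best <- cand[1]
  cutoff <- roc$thresholds[best]
  degenerate <- jmax <= 1e-12 || !is.finite(cutoff)
  column <- apply_cutoff(roc$values, cutoff, roc$direction)
  structure(list(feature = feature, cutoff = cutoff,
                 direction = roc$direction, youden = jmax,
                 sensitivity = roc$sensitivity[best],
                 specificity = roc$specificity[best],
                 degenerate = degenerate, column = column),
            class = "binarized_feature")
}

#' Apply a dichotomization cut-off
#'
#' @param values Numeric vector.
#' @param cutoff Threshold value (`NA` gives all-`NA` output).
#' @param direction `"greater"`: positive when `value > cutoff`; `"less"`:
#'   positive when `value < cutoff`.
#' @return Integer 0/1 vector (`NA` where `values` is `NA`).
#' @export
apply_cutoff <- function(values, cutoff, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (is.na(cutoff)) return(rep(NA_integer_, length(values)))
  if (direction == "greater") as.integer(values > cutoff)
  else as.integer(values < cutoff)
}

#' @export
print.binarized_feature <- function(x, ...) {
  cat(sprintf("<binarized_feature> %s: positive when %s %s %s (J* = %.3f%s)\n",
              x$feature, "value", if (x$direction == "greater") ">" else "<",
              format(x$cutoff), x$youden,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Dichotomize continuous cohort features via ROC/Youden
#'
#' Runs [roc_curve()] + [youden_cutoff()] for each requested feature on the
#' full sample and appends the resulting 0/1 columns (same names) to a copy
#' of the cohort.
#'
#' @param cohort Cohort `data.frame`.
#' @param features Continuous feature names.
#' @param class_col Class column.
#' @param positive Positive class label.
#' @return List with `cohort` (binary columns replacing the continuous ones,
#'   originals kept as `<name>_raw`) and `cutoffs` (named list of
#'   `"binarized_feature"`).
#' @export
dichotomize_cohort <- function(cohort, features, class_col = "group",
                               positive = "ALT") {
  cutoffs <- list()
  out <- cohort
  for (f in features) {
    roc <- roc_curve(cohort[[f]], cohort[[class_col]], positive = positive)
    bf <- youden_cutoff(roc, feature = f)
    cutoffs[[f]] <- bf
    out[[paste0(f, "_raw")]] <- cohort[[f]]
    col <- rep(NA_integer_, nrow(cohort))
    keep <- !is.na(cohort[[f]]) & !is.na(cohort[[class_col]])
    col[!is.na(cohort[[f]])] <- apply_cutoff(
      cohort[[f]][!is.na(cohort[[f]])], bf$cutoff, bf$direction)
    out[[f]] <- col
  }
  list(cohort = out, cutoffs = cutoffs)
}
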