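#' Fit a smoothed naive Bayes classifier on discrete features
#'
#' The Bayes network is fixed to the naive structure (class node parenting
#' every feature). Class priors are `(count + alpha) / (n + alpha * K)` and
#' each per-feature conditional table `P(state | class)` is smoothed the
#' same way with `alpha` pseudo-counts per cell, so every probability is
#' strictly positive for `alpha > 0`. With `alpha = 0` the tables are
#' maximum-likelihood and zero cells are permitted.
#'
#' @param data Training `data.frame`.
#' @param features Discrete (binary/categorical) feature columns.
#' @param class_col Class column; both classes should be present (an absent
#'   class survives through smoothing alone, with a warning).
#' @param alpha Smoothing pseudo-count per cell (default 0.5).
#' @param class_levels Class levels; defaults to `c("B", "ALT")` when those
#'   are the observed labels, otherwise the sorted observed labels.
#' @return An object of class `"nb_model"`: `priors` (named numeric),
#'   `tables` (per feature, a states x classes matrix of conditional
#'   probabilities whose columns sum to 1), `unseen` (per feature, the
#'   smoothed probability of a state never observed in training), `alpha`.
#' @examples
#' d <- data.frame(group = c("B", "B", "ALT"), f = c(0, 0, 1))
#' m <- nb_fit(d, "f", alpha = 0.5)
#' predict(m, data.frame(f = c(0, 1)))
#' @export
nb_fit <- function(data, features, class_col = "group", alpha = 0.5,
                   class_levels = NULL) {
  stopifnot(is.data.frame(data), length(features) >= 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("'alpha' must be a single non-negative number", call. = FALSE)
  }
  missing_cols <- setdiff(c(features, class_col), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cls_raw <- data[[class_col]]
  if (is.null(class_levels)) {
    obs <- unique(stats::na.omit(as.character(cls_raw)))
    class_levels <- if (setequal(obs, c("B", "ALT"))) c("B", "ALT") else
      sort(obs)
  }
  cls <- factor(as.character(cls_raw), levels = class_levels)
  if (anyNA(cls)) stop("class column contains labels outside class_levels",
                       call. = FALSE)
  K <- length(class_levels)
  counts <- table(cls)
  if (any(counts == 0)) {
    warning("class '", paste(class_levels[counts == 0], collapse = ", "),
            "' absent from training data; relying on smoothing only")
  }
  n <- length(cls)
  priors <- (as.numeric(counts) + alpha) / (n + alpha * K)
  names(priors) <- class_levels
  tables <- list()
  unseen <- list()
  for (f in features) {
    v <- factor(as.character(data[[f]]))
    tab <- unclass(table(v, cls))             # states x classes, counts
    J <- nrow(tab)
    denom <- colSums(tab) + alpha * J
    cond <- sweep(tab + alpha, 2L, denom, "/")
    tables[[f]] <- cond
    # a state never seen in training behaves like a smoothed zero-count cell
    unseen[[f]] <- alpha / denom
  }
  structure(list(priors = priors, tables = tables, unseen = unseen,
                 alpha = alpha, features = features,
                 class_levels = class_levels, n_train = n),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> naive Bayes,", length(x$features), "features, alpha =",
      x$alpha, "\n  priors:",
      paste(sprintf("%s %.3f", names(x$priors), x$priors), collapse = " | "),
      "\n")
  invisible(x)
}

#' Posterior class probabilities from a naive Bayes model
#'
#' Posteriors are proportional to `prior * prod(conditionals)`, accumulated
#' in log space and normalized to sum to 1. A feature state never seen in
#' training is handled through the smoothed table (an all-pseudo-count
#' cell); a missing feature value is skipped, i.e. marginalized by omission,
#' and the affected feature names are recorded in the `"skipped"` attribute.
#' If every class has zero likelihood (possible only with `alpha = 0`), the
#' priors are returned for that row.
#'
#' @param object An `"nb_model"`.
#' @param newdata `data.frame` containing the model's feature columns.
#' @param type `"prob"` for a posterior matrix (rows sum to 1) or `"class"`
#'   for the maximum-posterior label.
#' @param ... Unused.
#' @return A numeric matrix (rows = instances, columns = classes) or a
#'   character vector of class labels.
#' @export
predict.nb_model <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  K <- length(object$class_levels)
  n <- nrow(newdata)
  logpost <- matrix(rep(log(object$priors), each = n), nrow = n)
  skipped <- character(0)
  for (f in object$features) {
    if (!f %in% names(newdata)) {
      skipped <- c(skipped, f)
      next
    }
    v <- as.character(newdata[[f]])
    tab <- object$tables[[f]]
    idx <- match(v, rownames(tab))
    for (k in seq_len(K)) {
      p <- tab[idx, k]
      p[is.na(idx) & !is.na(v)] <- object$unseen[[f]][k]
      p[is.na(v)] <- 1                        # missing: marginalized out
      logpost[, k] <- logpost[, k] + log(p)
    }
    if (anyNA(v)) skipped <- unique(c(skipped, f))
  }
  m <- apply(logpost, 1L, max)
  post <- exp(logpost - m)
  bad <- !is.finite(m)                        # all-zero likelihood rows
  if (any(bad)) post[bad, ] <- matrix(object$priors, sum(bad), K,
                                      byrow = TRUE)
  post <- post / rowSums(post)
  colnames(post) <- object$class_levels
  attr(post, "skipped") <- skipped
  if (type == "class") {
    out <- object$class_levels[max.col(post, ties.method = "first")]
    attr(out, "skipped") <- skipped
    return(out)
  }
  post
}

#' Cross-validated evaluation of the naive Bayes classifier
#'
#' Splits the cohort into `k_folds` seeded unstratified folds (the same fold
#' engine as [cv_rank_features()]), fits the model on each training split
#' and pools the out-of-fold posteriors. The metric panel follows the usual
#' discrete-classifier conventions: correct classification rate (CCR, %),
#' mean absolute error of the class-probability estimates (MAE, the mean
#' over instances of the mean over classes of |posterior - indicator|),
#' class-frequency-weighted true and false positive rates and precision
#' (TP_avg, FP_avg, P_avg, %; a class never predicted contributes precision
#' 0), and the ROC AUC of the pooled positive-class posterior.
#'
#' @param cohort Cohort `data.frame`.
#' @param features Discrete feature columns.
#' @param class_col Class column.
#' @param k_folds Number of folds (default 30).
#' @param seed Fold-shuffle seed.
#' @param alpha Smoothing pseudo-count, see [nb_fit()].
#' @param positive Positive class for the AUC (default `"ALT"`).
#' @return An object of class `"nb_cv_report"`: `ccr`, `mae`, `tp_avg`,
#'   `fp_avg`, `p_avg`, `auc`, plus the pooled `posterior` matrix, the
#'   `predicted` labels and the fold assignment.
#' @export
nb_cv_evaluate <- function(cohort, features, class_col = "group",
                           k_folds = 30L, seed = 1L, alpha = 0.5,
                           positive = "ALT") {
  n <- nrow(cohort)
  fold <- make_folds(n, k_folds, seed)
  truth <- as.character(cohort[[class_col]])
  class_levels <- if (setequal(unique(truth), c("B", "ALT")))
    c("B", "ALT") else sort(unique(truth))
  post <- matrix(NA_real_, n, length(class_levels),
                 dimnames = list(NULL, class_levels))
  for (f in seq_len(k_folds)) {
    test <- fold == f
    model <- withCallingHandlers(
      nb_fit(cohort[!test, , drop = FALSE], features, class_col,
             alpha = alpha, class_levels = class_levels),
      warning = function(w) {
        message("fold ", f, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    post[test, ] <- predict(model, cohort[test, , drop = FALSE],
                            type = "prob")
  }
  predicted <- class_levels[max.col(post, ties.method = "first")]
  ccr <- 100 * mean(predicted == truth)
  indicator <- outer(truth, class_levels, "==") * 1
  mae <- mean(rowMeans(abs(post - indicator)))
  w <- vapply(class_levels, function(cl) mean(truth == cl), numeric(1))
  tp_rate <- vapply(class_levels, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1))
  fp_rate <- vapply(class_levels, function(cl) {
    mean(predicted[truth != cl] == cl)
  }, numeric(1))
  precision <- vapply(class_levels, function(cl) {
    pred_cl <- predicted == cl
    if (!any(pred_cl)) return(0)
    mean(truth[pred_cl] == cl)
  }, numeric(1))
  auc <- roc_curve(post[, positive], truth, positive = positive)$auc
  structure(list(
    ccr = ccr, mae = mae,
    tp_avg = 100 * sum(w * tp_rate),
    fp_avg = 100 * sum(w * fp_rate),
    p_avg = 100 * sum(w * precision),
    auc = auc,
    posterior = post, predicted = predicted, fold = fold,
    k_folds = k_folds, seed = seed, alpha = alpha
  ), class = "nb_cv_report")
}

#' @export
print.nb_cv_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<nb_cv_report> %d-fold CV (seed %d, alpha %.2g)\n",
    "  CCR %.1f%% | MAE %.4f | TP_avg %.1f%% | FP_avg %.1f%% | ",
    "P_avg %.1f%% | ROC AUC %.3f\n"),
    x$k_folds, x$seed, x$alpha, x$ccr, x$mae, x$tp_avg, x$fp_avg,
    x$p_avg, x$auc))
  invisible(x)
}
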