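#' Shannon entropy of a count vector
#'
#' `H = -sum(p_i * log2(p_i))` over the non-zero categories, in bits.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(5, 5))   # 1 bit
#' shannon_entropy(c(39, 6))  # ~0.5665 bits
#' @export
shannon_entropy <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L || any(is.na(counts)) ||
      any(counts < 0)) {
    stop("'counts' must be non-negative numbers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Gain ratio of a categorical feature for the class
#'
#' `GR = (H(class) - H(class | feature)) / H(feature)`: the information the
#' feature carries about the class, normalized by the feature's own entropy
#' so that multi-valued features are not automatically favoured. The value
#' lies in `[0, 1]`; it is 0 when the information gain is 0 and `NA`
#' (undefined) when the feature is constant. Pairs with a missing value in
#' either vector are dropped.
#'
#' @param feature Categorical (or 0/1) vector.
#' @param class Class labels, at least two distinct values.
#' @return The gain ratio, or `NA_real_` for a constant feature.
#' @examples
#' cls <- rep(c("B", "ALT"), c(39, 6))
#' gain_ratio(cls, cls)  # 1: feature identical to class
#' @export
gain_ratio <- function(feature, class) {
  keep <- !is.na(feature) & !is.na(class)
  feature <- feature[keep]
  class <- class[keep]
  if (length(class) == 0L || length(unique(class)) < 2L) {
    stop("class column must contain at least two classes", call. = FALSE)
  }
  if (length(unique(feature)) < 2L) return(NA_real_)
  tab <- table(feature, class)
  n <- sum(tab)
  h_class <- shannon_entropy(colSums(tab))
  h_feat <- shannon_entropy(rowSums(tab))
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    w <- sum(tab[i, ]) / n
    if (w == 0) 0 else w * shannon_entropy(tab[i, ])
  }, numeric(1)))
  ig <- h_class - h_cond
  max(ig, 0) / h_feat
}

#' Deterministic fold assignment for k-fold cross-validation
#'
#' Seeded unstratified shuffle into `k` near-equal folds (sizes differ by at
#' most one). Stratification is deliberately not offered: with 6 ALT cases
#' and 30 folds it is impossible, and the same fold engine is shared by the
#' feature ranking and the naive Bayes evaluation.
#'
#' @param n Number of instances.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
make_folds <- function(n, k, seed = 1L) {
  n <- stop_if_not_count(n, "n")
  k <- stop_if_not_count(k, "k")
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (k > n) stop("k_folds (", k, ") exceeds the number of instances (", n,
                  ")", call. = FALSE)
  base <- n %/% k
  sizes <- base + as.integer(seq_len(k) <= n %% k)
  fold <- integer(n)
  fold[with_seed(seed, sample.int(n))] <- rep(seq_len(k), times = sizes)
  fold
}

#' Cross-validated gain-ratio feature ranking
#'
#' For each CV fold the gain ratio of every feature is computed on the
#' training split (all instances outside the fold); features are then ranked
#' within each fold (rank 1 = largest merit, ties share the mean rank). The
#' report gives the per-feature mean and SD of the merit and of the rank
#' across folds, plus the full-data gain ratio, sorted by average rank.
#' Features must already be categorical or binary; continuous predictors are
#' dichotomized upstream (see [dichotomize_cohort()]). A merit that is
#' undefined on some training split (constant feature there) counts as 0 in
#' that fold.
#'
#' @param cohort Cohort `data.frame`.
#' @param features Feature column names (categorical/binary).
#' @param class_col Class column.
#' @param k_folds Number of folds (default 30).
#' @param seed Seed for the fold shuffle.
#' @return A `data.frame` of class `"ranked_features"` with columns
#'   `feature`, `merit_mean`, `merit_sd`, `rank_mean`, `rank_sd`,
#'   `gain_ratio_full`, sorted by `rank_mean` (ties: smaller `rank_sd`, then
#'   name). The fold assignment seed is kept in attribute `"seed"`.
#' @examples
#' cohort <- data.frame(
#'   group = rep(c("B", "ALT"), c(39, 6)),
#'   stir = rep(c(0, 1, 0, 1), c(37, 2, 1, 5)),
#'   ce   = rep(c(0, 1, 1), c(29, 10, 6)))
#' cv_rank_features(cohort, c("stir", "ce"), k_folds = 30, seed = 42)
#' @export
cv_rank_features <- function(cohort, features, class_col = "group",
                             k_folds = 30L, seed = 1L) {
  stopifnot(length(features) >= 1L)
  missing_cols <- setdiff(c(features, class_col), names(cohort))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  suspect <- features[vapply(features, function(f) {
    v <- cohort[[f]]
    is.numeric(v) && length(unique(stats::na.omit(v))) > 10L
  }, logical(1))]
  if (length(suspect)) {
    warning("feature(s) ", paste(suspect, collapse = ", "),
            " look continuous (many distinct numeric values); the gain ",
            "ratio treats every distinct value as a category - ",
            "dichotomize first (see dichotomize_cohort())", call. = FALSE)
  }
  fold <- make_folds(n, k_folds, seed)
  merits <- matrix(NA_real_, nrow = k_folds, ncol = length(features),
                   dimnames = list(NULL, features))
  for (f in seq_len(k_folds)) {
    train <- fold != f
    cls <- cohort[[class_col]][train]
    merits[f, ] <- vapply(features, function(ft) {
      gr <- gain_ratio(cohort[[ft]][train], cls)
      if (is.na(gr)) 0 else gr
    }, numeric(1))
  }
  ranks <- t(apply(-merits, 1L, rank, ties.method = "average"))
  if (length(features) == 1L) ranks <- matrix(1, k_folds, 1)
  full <- vapply(features, function(ft)
    gain_ratio(cohort[[ft]], cohort[[class_col]]), numeric(1))
  out <- data.frame(
    feature = features,
    merit_mean = colMeans(merits),
    merit_sd = apply(merits, 2L, stats::sd),
    rank_mean = colMeans(ranks),
    rank_sd = apply(ranks, 2L, stats::sd),
    gain_ratio_full = full,
    row.names = NULL)
  out <- out[order(out$rank_mean, out$rank_sd, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "k_folds") <- k_folds
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' @export
print.ranked_features <- function(x, digits = 3, ...) {
  cat("Cross-validated gain-ratio ranking (", attr(x, "k_folds"),
      " folds, seed ", attr(x, "seed"), ")\n", sep = "")
  df <- data.frame(
    Feature = x$feature,
    `Avg rank` = sprintf("%.1f ± %.2f", x$rank_mean, x$rank_sd),
    `Gain-ratio merit` = sprintf("%.3f ± %.3f", x$merit_mean, x$merit_sd),
    `Full-data GR` = sprintf("%.3f", x$gain_ratio_full),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
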