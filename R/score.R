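#' Assemble a score definition from a ranking and dichotomization cut-offs
#'
#' Takes the `top_k` features by average cross-validated rank (ties broken
#' toward the smaller rank SD, then lexicographic name) and turns each into
#' a score item: continuous features become threshold items using their
#' Youden cut-off and direction, binary features award the point for their
#' positive state. One point per positive item; the patient is called ALT
#' when the total reaches `decision_cutoff`.
#'
#' @param ranking A `"ranked_features"` data frame (see
#'   [cv_rank_features()]).
#' @param cutoffs Named list of `"binarized_feature"` objects (see
#'   [youden_cutoff()]) for the continuous features.
#' @param top_k Number of items (default 5).
#' @param decision_cutoff Minimum score that calls ALT (default 3).
#' @param continuous_features Names of features that require a cut-off;
#'   defaults to `names(cutoffs)`. Selecting a continuous feature without a
#'   cut-off is an error naming the feature.
#' @param positive_state State of a binary item that scores the point
#'   (default `1`).
#' @return An object of class `"score_definition"`: a list of items (each
#'   `feature`, `type`, `cutoff`, `direction` or `positive_state`) plus
#'   `decision_cutoff` and `range = c(0, length(items))`.
#' @export
build_score <- function(ranking, cutoffs = list(), top_k = 5L,
                        decision_cutoff = 3L,
                        continuous_features = names(cutoffs),
                        positive_state = 1) {
  stopifnot(inherits(ranking, "data.frame"), nrow(ranking) >= 1L)
  top_k <- stop_if_not_count(top_k, "top_k")
  if (top_k < 1L || top_k > nrow(ranking)) {
    stop("top_k must be between 1 and the number of ranked features",
         call. = FALSE)
  }
  ord <- order(ranking$rank_mean, ranking$rank_sd, ranking$feature)
  selected <- ranking$feature[ord][seq_len(top_k)]
  items <- lapply(selected, function(f) {
    if (f %in% names(cutoffs)) {
      bf <- cutoffs[[f]]
      if (is.na(bf$cutoff)) {
        stop("feature '", f, "' has a degenerate cut-off", call. = FALSE)
      }
      list(feature = f, type = "threshold", cutoff = bf$cutoff,
           direction = bf$direction)
    } else if (f %in% continuous_features) {
      stop("continuous feature '", f,
           "' selected for the score but no cut-off was supplied",
           call. = FALSE)
    } else {
      list(feature = f, type = "binary", positive_state = positive_state)
    }
  })
  score_definition(items, decision_cutoff = decision_cutoff)
}

#' Construct a score definition directly
#'
#' @param items List of items; each item is a list with `feature`, `type`
#'   (`"threshold"` or `"binary"`) and either `cutoff` + `direction`
#'   (`"greater"`/`"less"`) or `positive_state`.
#' @param decision_cutoff Minimum total that calls ALT; must lie within the
#'   score range `0..length(items)`.
#' @return An object of class `"score_definition"`.
#' @export
score_definition <- function(items, decision_cutoff = 3L) {
  stopifnot(is.list(items), length(items) >= 1L)
  decision_cutoff <- stop_if_not_count(decision_cutoff, "decision_cutoff")
  if (decision_cutoff > length(items)) {
    stop("decision_cutoff (", decision_cutoff,
         ") outside the score range 0..", length(items), call. = FALSE)
  }
  for (it in items) {
    if (!all(c("feature", "type") %in% names(it)) ||
        !it$type %in% c("threshold", "binary")) {
      stop("each item needs 'feature' and 'type' in {threshold, binary}",
           call. = FALSE)
    }
    if (it$type == "threshold" &&
        (!is.numeric(it$cutoff) ||
         !it$direction %in% c("greater", "less"))) {
      stop("threshold item '", it$feature,
           "' needs a numeric cutoff and a direction", call. = FALSE)
    }
  }
  structure(list(items = items, decision_cutoff = decision_cutoff,
                 range = c(0L, length(items))),
            class = "score_definition")
}

#' The published five-item ALT score
#'
#' One point each for maximum diameter > 125.5 mm, orthogonal diameter >
#' 39.5 mm, maximum septation thickness > 1.3 mm, presence of contrast
#' enhancement, and intratumoral STIR fluid signal without surrounding
#' fluid; ALT is called at 3 or more points. The same definition ships as
#' JSON under `inst/extdata/alt_score_definition.json`.
#'
#' @return A `"score_definition"` with five items and decision cut-off 3.
#' @export
default_score_definition <- function() {
  score_definition(list(
    list(feature = "septation_thickness", type = "threshold",
         cutoff = 1.3, direction = "greater"),
    list(feature = "stir_discrepancy", type = "binary", positive_state = 1),
    list(feature = "diameter_y", type = "threshold",
         cutoff = 39.5, direction = "greater"),
    list(feature = "contrast_enhancement", type = "binary",
         positive_state = 1),
    list(feature = "diameter_x", type = "threshold",
         cutoff = 125.5, direction = "greater")
  ), decision_cutoff = 3L)
}

#' @export
print.score_definition <- function(x, ...) {
  cat("<score_definition> ", length(x$items), " items, ALT called at >= ",
      x$decision_cutoff, " points\n", sep = "")
  for (it in x$items) {
    if (it$type == "threshold") {
      cat(sprintf("  + %s %s %s\n", it$feature,
                  if (it$direction == "greater") ">" else "<",
                  format(it$cutoff)))
    } else {
      cat(sprintf("  + %s == %s\n", it$feature, format(it$positive_state)))
    }
  }
  invisible(x)
}

#' Score patients with a score definition
#'
#' The score is the count of positive items (an integer in
#' `0..length(items)`). A missing item value scores 0 for that item and is
#' flagged; the flags are returned in the `"missing_items"` attribute (an
#' instances x items logical matrix).
#'
#' @param definition A `"score_definition"`.
#' @param data `data.frame` of patients (or a single row).
#' @return Integer vector of scores with attribute `"missing_items"`.
#' @export
apply_score <- function(definition, data) {
  stopifnot(inherits(definition, "score_definition"), is.data.frame(data))
  n <- nrow(data)
  k <- length(definition$items)
  pos <- matrix(FALSE, n, k)
  miss <- matrix(FALSE, n, k,
                 dimnames = list(NULL, vapply(definition$items, `[[`,
                                              character(1), "feature")))
  for (j in seq_len(k)) {
    it <- definition$items[[j]]
    if (!it$feature %in% names(data)) {
      miss[, j] <- TRUE
      next
    }
    v <- data[[it$feature]]
    p <- if (it$type == "threshold") {
      if (it$direction == "greater") v > it$cutoff else v < it$cutoff
    } else {
      v == it$positive_state
    }
    miss[, j] <- is.na(p)
    p[is.na(p)] <- FALSE
    pos[, j] <- p
  }
  out <- as.integer(rowSums(pos))
  attr(out, "missing_items") <- miss
  out
}

#' Evaluate a score on a labelled cohort
#'
#' Scores every patient, then, for each decision cut-off `t` in
#' `0..length(items)`, forms the 2x2 table in the ALT-positive orientation
#' (test-positive = score >= t) and derives the metric panel through
#' [diagnostic_metrics()]: CCR, sensitivity, specificity (with intervals),
#' the positive likelihood ratio and the Fisher p. The integer score's ROC
#' AUC and the per-group score means with t-based 95% intervals complete
#' the report.
#'
#' @param cohort Labelled cohort `data.frame`.
#' @param definition A `"score_definition"`.
#' @param class_col Class column (values `B`/`ALT`; both must be present).
#' @param ci_method Proportion interval method, see [proportion_ci()].
#' @return An object of class `"score_report"`: `scores` (per patient),
#'   `by_cutoff` (data frame over cut-offs 0..k with counts and metrics),
#'   `auc`, `group_means` and the `definition`.
#' @export
evaluate_score <- function(cohort, definition, class_col = "group",
                           ci_method = "wilson") {
  stopifnot(inherits(definition, "score_definition"))
  truth <- as.character(cohort[[class_col]])
  if (length(unique(stats::na.omit(truth))) < 2L) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  scores <- apply_score(definition, cohort)
  k <- length(definition$items)
  is_alt <- truth == "ALT"
  rows <- lapply(0:k, function(t) {
    test_pos <- scores >= t
    tab <- contingency_2x2(sum(is_alt & test_pos), sum(is_alt & !test_pos),
                           sum(!is_alt & test_pos), sum(!is_alt & !test_pos),
                           positive_class = "ALT",
                           test_positive = paste0("score >= ", t))
    dm <- diagnostic_metrics(tab, ci_method = ci_method)
    data.frame(
      cutoff = t, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      ccr = 100 * (tab$a + tab$d) / sum(unlist(tab[c("a", "b", "c", "d")])),
      sensitivity = 100 * dm$sensitivity$estimate,
      sens_lo = 100 * dm$sensitivity$ci[1],
      sens_hi = 100 * dm$sensitivity$ci[2],
      specificity = 100 * dm$specificity$estimate,
      spec_lo = 100 * dm$specificity$ci[1],
      spec_hi = 100 * dm$specificity$ci[2],
      lr_positive = dm$lr_positive,
      fisher_p = dm$fisher_p)
  })
  by_cutoff <- do.call(rbind, rows)
  auc <- roc_curve(scores, truth, positive = "ALT")$auc
  group_means <- do.call(rbind, lapply(c("B", "ALT"), function(g) {
    s <- scores[truth == g]
    n <- length(s)
    se <- stats::sd(s) / sqrt(n)
    half <- stats::qt(0.975, n - 1) * se
    data.frame(group = g, n = n, mean = mean(s),
               ci_lo = mean(s) - half, ci_hi = mean(s) + half)
  }))
  structure(list(scores = scores, by_cutoff = by_cutoff, auc = auc,
                 group_means = group_means, definition = definition,
                 decision_cutoff = definition$decision_cutoff),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  t <- x$decision_cutoff
  row <- x$by_cutoff[x$by_cutoff$cutoff == t, ]
  cat(sprintf(paste0(
    "<score_report> %d-item score, ROC AUC %.3f\n",
    "  at decision cut-off >= %d: CCR %.1f%%, sensitivity %.1f%% ",
    "[%.1f to %.1f], specificity %.1f%% [%.1f to %.1f], LR+ %s\n"),
    length(x$definition$items), x$auc, t, row$ccr,
    row$sensitivity, row$sens_lo, row$sens_hi,
    row$specificity, row$spec_lo, row$spec_hi,
    if (is.infinite(row$lr_positive)) "Inf" else
      sprintf("%.2f", row$lr_positive)))
  gm <- x$group_means
  cat(sprintf("  group means: B %.2f [%.2f to %.2f] | ALT %.2f [%.2f to %.2f]\n",
              gm$mean[gm$group == "B"], gm$ci_lo[gm$group == "B"],
              gm$ci_hi[gm$group == "B"], gm$mean[gm$group == "ALT"],
              gm$ci_lo[gm$group == "ALT"], gm$ci_hi[gm$group == "ALT"]))
  invisible(x)
}

#' Read and write score definitions as JSON
#'
#' @param definition A `"score_definition"`.
#' @param path File path.
#' @return `write_score_definition_json()` returns `path` invisibly;
#'   `read_score_definition_json()` returns a `"score_definition"`.
#' @export
write_score_definition_json <- function(definition, path) {
  stopifnot(inherits(definition, "score_definition"))
  jsonlite::write_json(
    list(decision_cutoff = definition$decision_cutoff,
         items = definition$items),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_definition_json
#' @export
read_score_definition_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  score_definition(lapply(raw$items, function(it) {
    it$cutoff <- if (!is.null(it$cutoff)) as.numeric(it$cutoff)
    it
  }), decision_cutoff = raw$decision_cutoff)
}
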