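#' Fit the full ALT discrimination pipeline on a cohort
#'
#' Runs the complete analysis sequence on a labelled feature table:
#' per-feature two-group comparisons ([compare_cohort()]; descriptive only,
#' never used as a filter), ROC/Youden dichotomization of the continuous
#' predictors ([dichotomize_cohort()]), cross-validated gain-ratio ranking
#' of the resulting binary/categorical predictors ([cv_rank_features()]),
#' naive Bayes cross-validation on the same predictor set
#' ([nb_cv_evaluate()]), and construction plus evaluation of the unweighted
#' additive score from the `top_k` best-ranked predictors ([build_score()],
#' [evaluate_score()]).
#'
#' @param data Labelled cohort `data.frame` (class column with values
#'   `B`/`ALT`).
#' @param class_col Class column name.
#' @param features Feature columns; defaults to everything except the class
#'   column and `patient_id`. Numeric columns with more than two distinct
#'   values are treated as continuous and dichotomized; 0/1 and
#'   character/factor columns are used as-is.
#' @param k_folds Cross-validation folds for ranking and classification.
#' @param seed Seed for the fold shuffles.
#' @param alpha Naive Bayes smoothing pseudo-count.
#' @param top_k Number of score items.
#' @param decision_cutoff Score decision cut-off calling ALT.
#' @param ci_method Proportion interval method (`"wilson"` or
#'   `"clopper_pearson"`).
#' @return An object of class `"alt_fit"` with components `comparisons`,
#'   `cutoffs`, `ranking`, `cv_report`, `score_definition`, `score_report`,
#'   `data` (the dichotomized cohort) and the call parameters.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(), seed = 1)
#' fit <- alt_fit(cohort, seed = 1)
#' fit
#' coef(fit)
#' @export
alt_fit <- function(data, class_col = "group", features = NULL,
                    k_folds = 30L, seed = 1L, alpha = 0.5, top_k = 5L,
                    decision_cutoff = 3L, ci_method = "wilson") {
  stopifnot(is.data.frame(data))
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found", call. = FALSE)
  }
  features <- features %||% setdiff(names(data), c(class_col, "patient_id"))
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    stop("feature columns not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  is_continuous <- vapply(features, function(f) {
    v <- data[[f]]
    is.numeric(v) && length(unique(stats::na.omit(v))) > 2L &&
      !all(stats::na.omit(v) %in% c(0, 1))
  }, logical(1))
  continuous <- features[is_continuous]
  comparisons <- compare_cohort(data, features, class_col = class_col)
  dich <- dichotomize_cohort(data, continuous, class_col = class_col)
  usable <- features[vapply(features, function(f) {
    !isTRUE(dich$cutoffs[[f]]$degenerate)
  }, logical(1))]
  ranking <- cv_rank_features(dich$cohort, usable, class_col = class_col,
                              k_folds = k_folds, seed = seed)
  cv_report <- nb_cv_evaluate(dich$cohort, usable, class_col = class_col,
                              k_folds = k_folds, seed = seed, alpha = alpha)
  score_def <- build_score(ranking, dich$cutoffs, top_k = top_k,
                           decision_cutoff = decision_cutoff,
                           continuous_features = continuous)
  score_report <- evaluate_score(data, score_def, class_col = class_col,
                                 ci_method = ci_method)
  structure(list(
    comparisons = comparisons, cutoffs = dich$cutoffs, ranking = ranking,
    cv_report = cv_report, score_definition = score_def,
    score_report = score_report, data = dich$cohort,
    class_col = class_col, features = features, continuous = continuous,
    k_folds = k_folds, seed = seed, alpha = alpha, top_k = top_k,
    decision_cutoff = decision_cutoff, ci_method = ci_method
  ), class = "alt_fit")
}

#' @export
print.alt_fit <- function(x, ...) {
  cat("ALT discrimination pipeline fit\n")
  cat("  cohort: ", nrow(x$data), " patients (",
      sum(x$data[[x$class_col]] == "B"), " B / ",
      sum(x$data[[x$class_col]] == "ALT"), " ALT), ",
      length(x$features), " features (", length(x$continuous),
      " dichotomized)\n", sep = "")
  cat("  top-ranked predictors: ",
      paste(utils::head(x$ranking$feature, x$top_k), collapse = ", "),
      "\n", sep = "")
  print(x$cv_report)
  print(x$score_report)
  invisible(x)
}

#' @export
summary.alt_fit <- function(object, ...) {
  cat("== Two-group comparisons ==\n")
  print(object$comparisons, row.names = FALSE)
  cat("\n== Youden cut-offs ==\n")
  for (bf in object$cutoffs) print(bf)
  cat("\n== Gain-ratio ranking ==\n")
  print(object$ranking)
  cat("\n== Naive Bayes cross-validation ==\n")
  print(object$cv_report)
  cat("\n== Score ==\n")
  print(object$score_definition)
  print(object$score_report)
  invisible(object)
}

#' Score items of a fitted pipeline
#'
#' @param object An `"alt_fit"`.
#' @param ... Unused.
#' @return A `data.frame` with one row per score item: feature, type,
#'   cut-off and direction (threshold items) or positive state.
#' @export
coef.alt_fit <- function(object, ...) {
  items <- object$score_definition$items
  data.frame(
    feature = vapply(items, `[[`, character(1), "feature"),
    type = vapply(items, `[[`, character(1), "type"),
    cutoff = vapply(items, function(it) it$cutoff %||% NA_real_, numeric(1)),
    direction = vapply(items, function(it) it$direction %||% NA_character_,
                       character(1)),
    positive_state = vapply(items, function(it) {
      if (is.null(it$positive_state)) NA_real_ else
        as.numeric(it$positive_state)
    }, numeric(1)),
    row.names = NULL)
}

#' Predict scores and classes for new patients
#'
#' @param object An `"alt_fit"`.
#' @param newdata `data.frame` of new patients on the original (raw) feature
#'   scale; defaults to the training cohort.
#' @param type `"score"` (integer 0..k), `"class"` (`"ALT"` when the score
#'   reaches the decision cut-off, else `"B"`) or `"posterior"` (naive Bayes
#'   posterior probabilities from a model refitted on the full cohort).
#' @param ... Unused.
#' @return Integer scores, character classes, or a posterior matrix.
#' @export
predict.alt_fit <- function(object, newdata = NULL,
                            type = c("score", "class", "posterior"), ...) {
  type <- match.arg(type)
  raw <- is.null(newdata)
  if (raw) newdata <- object$data
  if (type == "posterior") {
    nd <- newdata
    if (!raw) {
      for (f in object$continuous) {
        bf <- object$cutoffs[[f]]
        if (f %in% names(nd)) {
          nd[[f]] <- apply_cutoff(nd[[f]], bf$cutoff, bf$direction)
        }
      }
    }
    model <- nb_fit(object$data,
                    features = object$ranking$feature,
                    class_col = object$class_col, alpha = object$alpha)
    return(predict(model, nd, type = "prob"))
  }
  # score items expect the raw continuous scale; training data keeps it in
  # the *_raw columns
  nd <- newdata
  if (raw) {
    for (f in object$continuous) nd[[f]] <- nd[[paste0(f, "_raw")]]
  }
  scores <- apply_score(object$score_definition, nd)
  if (type == "score") return(scores)
  ifelse(scores >= object$decision_cutoff, "ALT", "B")
}

#' Plot the ROC curve of the fitted score
#'
#' Base-graphics ROC plot of the integer score against the class labels,
#' with the operating point of the decision cut-off marked.
#'
#' @param x An `"alt_fit"`.
#' @param ... Passed to `plot()`.
#' @export
plot.alt_fit <- function(x, ...) {
  truth <- as.character(x$data[[x$class_col]])
  roc <- roc_curve(x$score_report$scores, truth, positive = "ALT")
  ord <- order(1 - roc$specificity, roc$sensitivity)
  plot(1 - roc$specificity[ord], roc$sensitivity[ord], type = "b",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("Score ROC (AUC = %.3f)", roc$auc),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey50")
  row <- x$score_report$by_cutoff[
    x$score_report$by_cutoff$cutoff == x$decision_cutoff, ]
  points(1 - row$specificity / 100, row$sensitivity / 100, pch = 19,
         col = "red3")
  text(1 - row$specificity / 100, row$sensitivity / 100,
       labels = sprintf(">= %d", x$decision_cutoff), pos = 4, col = "red3")
  invisible(x)
}

#' Run the pipeline end to end from a configuration
#'
#' Orchestrates simulate/read -> compare -> dichotomize -> rank -> classify
#' -> score. The configuration is a list (or a path to a JSON file) with
#' fields `input` (a [cohort_spec()], a CSV path, or `NULL` for the default
#' generator), `class_col`, `seed`, `k_folds`, `alpha`, `top_k`,
#' `decision_cutoff`, `ci_method` and optionally `output_dir`, where a JSON
#' report and per-patient score CSV are written. All randomness flows from
#' `config$seed`; two runs with the same configuration give identical
#' reports apart from the timestamp. A failing stage halts with an error
#' naming the stage; stages already completed are attached to the error
#' condition as `partial`.
#'
#' @param config Configuration list or path to a JSON configuration file.
#' @return An object of class `"run_report"`: the fitted `"alt_fit"`, the
#'   resolved configuration, and a provenance block (config hash, seed,
#'   package version, R version, timestamp).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- list(
    input = config$input %||% NULL,
    class_col = config$class_col %||% "group",
    seed = as.integer(config$seed %||% 1L),
    k_folds = as.integer(config$k_folds %||% 30L),
    alpha = config$alpha %||% 0.5,
    top_k = as.integer(config$top_k %||% 5L),
    decision_cutoff = as.integer(config$decision_cutoff %||% 3L),
    ci_method = config$ci_method %||% "wilson",
    output_dir = config$output_dir %||% NULL)
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- structure(
        class = c("altscore_stage_error", "error", "condition"),
        list(message = paste0("stage '", name, "' failed: ",
                              conditionMessage(e)),
             call = sys.call(-1), stage = name, partial = done))
      stop(cond)
    })
  }
  cohort <- stage("input", {
    inp <- cfg$input
    if (is.null(inp)) {
      simulate_cohort(default_cohort_spec(), seed = cfg$seed)
    } else if (inherits(inp, "cohort_spec")) {
      simulate_cohort(inp, seed = cfg$seed)
    } else if (is.character(inp)) {
      read_cohort_csv(inp, class_col = cfg$class_col)
    } else {
      stop("config$input must be NULL, a cohort_spec or a CSV path")
    }
  })
  done$cohort <- cohort
  fit <- stage("fit", alt_fit(
    cohort, class_col = cfg$class_col, k_folds = cfg$k_folds,
    seed = cfg$seed, alpha = cfg$alpha, top_k = cfg$top_k,
    decision_cutoff = cfg$decision_cutoff, ci_method = cfg$ci_method))
  done$fit <- fit
  hash_cfg <- cfg
  hash_cfg$output_dir <- NULL
  if (inherits(hash_cfg$input, "cohort_spec")) {
    hash_cfg$input <- unclass(hash_cfg$input)
  }
  report <- structure(list(
    fit = fit, config = cfg,
    provenance = list(
      config_hash = config_hash(hash_cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("altscore")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "run_report")
  if (!is.null(cfg$output_dir)) {
    stage("write", write_run_report(report, cfg$output_dir))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> config", x$provenance$config_hash, "seed",
      x$provenance$seed, "\n")
  print(x$fit)
  invisible(x)
}

#' Serialize a run report
#'
#' Writes `report.json` (rankings, CV metrics, score definition and
#' per-cut-off performance, provenance) and `scores.csv` (per-patient id,
#' class and score) into `dir`. Everything except the timestamp is
#' reproducible bit-identically from the configuration and seed.
#'
#' @param report A `"run_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- report$fit
  items <- fit$score_definition$items
  out <- list(
    provenance = report$provenance,
    comparisons = fit$comparisons,
    cutoffs = lapply(fit$cutoffs, function(bf) {
      bf[c("feature", "cutoff", "direction", "youden", "degenerate")]
    }),
    ranking = as.data.frame(fit$ranking),
    cv_report = fit$cv_report[c("ccr", "mae", "tp_avg", "fp_avg", "p_avg",
                                "auc", "k_folds", "seed", "alpha")],
    score_definition = list(items = items,
                            decision_cutoff = fit$decision_cutoff),
    score_by_cutoff = fit$score_report$by_cutoff,
    score_auc = fit$score_report$auc,
    score_group_means = fit$score_report$group_means)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  scores <- data.frame(
    patient_id = fit$data$patient_id %||% seq_along(fit$score_report$scores),
    group = fit$data[[fit$class_col]],
    score = fit$score_report$scores)
  utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(dir)
}
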