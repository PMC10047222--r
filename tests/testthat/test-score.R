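make_ranking <- function(features, rank_mean, rank_sd = rep(0, length(features))) {
  structure(data.frame(feature = features, merit_mean = rev(seq_along(features)) / 10,
                       merit_sd = 0.01, rank_mean = rank_mean, rank_sd = rank_sd,
                       gain_ratio_full = rev(seq_along(features)) / 10),
            class = c("ranked_features", "data.frame"))
}

test_that("build_score selects the five published items", {
  rk <- make_ranking(
    c("septation_thickness", "stir_discrepancy", "diameter_y",
      "contrast_enhancement", "diameter_x", "septation_morphology"),
    rank_mean = c(1.6, 3.0, 3.0, 4.8, 5.5, 6.4))
  cuts <- list(
    septation_thickness = list(feature = "septation_thickness",
                               cutoff = 1.3, direction = "greater"),
    diameter_y = list(feature = "diameter_y", cutoff = 39.5,
                      direction = "greater"),
    diameter_x = list(feature = "diameter_x", cutoff = 125.5,
                      direction = "greater"))
  def <- build_score(rk, cuts, top_k = 5)
  feats <- vapply(def$items, `[[`, character(1), "feature")
  expect_setequal(feats, c("septation_thickness", "stir_discrepancy",
                           "diameter_y", "contrast_enhancement",
                           "diameter_x"))
  st <- def$items[[which(feats == "septation_thickness")]]
  expect_equal(st$cutoff, 1.3)
  expect_equal(st$direction, "greater")
  # single-item score
  def1 <- build_score(rk, cuts, top_k = 1, decision_cutoff = 1)
  expect_equal(length(def1$items), 1L)
  expect_equal(def1$items[[1]]$feature, "septation_thickness")
})

test_that("build_score ties break by rank SD then name, and missing cut-offs fail loudly", {
  rk <- make_ranking(c("zeta", "alpha", "beta"), rank_mean = c(1, 2, 2),
                     rank_sd = c(0, 0.5, 0.5))
  def <- build_score(rk, list(), top_k = 2, decision_cutoff = 1)
  expect_equal(vapply(def$items, `[[`, character(1), "feature"),
               c("zeta", "alpha"))
  rk2 <- make_ranking(c("good", "cont"), rank_mean = c(1, 2))
  expect_error(build_score(rk2, list(), top_k = 2, decision_cutoff = 1,
                           continuous_features = "cont"),
               "'cont'.*no cut-off")
})

test_that("apply_score counts positive items and flags missing ones", {
  def <- default_score_definition()
  alt_means <- data.frame(diameter_x = 171.2, diameter_y = 56.3,
                          septation_thickness = 3.25,
                          contrast_enhancement = 1, stir_discrepancy = 1)
  expect_equal(apply_score(def, alt_means)[1], 5L)
  negative <- data.frame(diameter_x = 50, diameter_y = 20,
                         septation_thickness = 0.5,
                         contrast_enhancement = 0, stir_discrepancy = 0)
  expect_equal(apply_score(def, negative)[1], 0L)
  partial <- alt_means
  partial$septation_thickness <- NA
  s <- apply_score(def, partial)
  expect_equal(s[1], 4L)
  expect_true(attr(s, "missing_items")[1, "septation_thickness"])
})

test_that("score evaluation reproduces the published operating point", {
  # 6/6 ALT at score >= 3 and 2/39 benign at score >= 3
  co <- data.frame(
    group = rep(c("ALT", "B"), c(6, 39)),
    item1 = c(rep(1, 6), rep(1, 2), rep(0, 37)),
    item2 = c(rep(1, 6), rep(1, 2), rep(0, 37)),
    item3 = c(rep(1, 6), rep(1, 2), rep(0, 37)),
    item4 = 0, item5 = 0)
  def <- score_definition(lapply(paste0("item", 1:5), function(f)
    list(feature = f, type = "binary", positive_state = 1)),
    decision_cutoff = 3)
  rep3 <- evaluate_score(co, def)
  row <- rep3$by_cutoff[rep3$by_cutoff$cutoff == 3, ]
  expect_equal(row$sensitivity, 100.0)
  expect_equal(round(row$specificity, 1), 94.9)   # 37/39
  expect_equal(row$lr_positive, 19.5)
  expect_equal(round(row$ccr, 1), 95.6)           # 43/45
})

test_that("an all-positive cohort has sensitivity 100 and specificity 0", {
  co <- data.frame(group = rep(c("ALT", "B"), c(5, 10)),
                   f1 = 1, f2 = 1, f3 = 1, f4 = 1, f5 = 1)
  def <- score_definition(lapply(paste0("f", 1:5), function(f)
    list(feature = f, type = "binary", positive_state = 1)),
    decision_cutoff = 3)
  row <- evaluate_score(co, def)$by_cutoff
  r3 <- row[row$cutoff == 3, ]
  expect_equal(r3$sensitivity, 100)
  expect_equal(r3$specificity, 0)
})

test_that("score metrics agree with diagnostic_metrics and the score ROC", {
  set.seed(53)
  co <- simulate_cohort(default_cohort_spec(), seed = 8)
  def <- default_score_definition()
  rep8 <- evaluate_score(co, def)
  truth <- co$group
  scores <- apply_score(def, co)
  for (t in 0:5) {
    pos <- scores >= t
    tab <- contingency_2x2(sum(truth == "ALT" & pos),
                           sum(truth == "ALT" & !pos),
                           sum(truth == "B" & pos),
                           sum(truth == "B" & !pos))
    dm <- diagnostic_metrics(tab)
    row <- rep8$by_cutoff[rep8$by_cutoff$cutoff == t, ]
    expect_equal(row$sensitivity, 100 * dm$sensitivity$estimate)
    expect_equal(row$specificity, 100 * dm$specificity$estimate)
    expect_equal(row$fisher_p, dm$fisher_p)
  }
  expect_equal(rep8$auc, roc_curve(scores, truth)$auc_rank, tolerance = 1e-12)
})

test_that("decision cut-off must lie in the score range", {
  expect_error(score_definition(list(list(feature = "f", type = "binary",
                                          positive_state = 1)),
                                decision_cutoff = 2),
               "outside the score range")
})

test_that("the shipped JSON definition equals the built-in one", {
  path <- system.file("extdata", "alt_score_definition.json",
                      package = "altscore")
  skip_if(path == "", "extdata not installed")
  shipped <- read_score_definition_json(path)
  builtin <- default_score_definition()
  expect_equal(shipped$decision_cutoff, builtin$decision_cutoff)
  expect_equal(lapply(shipped$items, `[[`, "feature"),
               lapply(builtin$items, `[[`, "feature"))
  expect_equal(lapply(shipped$items, function(i) i$cutoff),
               lapply(builtin$items, function(i) i$cutoff))
  # round trip
  tf <- tempfile(fileext = ".json")
  write_score_definition_json(builtin, tf)
  again <- read_score_definition_json(tf)
  expect_equal(lapply(again$items, `[[`, "feature"),
               lapply(builtin$items, `[[`, "feature"))
})
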