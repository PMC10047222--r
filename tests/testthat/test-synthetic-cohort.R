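test_that("feature and cohort specs reject invalid parameters", {
  expect_error(feature_spec("x", "continuous", mean = c(B = 1, ALT = 2),
                            sd = c(B = 0, ALT = 1)), "must be > 0")
  expect_error(feature_spec("x", "binary", prevalence = c(B = 1.2, ALT = 0.5)),
               "\\[0, 1\\]")
  expect_error(feature_spec("x", "categorical", levels = c("a", "b"),
                            probs = list(B = c(0.6, 0.5), ALT = c(0.5, 0.5))),
               "sum to")
  expect_error(feature_spec("x", "continuous", mean = c(B = 1, ALT = 2),
                            sd = c(B = 1, ALT = 1), lower = 5, upper = 2),
               "lower < upper")
  f <- feature_spec("x", "binary", prevalence = c(B = 0.5, ALT = 0.5))
  expect_error(cohort_spec(list(f), n_B = 1, n_ALT = 0), ">= 2")
  bad_corr <- matrix(c(1, 2, 2, 1), 2)
  f2 <- feature_spec("y", "binary", prevalence = c(B = 0.5, ALT = 0.5))
  expect_error(cohort_spec(list(f, f2), correlation = bad_corr),
               "positive semi-definite")
  expect_error(cohort_spec(list(f, f2),
                           correlation = matrix(c(2, 0, 0, 2), 2)),
               "unit diagonal")
})

test_that("simulation is deterministic and respects group sizes and bounds", {
  spec <- default_cohort_spec()
  a <- simulate_cohort(spec, seed = 1)
  b <- simulate_cohort(spec, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(spec, seed = 2)))
  expect_equal(unname(table(a$group)[c("B", "ALT")]), c(39L, 6L),
               ignore_attr = TRUE)
  for (f in spec$features) {
    v <- a[[f$name]]
    expect_false(anyNA(v))
    if (f$kind == "binary") expect_true(all(v %in% c(0L, 1L)))
    if (f$kind == "continuous") {
      expect_true(all(v >= f$lower & v <= f$upper))
    }
  }
  expect_true(all(a$group %in% c("B", "ALT")))
})

test_that("feature sub-streams are stable when a feature is appended", {
  f1 <- feature_spec("alpha", "continuous", family = "truncnorm",
                     mean = c(B = 10, ALT = 12), sd = c(B = 2, ALT = 2))
  f2 <- feature_spec("beta", "binary", prevalence = c(B = 0.3, ALT = 0.8))
  f3 <- feature_spec("gamma", "continuous", family = "lognormal",
                     mean = c(B = 5, ALT = 9), sd = c(B = 2, ALT = 4))
  small <- simulate_cohort(cohort_spec(list(f1, f2), 20, 10), seed = 9)
  large <- simulate_cohort(cohort_spec(list(f1, f2, f3), 20, 10), seed = 9)
  expect_identical(small$alpha, large$alpha)
  expect_identical(small$beta, large$beta)
})

test_that("empirical prevalences converge to the configured rates", {
  spec <- default_cohort_spec()
  spec$n_B <- 50000L
  spec$n_ALT <- 50000L
  co <- simulate_cohort(spec, seed = 7)
  alt_ce <- mean(co$contrast_enhancement[co$group == "ALT"])
  expect_lt(abs(alt_ce - 1.0), 0.01)
  b_stir <- mean(co$stir_discrepancy[co$group == "B"])
  expect_lt(abs(b_stir - 2 / 39), 0.01)
})

test_that("latent copula correlation induces dependence and identity does not", {
  f1 <- feature_spec("u", "continuous", family = "truncnorm",
                     mean = c(B = 0.5, ALT = 0.5), sd = c(B = 0.1, ALT = 0.1),
                     lower = -Inf, upper = Inf)
  f2 <- feature_spec("v", "continuous", family = "truncnorm",
                     mean = c(B = 10, ALT = 10), sd = c(B = 3, ALT = 3),
                     lower = -Inf, upper = Inf)
  ind <- simulate_cohort(cohort_spec(list(f1, f2), 50000, 0), seed = 5)
  expect_lt(abs(stats::cor(ind$u, ind$v)), 0.02)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  dep <- simulate_cohort(cohort_spec(list(f1, f2), 50000, 0,
                                     correlation = R), seed = 5)
  # normal marginals: latent correlation carries through almost unchanged
  expect_lt(abs(stats::cor(dep$u, dep$v) - 0.6), 0.05)
  # marginals are preserved under correlation
  expect_lt(abs(mean(dep$u) - 0.5) / 0.5, 0.02)
  expect_lt(abs(mean(dep$v) - 10) / 10, 0.02)
})

test_that("categorical features follow their probability vectors", {
  f <- feature_spec("pattern", "categorical",
                    levels = c("none", "patchy", "nodular"),
                    probs = list(B = c(0.7, 0.2, 0.1),
                                 ALT = c(0.1, 0.4, 0.5)))
  co <- simulate_cohort(cohort_spec(list(f), 30000, 30000), seed = 2)
  pb <- prop.table(table(co$pattern[co$group == "B"]))
  expect_lt(abs(pb[["none"]] - 0.7), 0.01)
  pa <- prop.table(table(co$pattern[co$group == "ALT"]))
  expect_lt(abs(pa[["nodular"]] - 0.5), 0.01)
})

test_that("spec JSON and cohort CSV round-trip faithfully", {
  spec <- default_cohort_spec()
  spec$correlation <- diag(length(spec$features))
  tf <- tempfile(fileext = ".json")
  write_cohort_spec_json(spec, tf)
  spec2 <- read_cohort_spec_json(tf)
  expect_identical(simulate_cohort(spec, seed = 3),
                   simulate_cohort(spec2, seed = 3))

  co <- simulate_cohort(default_cohort_spec(), seed = 4)
  tc <- tempfile(fileext = ".csv")
  write_cohort_csv(co, tc)
  co2 <- read_cohort_csv(tc)
  expect_equal(co2$group, co$group)
  expect_equal(co2$fat_fraction, co$fat_fraction, tolerance = 1e-12)

  bad <- co
  names(bad)[names(bad) == "group"] <- "klass"
  write_cohort_csv(bad, tc)
  expect_error(read_cohort_csv(tc), "class column 'group' not found")
  bad2 <- co
  bad2$group[1] <- "XX"
  write_cohort_csv(bad2, tc)
  expect_error(read_cohort_csv(tc), "other than B/ALT")
})
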