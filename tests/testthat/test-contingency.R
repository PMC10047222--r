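test_that("diagnostic metrics reproduce the published 2x2 panels", {
  # benign-positive orientation, test-positive = STIR discrepancy absent
  stir <- diagnostic_metrics(contingency_2x2(37, 2, 1, 5,
                                             positive_class = "B"))
  expect_equal(stir$ppv$estimate, 37 / 38)          # printed 97.4
  expect_equal(stir$npv$estimate, 5 / 7)            # printed 71.4
  expect_equal(stir$specificity$estimate, 5 / 6)    # printed 83.3
  expect_equal(stir$sensitivity$estimate, 37 / 39)  # printed 95.0

  ce <- diagnostic_metrics(contingency_2x2(29, 10, 0, 6,
                                           positive_class = "B"))
  expect_equal(ce$sensitivity$estimate, 29 / 39)    # printed 74.4
  expect_equal(ce$npv$estimate, 6 / 16)             # printed 37.5
  expect_equal(ce$specificity$estimate, 1)
})

test_that("perfect tests and zero denominators behave as documented", {
  perfect <- diagnostic_metrics(contingency_2x2(10, 0, 0, 10))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(perfect[[m]]$estimate, 1)
  }
  # no test-positives at all: PPV undefined, never an error
  degen <- diagnostic_metrics(contingency_2x2(0, 5, 0, 5))
  expect_true(is.na(degen$ppv$estimate))
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher exact p-values match printed values and the stats oracle", {
  # contrast enhancement: 10/39 benign vs 6/6 ALT enhancing
  p_ce <- fisher_exact_2x2(contingency_2x2(10, 29, 6, 0))
  expect_equal(round(p_ce, 4), 0.0010)
  expect_equal(p_ce, stats::fisher.test(matrix(c(10, 29, 6, 0), 2,
                                               byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # STIR discrepancy: 2/39 benign vs 5/6 ALT positive
  p_stir <- fisher_exact_2x2(contingency_2x2(2, 37, 5, 1))
  expect_lt(p_stir, 1e-4)
  expect_equal(p_stir, fisher_enumeration_oracle(2, 37, 5, 1),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(contingency_2x2(5, 5, 5, 5)), 1.0)
})

test_that("Fisher p is invariant to transposition on random tables", {
  set.seed(42)
  for (i in 1:200) {
    cnt <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    p1 <- fisher_exact_2x2(contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4]))
    p2 <- fisher_exact_2x2(contingency_2x2(cnt[1], cnt[3], cnt[2], cnt[4]))
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("orientation swap exchanges sensitivity/specificity and PPV/NPV", {
  set.seed(7)
  for (i in 1:50) {
    cnt <- as.integer(rmultinom(1, 40, c(0.3, 0.2, 0.2, 0.3)))
    m1 <- diagnostic_metrics(contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4]))
    m2 <- diagnostic_metrics(contingency_2x2(cnt[4], cnt[3], cnt[2], cnt[1]))
    expect_equal(m1$sensitivity$estimate, m2$specificity$estimate)
    expect_equal(m1$ppv$estimate, m2$npv$estimate)
  }
})

test_that("odds ratio uses the Haldane-Anscombe correction and Woolf CI", {
  expect_equal(odds_ratio_ci(contingency_2x2(1, 1, 1, 1))$or, 1.0)
  o <- odds_ratio_ci(contingency_2x2(2, 37, 5, 1))
  expect_equal(o$or, (2 * 1) / (37 * 5), tolerance = 1e-12)
  expect_false(o$corrected)
  # same table, orientation flipped
  expect_equal(odds_ratio_ci(contingency_2x2(5, 1, 2, 37))$or,
               1 / o$or, tolerance = 1e-12)
  # Woolf interval arithmetic, independently recomputed
  se <- sqrt(1 / 2 + 1 / 37 + 1 / 5 + 1 / 1)
  expect_equal(o$ci, exp(log(o$or) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  oz <- odds_ratio_ci(contingency_2x2(10, 0, 3, 7))
  expect_true(oz$corrected && is.finite(oz$or))
  expect_equal(oz$or, (10.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
})

test_that("proportion intervals are valid, match oracles and tighten with n", {
  expect_equal(proportion_ci(0, 10, "clopper_pearson")[1], 0)
  # Wilson closed form, independently recomputed
  w <- proportion_ci(37, 38, "wilson")
  z <- qnorm(0.975)
  p <- 37 / 38
  n <- 38
  ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(w, c(ctr - hw, ctr + hw), tolerance = 1e-12)
  expect_true(w[1] < 0.974 && 0.974 < w[2])
  # Clopper-Pearson against the beta-quantile oracle
  cp <- proportion_ci(5, 6, "clopper_pearson")
  expect_equal(cp, c(qbeta(0.025, 5, 2), qbeta(0.975, 6, 1)),
               tolerance = 1e-12)
  expect_true(cp[1] < 5 / 6 && 5 / 6 < cp[2])
  # intervals contain k/n and lie in [0,1]
  set.seed(3)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    for (m in c("wilson", "clopper_pearson")) {
      ci <- proportion_ci(k, n, m)
      expect_true(ci[1] >= 0 && ci[2] <= 1)
      expect_true(ci[1] <= k / n + 1e-12 && k / n <= ci[2] + 1e-12)
    }
  }
  # Clopper-Pearson width shrinks as n grows at fixed k/n
  widths <- sapply(c(10, 40, 160, 640), function(n) {
    diff(proportion_ci(n * 0.3, n, "clopper_pearson"))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("positive likelihood ratio follows its identity", {
  expect_equal(positive_likelihood_ratio(1.0, 37 / 39), 19.5)
  expect_equal(positive_likelihood_ratio(0.5, 0.5), 1.0)
  expect_identical(positive_likelihood_ratio(1, 1), Inf)
})

test_that("cohort cross-tabulation matches manual counting", {
  co <- reconstructed_cohort()
  tab <- contingency_from_cohort(co, "stir_discrepancy",
                                 positive_class = "ALT")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(5L, 1L, 2L, 37L))
})
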