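# Shared fixtures, all built in code.

# 45-patient binary table reconstructed from the published group counts:
# STIR discrepancy positive in 2/39 benign and 5/6 ALT, contrast
# enhancement positive in 10/39 benign and 6/6 ALT.
reconstructed_cohort <- function() {
  data.frame(
    group = rep(c("B", "ALT"), c(39, 6)),
    stir_discrepancy = c(rep(0L, 37), rep(1L, 2), 0L, rep(1L, 5)),
    contrast_enhancement = c(rep(0L, 29), rep(1L, 10), rep(1L, 6)))
}

# Generator with exactly five informative features (published effect sizes)
# among pure-noise features, used for parameter-recovery checks.
recovery_spec <- function(n_per_group = 250L) {
  cohort_spec(list(
    feature_spec("septation_thickness", "continuous", family = "lognormal",
                 mean = c(B = 0.80, ALT = 3.25), sd = c(B = 0.45, ALT = 2.65)),
    feature_spec("stir_discrepancy", "binary",
                 prevalence = c(B = 2 / 39, ALT = 5 / 6)),
    feature_spec("diameter_y", "continuous", family = "truncnorm",
                 mean = c(B = 37.6, ALT = 56.3), sd = c(B = 18.6, ALT = 39.3)),
    feature_spec("contrast_enhancement", "binary",
                 prevalence = c(B = 10 / 39, ALT = 1)),
    feature_spec("diameter_x", "continuous", family = "truncnorm",
                 mean = c(B = 94.3, ALT = 171.2), sd = c(B = 49.2, ALT = 43.4)),
    feature_spec("noise_bin1", "binary", prevalence = c(B = 0.3, ALT = 0.3)),
    feature_spec("noise_bin2", "binary", prevalence = c(B = 0.5, ALT = 0.5)),
    feature_spec("noise_cont1", "continuous", family = "truncnorm",
                 mean = c(B = 50, ALT = 50), sd = c(B = 10, ALT = 10)),
    feature_spec("noise_cont2", "continuous", family = "lognormal",
                 mean = c(B = 100, ALT = 100), sd = c(B = 40, ALT = 40)),
    feature_spec("noise_cont3", "continuous", family = "truncnorm",
                 mean = c(B = 5, ALT = 5), sd = c(B = 2, ALT = 2))
  ), n_B = n_per_group, n_ALT = n_per_group)
}

recovery_informative <- c("septation_thickness", "stir_discrepancy",
                          "diameter_y", "contrast_enhancement", "diameter_x")

recovery_continuous <- c("septation_thickness", "diameter_y", "diameter_x",
                         "noise_cont1", "noise_cont2", "noise_cont3")

# Independent two-sided Fisher oracle: full enumeration of the
# hypergeometric support with log-binomial arithmetic (sum-of-small-p).
fisher_enumeration_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  supp <- max(0, k - n):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p0 <- lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k)
  min(sum(exp(lp)[exp(lp) <= exp(p0) * (1 + 1e-7)]), 1)
}
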