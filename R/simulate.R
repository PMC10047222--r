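# Synthetic cohort generation: latent Gaussian copula with exact marginal
# back-transforms per feature and group.

# Effective standardized grid for the truncated normal: the support
# [alpha, beta] clipped to where the density has non-negligible mass.
truncnorm_zgrid <- function(alpha, beta, n = 4001L) {
  zlo <- if (is.finite(alpha)) alpha else
    if (beta < -1) beta - 50 / abs(beta) else -40
  zhi <- if (is.finite(beta)) beta else
    if (alpha > 1) alpha + 50 / alpha else 40
  seq(zlo, zhi, length.out = n)
}

# Mean and variance of a normal(mu, sigma) truncated to [a, b].
# The closed form loses all precision when the support sits deep in one
# tail of the parent (pnorm differences cancel); a log-weighted trapezoid
# quadrature over the standardized support is used there instead.
truncnorm_moments <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  Z <- stats::pnorm(beta) - stats::pnorm(alpha)
  if (Z > 1e-8) {
    phi_a <- stats::dnorm(alpha)
    phi_b <- stats::dnorm(beta)
    A <- if (is.finite(alpha)) alpha * phi_a else 0
    B <- if (is.finite(beta)) beta * phi_b else 0
    d <- (phi_a - phi_b) / Z
    return(list(mean = mu + sigma * d,
                var = sigma^2 * (1 + (A - B) / Z - d^2)))
  }
  z <- truncnorm_zgrid(alpha, beta)
  logw <- -z^2 / 2
  w <- exp(logw - max(logw))
  w[c(1L, length(w))] <- w[c(1L, length(w))] / 2   # trapezoid ends
  sw <- sum(w)
  m1 <- sum(w * z) / sw
  m2 <- sum(w * z^2) / sw
  list(mean = mu + sigma * m1, var = sigma^2 * max(m2 - m1^2, 0))
}

# Parent (mu, sigma) such that the [a, b]-truncated normal has the requested
# mean exactly and an SD as close as the family allows. A bounded support
# caps the attainable SD (the sigma -> Inf limit is uniform on [a, b]), so
# the SD is matched by least squares and the mean then polished by a
# root-find in mu, where the truncated mean is strictly increasing.
truncnorm_match <- function(target_mean, target_sd, a, b) {
  if (target_mean <= a || target_mean >= b) {
    stop("target mean ", target_mean, " must lie inside the bounds [",
         a, ", ", b, "]", call. = FALSE)
  }
  # no appreciable truncation: parent parameters are the targets
  pa <- stats::pnorm((a - target_mean) / target_sd)
  pb <- stats::pnorm((b - target_mean) / target_sd)
  if (pa < 1e-12 && (1 - pb) < 1e-12) {
    return(list(mu = target_mean, sigma = target_sd))
  }
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), a, b)
    ((m$mean - target_mean) / target_sd)^2 +
      ((sqrt(max(m$var, 0)) - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  sigma <- exp(fit$par[2])
  froot <- function(mu) truncnorm_moments(mu, sigma, a, b)$mean - target_mean
  lo <- fit$par[1] - 50 * sigma
  hi <- fit$par[1] + 50 * sigma
  mu <- stats::uniroot(froot, c(lo, hi), tol = 1e-10)$root
  list(mu = mu, sigma = sigma)
}

# Quantile of the truncated normal via the parent normal quantile, with a
# grid-inverted CDF in the deep-tail regime where the direct formula
# degenerates.
qtruncnorm <- function(u, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  if (pb - pa > 1e-8) {
    x <- stats::qnorm(pa + u * (pb - pa), mu, sigma)
    return(pmin(pmax(x, a), b))
  }
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- truncnorm_zgrid(alpha, beta)
  logw <- -z^2 / 2
  w <- exp(logw - max(logw))
  cw <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
  cw <- cw / cw[length(cw)]
  # strictly increasing CDF grid for interpolation
  keep <- c(TRUE, diff(cw) > 0)
  x <- mu + sigma * stats::approx(cw[keep], z[keep], xout = u,
                                  rule = 2, ties = "ordered")$y
  pmin(pmax(x, a), b)
}

# Lognormal (meanlog, sdlog) with distribution mean m and SD s.
lognormal_match <- function(m, s) {
  sdlog2 <- log1p((s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Back-transform a uniform column to the feature's marginal for one group.
marginal_quantile <- function(f, group, u) {
  switch(f$kind,
    binary = as.integer(u <= f$prevalence[[group]]),
    categorical = {
      br <- c(0, cumsum(f$probs[[group]]))
      br[length(br)] <- 1
      f$levels[findInterval(u, br, rightmost.closed = TRUE,
                            all.inside = TRUE)]
    },
    continuous = {
      if (f$family == "lognormal") {
        p <- lognormal_match(f$mean[[group]], f$sd[[group]])
        pmin(stats::qlnorm(u, p$meanlog, p$sdlog), f$upper)
      } else {
        p <- truncnorm_match(f$mean[[group]], f$sd[[group]], f$lower, f$upper)
        qtruncnorm(u, p$mu, p$sigma, f$lower, f$upper)
      }
    }
  )
}

#' Simulate a synthetic two-group cohort
#'
#' Draws a per-patient feature table from a [cohort_spec()]. Features are
#' generated through a latent Gaussian copula: each feature receives its own
#' deterministic RNG sub-stream (derived from the global seed, the group and
#' the feature name, so adding a feature never reshuffles existing ones), the
#' latent normals are mixed by the Cholesky factor of the spec's correlation
#' matrix, and each column is back-transformed through its group-specific
#' marginal quantile function. Identical `(spec, seed)` pairs therefore give
#' bit-identical tables.
#'
#' @param spec A `"cohort_spec"`.
#' @param seed Integer seed controlling all randomness of the draw.
#' @return A `data.frame` with columns `patient_id`, `group` (`"B"`/`"ALT"`)
#'   and one column per feature; binary features are 0/1 integers.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(), seed = 1)
#' table(cohort$group)
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- stop_if_not_count(seed, "seed")
  feats <- spec$features
  k <- length(feats)
  R_chol <- NULL
  if (!is.null(spec$correlation)) {
    R <- spec$correlation
    # PSD was validated at construction; lift tiny negative eigenvalues
    R_chol <- tryCatch(chol(R), error = function(e) {
      e <- eigen(R, symmetric = TRUE)
      chol(e$vectors %*% diag(pmax(e$values, 1e-10)) %*% t(e$vectors))
    })
  }
  sizes <- c(B = spec$n_B, ALT = spec$n_ALT)
  blocks <- lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    cols <- as.data.frame(matrix(nrow = n, ncol = 0))
    if (n == 0L) {
      cols <- stats::setNames(
        as.data.frame(lapply(feats, function(f) {
          if (f$kind == "categorical") character(0)
          else if (f$kind == "binary") integer(0) else numeric(0)
        })), names(feats))
      return(cbind(group = character(0), cols))
    }
    Z <- vapply(names(feats), function(nm) {
      with_seed(derive_seed(seed, paste0(g, "/", nm)), stats::rnorm(n))
    }, numeric(n))
    Z <- matrix(Z, nrow = n, ncol = k)
    if (!is.null(R_chol)) Z <- Z %*% R_chol
    U <- stats::pnorm(Z)
    for (j in seq_len(k)) {
      cols[[names(feats)[j]]] <- marginal_quantile(feats[[j]], g, U[, j])
    }
    cbind(group = rep(g, n), cols, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read and write cohort tables as CSV
#'
#' The CSV dialect is fixed: UTF-8, comma separator, header row, a class
#' column (default `group`) holding the literal values `B`/`ALT`, binary
#' features encoded 0/1 and missing values as empty cells.
#'
#' @param cohort A cohort `data.frame` as produced by [simulate_cohort()].
#' @param path File path.
#' @param class_col Name of the class column expected on read.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, class_col = "group") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  if (!class_col %in% names(x)) {
    stop("class column '", class_col, "' not found in ", path, call. = FALSE)
  }
  bad <- setdiff(unique(stats::na.omit(x[[class_col]])), c("B", "ALT"))
  if (length(bad)) {
    stop("class column '", class_col, "' contains values other than B/ALT: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}
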