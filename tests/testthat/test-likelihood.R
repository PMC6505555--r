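test_that("sampling variances follow the published construction", {
  snap <- simulate_population(theta_ref(), 1000, tg_short(), k_max = 6, seed = 2)
  W <- moments_wide(snap$moments)
  sv <- sampling_variances(snap$moments, 1000, k_max = 3)
  s <- tidyr::pivot_wider(sv, names_from = order, values_from = sigma2,
                          names_prefix = "s")
  expect_equal(s$s1, W$mu2^2 / 1000)
  expect_equal(s$s2, (W$mu4 - (997 / 999) * W$mu2^2) / 1000)
  expect_equal(s$s3, (W$mu6 - W$mu3^2) / 1000)
  # infinite-sample limit: 1/N dropped, small-sample factor -> 1
  sv_inf <- sampling_variances(snap$moments, Inf, k_max = 2)
  s_inf <- tidyr::pivot_wider(sv_inf, names_from = order,
                              values_from = sigma2, names_prefix = "s")
  expect_equal(s_inf$s2, W$mu4 - W$mu2^2)
  # degenerate (constant) data is refused
  const <- snap
  const$counts[] <- 5L
  const$moments <- loopmoments:::counts_to_moments(const$counts, const$times, 6, "sample")
  expect_error(sampling_variances(const$moments, 1000, 2), "degenerate")
})

test_that("exact-variant sigma1/sigma2 match the bootstrap spread of the moments", {
  # oracle: bootstrap variance of mu1_hat and mu2_hat across resamples
  withr::local_seed(99)
  n <- 10000
  x <- rgamma(n, shape = 2, rate = 0.1)  # skewed, protein-count-like
  mu <- sample_central_moments(x, 4)
  se1sq <- mu[2] / n
  se2sq <- (mu[4] - (n - 3) / (n - 1) * mu[2]^2) / n
  B <- 500
  boots <- t(replicate(B, {
    xb <- x[sample.int(n, n, replace = TRUE)]
    sample_central_moments(xb, 2)
  }))
  v1 <- var(boots[, 1]); v2 <- var(boots[, 2])
  # bootstrap variance of a variance estimate has ~ sqrt(2/B) relative spread
  expect_lt(abs(v1 - se1sq) / se1sq, 3 * sqrt(2 / B))
  expect_lt(abs(v2 - se2sq) / se2sq, 4 * sqrt(2 / B))
})

test_that("the objective is zero at a perfect match and scales with the weights", {
  theta <- theta_ref()
  tg <- tg_short()
  pred <- predict_moments(theta, tg, "CDM")
  unit_w <- tibble::tibble(time = rep(tg, each = 2),
                           order = rep(1:2, length(tg)), sigma2 = 1)
  lik <- moment_likelihood(pred, Inf, "CDM", sigma2 = unit_w)
  expect_equal(neg_log_likelihood(as.double(theta), lik), 0, tolerance = 1e-12)
  # moving away from the generating parameters increases the objective
  expect_gt(neg_log_likelihood(c(14, 3, 1, 0.001, 0.1), lik), 0.1)
  # scaling all sigma_k^2 by c scales the objective by 1/c (argmin invariant)
  lik2 <- moment_likelihood(pred, Inf, "CDM",
                            sigma2 = dplyr::mutate(unit_w, sigma2 = 7))
  th <- c(14, 3, 1, 0.001, 0.1)
  expect_equal(neg_log_likelihood(th, lik2),
               neg_log_likelihood(th, lik) / 7, tolerance = 1e-10)
})

test_that("the objective is finite on real data and infinite when flagged", {
  M <- cached_fsp_moments(theta_ref(), tg_short(), 4)
  lik <- moment_likelihood(M, Inf, "LNA")
  v <- neg_log_likelihood(as.double(theta_ref()), lik)
  expect_true(is.finite(v) && v > 0)
  expect_identical(neg_log_likelihood(c(-1, 3, 1, 0.001, 0.1), lik), Inf)
  expect_identical(neg_log_likelihood(c(NA, 3, 1, 0.001, 0.1), lik), Inf)
})

test_that("mean-only data cannot separate production rate from burst size", {
  # the likelihood is flat along rho_u * b = const with K = 1 and curved
  # along it once the variance is added (K = 2)
  M <- cached_fsp_moments(theta_ref(), tg_short(), 4)
  lik1 <- moment_likelihood(M, Inf, "CDM", k_max = 1)
  lik2 <- moment_likelihood(M, Inf, "CDM", k_max = 2)
  prod <- 13 * 3
  scale <- c(1 / 3, 1, 3)
  on_ridge1 <- vapply(scale, function(s) {
    neg_log_likelihood(c(13 * s, prod / (13 * s), 1, 0.001, 0.1), lik1)
  }, 0)
  on_ridge2 <- vapply(scale, function(s) {
    neg_log_likelihood(c(13 * s, prod / (13 * s), 1, 0.001, 0.1), lik2)
  }, 0)
  # K = 1: the whole ridge is as good as the truth (flat to numerical noise)
  expect_lt(max(on_ridge1) - min(on_ridge1), 1e-2 * (1 + max(on_ridge1)))
  # K = 2: leaving the true point along the ridge is strongly penalized
  expect_gt(on_ridge2[1] / (on_ridge2[2] + 1e-12), 1e3)
  expect_gt(on_ridge2[3] / (on_ridge2[2] + 1e-12), 1e3)
})
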