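test_that("degenerate rate limits behave as the reaction scheme dictates", {
  tg <- tg_short()
  # no production: counts identically zero
  z <- simulate_cell(feedback_params(0, 3, 1, 0.001, 0.1), tg, seed = 1)
  expect_true(all(z$count == 0))
  # no decay, no binding: counts are nondecreasing
  up <- simulate_cell(feedback_params(13, 3, 0, 0, 0.1), tg, seed = 2)
  expect_true(all(diff(up$count) >= 0))
  # tiny population is still well-defined
  s2 <- simulate_population(theta_ref(), 2, tg, k_max = 2, seed = 3)
  expect_identical(dim(s2$counts), c(2L, 10L))
  expect_true(all(is.finite(s2$moments$value)))
})

test_that("sample central moments implement the population-normalized sums", {
  expect_equal(unname(sample_central_moments(c(1, 2, 3), 2)), c(2, 2 / 3))
  cm <- sample_central_moments(rep(5, 4), 6)
  expect_equal(unname(cm), c(5, 0, 0, 0, 0, 0))
  x <- withr::with_seed(11, runif(1000, 0, 50))
  expect_equal(unname(sample_central_moments(x, 6)),
               brute_central_moments(x, 6), tolerance = 1e-12)
  expect_error(sample_central_moments(numeric(0), 2), "at least one")
})

test_that("per-cell substreams make runs reproducible and extendable", {
  theta <- theta_ref()
  tg <- tg_short()
  a <- simulate_population(theta, 50, tg, seed = 42)
  b <- simulate_population(theta, 50, tg, seed = 42)
  expect_identical(a$counts, b$counts)
  # growing the population leaves earlier cells untouched
  big <- simulate_population(theta, 80, tg, seed = 42)
  expect_identical(big$counts[1:50, ], a$counts)
  # different seeds decorrelate
  c_ <- simulate_population(theta, 50, tg, seed = 43)
  expect_false(identical(a$counts, c_$counts))
})

test_that("two master seeds agree within combined Monte-Carlo error", {
  theta <- theta_ref()
  n <- 4000
  a <- simulate_population(theta, n, tg_short(), seed = 101)
  b <- simulate_population(theta, n, tg_short(), seed = 202)
  for (l in c(3, 10)) {
    xa <- a$counts[, l]; xb <- b$counts[, l]
    se <- sqrt(var(xa) / n + var(xb) / n)
    expect_lt(abs(mean(xa) - mean(xb)), 4 * se)
  }
})

test_that("heterogeneous simulation with zero spread equals the homogeneous run", {
  hp <- heterogeneous_params(13, 0, 3, 1, 0.001, 0.1)
  th <- feedback_params(13, 3, 1, 0.001, 0.1)
  a <- simulate_population(hp, 40, tg_short(), seed = 9)
  b <- simulate_population(th, 40, tg_short(), seed = 9)
  expect_identical(a$counts, b$counts)
})

test_that("harvested burst sizes follow the geometric law", {
  for (b in c(1, 3, 10)) {
    # pool bursts from several long single-cell runs
    bursts <- unlist(lapply(1:40, function(i) {
      attr(simulate_cell(feedback_params(13, b, 1, 1e-4, 0.1),
                         time_grid(30), seed = 1000 + i,
                         collect_bursts = TRUE), "bursts")
    }))
    expect_gt(length(bursts), 2000)
    # chi-square goodness of fit against psi, tail-pooled
    cut <- max(5, stats::qgeom(0.995, 1 / (1 + b)))
    obs <- tabulate(pmin(bursts, cut) + 1L, nbins = cut + 1L)
    p <- burst_pmf(b, 0:(cut - 1))
    p <- c(p, 1 - sum(p))
    keep <- p * length(bursts) >= 5
    chi <- sum((obs[keep] - length(bursts) * p[keep])^2 /
                 (length(bursts) * p[keep]))
    pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("SSA moments agree with the master-equation solution", {
  theta <- theta_ref()
  tg <- tg_short()
  M <- moments_wide(cached_fsp_moments(theta, tg, 2))
  n <- 10000
  snap <- simulate_population(theta, n, tg, k_max = 2, seed = 7)
  for (l in c(2, 10)) {
    x <- snap$counts[, l]
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - M$mu1[l]), 3 * se)
  }
})

test_that("measurement noise is identity at zero and perturbs moments at scale", {
  theta <- theta_ref()
  snap <- simulate_population(theta, 2000, tg_short(), k_max = 2, seed = 5)
  expect_identical(add_measurement_noise(snap, 0), snap)
  noisy <- add_measurement_noise(snap, 0.05, seed = 8)
  expect_false(identical(noisy$counts, snap$counts))
  # lognormal multiplicative noise with unit median inflates the mean by
  # ~ exp(s^2/2) - 1 (about 0.13% at s = 0.05), well within 1%
  ratio <- mean(noisy$counts[, 10]) / mean(snap$counts[, 10])
  expect_lt(abs(ratio - 1), 0.01)
  expect_error(add_measurement_noise(snap, -0.1), "nonnegative")
})

test_that("moment series round-trip through the CSV interchange format", {
  snap <- simulate_population(theta_ref(), 100, tg_short(), k_max = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_moments_csv(snap$moments, f)
  back <- read_moments_csv(f)
  expect_equal(back$value, snap$moments$value)
  expect_equal(moments_wide(back)$mu2, moments_wide(snap$moments)$mu2)
})
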