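test_that("fractional errors implement the elementwise definitions", {
  theta <- theta_ref()
  same <- fractional_errors(theta_mle = as.double(theta),
                            theta_map = as.double(theta), theta_true = theta)
  expect_true(all(same$fe_mle_true == 0))
  expect_true(all(same$fe_mle_map == 0))
  map <- as.double(theta); map["rho_u"] <- 14.3
  rep_ <- fractional_errors(theta_map = map, theta_true = theta)
  expect_equal(rep_$fe_map_true[rep_$parameter == "rho_u"], 0.1)
  expect_equal(mean_fe_percent(rep_, "fe_map_true"), 100 * 0.1 / 5)
  expect_error(fractional_errors(theta_mle = as.double(theta),
                                 theta_true = c(rho_u = 0, b = 3, d = 1,
                                                sigma_b = 1, sigma_u = 1)),
               "zero")
})

test_that("symmetric data have zero mean-variance correlation", {
  snap <- simulate_population(theta_ref(), 100, c(1, 2), k_max = 2, seed = 1)
  snap$counts <- matrix(rep(c(1, 2, 3), length.out = 198), ncol = 2)  # symmetric about 2
  mv <- mean_variance_correlation(snap)
  expect_equal(mv$per_time$rho, c(0, 0))
  expect_equal(mv$lambda, 0)
})

test_that("the mean-variance covariance formula matches replicate sampling", {
  # oracle: empirical covariance of (mu1_hat, mu2_hat) across replicate
  # samples equals mu3/N (exact result used by the correlation diagnostic)
  theta <- theta_ref()
  n <- 1000
  reps <- 400
  stats <- t(vapply(seq_len(reps), function(r) {
    x <- simulate_population(theta, n, c(5), k_max = 3, seed = 5000 + r)
    sample_central_moments(x$counts[, 1], 3)
  }, numeric(3)))
  emp_cov <- cov(stats[, 1], stats[, 2])
  mu3_bar <- mean(stats[, 3])
  want <- mu3_bar / n
  # Monte-Carlo standard error of the covariance estimate
  se <- sd((stats[, 1] - mean(stats[, 1])) * (stats[, 2] - mean(stats[, 2]))) /
    sqrt(reps)
  expect_lt(abs(emp_cov - want), 3 * se)
})

test_that("the time-averaged correlation is small for realistic populations", {
  snap <- simulate_population(theta_ref(), 1000, tg_short(), k_max = 4,
                              seed = 77)
  mv <- mean_variance_correlation(snap)
  expect_lt(abs(mv$lambda), 0.1)
})

test_that("the benchmark driver is deterministic given seeds", {
  theta <- theta_ref()
  ctl <- list(max_eval = 1500, stall_gens = 15, np = 30, polish_maxit = 500)
  b1 <- run_closure_benchmark(theta, closures = "CDM", data = "ssa",
                              n_cells = 500, times = c(2, 5, 10),
                              seed = 3, mle_control = ctl)
  b2 <- run_closure_benchmark(theta, closures = "CDM", data = "ssa",
                              n_cells = 500, times = c(2, 5, 10),
                              seed = 3, mle_control = ctl)
  expect_equal(b1$mean_fe_pct, b2$mean_fe_pct)
  expect_equal(b1$rho_u, b2$rho_u)
})

test_that("measurement noise degrades the maximum-likelihood estimate", {
  theta <- theta_ref()
  tg <- time_grid(20)
  ctl <- list(max_eval = 6000, stall_gens = 25)
  fe_at <- function(noise) {
    snap <- simulate_population(theta, 5000, tg, k_max = 4, seed = 13)
    if (noise > 0) snap <- add_measurement_noise(snap, noise, seed = 14)
    lik <- moment_likelihood(snap$moments, 5000, "CDM")
    fit <- fit_mle(lik, seed = 15, control = ctl)
    mean_fe_percent(fractional_errors(theta_mle = fit, theta_true = theta))
  }
  clean <- fe_at(0)
  noisy <- fe_at(0.1)
  expect_gt(noisy, clean)
})

test_that("sweep records failures without aborting and tags cells", {
  ctl <- list(max_eval = 1200, stall_gens = 12, np = 25, polish_maxit = 400)
  sw <- run_sweep(sigma_b = 1e-3, b = c(1, 3), rho_u = 13,
                  closures = "CDM", times = c(2, 5, 10), mle_control = ctl)
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$ok))
  expect_true(all(c("sigma_b", "b", "rho_u", "closure", "mean_fe_pct")
                  %in% names(sw)))
})
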