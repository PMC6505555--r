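test_that("FSP conserves mass and starts from the zero-protein ON state", {
  theta <- theta_ref()
  sol <- fsp_solve(theta, c(1e-9, tg_short()))
  # essentially t = 0: all mass on (ON, n = 0)
  expect_gt(sol$prob[1, 1], 1 - 1e-6)
  # retained mass within the leak tolerance at every time
  expect_true(all(colSums(sol$prob) <= 1 + 1e-12))
  expect_true(all(sol$leak <= 1e-8))
})

test_that("no-feedback mean matches the closed-form bursty birth-death mean", {
  theta <- theta_linear()  # sigma_b = 0
  tg <- tg_short()
  M <- moments_wide(fsp_moments(fsp_solve(theta, tg), 1))
  want <- (theta$rho_u * theta$b / theta$d) * (1 - exp(-theta$d * tg))
  expect_equal(M$mu1, want, tolerance = 1e-6)
})

test_that("FSP moments match a dense matrix-exponential solve on a small space", {
  # weak parameters on a small truncation; independent oracle: expm via
  # scaling-and-squaring on the dense generator (uniformization-free)
  theta <- feedback_params(2, 1, 1, 0.01, 0.2)
  n_max <- 50L
  ns <- n_max + 1L
  A <- matrix(0, 2 * ns, 2 * ns)
  psi <- burst_pmf(theta$b, 0:n_max)
  for (n in 0:n_max) {
    iON <- n + 1L; iOFF <- ns + n + 1L
    A[iON, iON] <- A[iON, iON] - (theta$rho_u * (1 - psi[1]) +
                                    theta$sigma_b * n + theta$d * n)
    A[iOFF, iOFF] <- A[iOFF, iOFF] - (theta$sigma_u + theta$d * n)
    if (n > 0) {
      A[iON - 1L, iON] <- A[iON - 1L, iON] + theta$d * n
      A[iOFF - 1L, iOFF] <- A[iOFF - 1L, iOFF] + theta$d * n
      A[iOFF - 1L, iON] <- A[iOFF - 1L, iON] + theta$sigma_b * n
    }
    A[iON, iOFF] <- A[iON, iOFF] + theta$sigma_u
    for (m in seq_len(n_max - n)) {
      A[iON + m, iON] <- A[iON + m, iON] + theta$rho_u * psi[m + 1L]
    }
  }
  p0 <- numeric(2 * ns); p0[1] <- 1
  # expm by repeated squaring of expm(A h)
  expm_taylor <- function(M) {
    s <- max(1, ceiling(log2(max(1, norm(M, "1")))))
    X <- M / 2^s
    E <- diag(nrow(M)); term <- diag(nrow(M))
    for (k in 1:30) {
      term <- term %*% X / k
      E <- E + term
    }
    for (i in seq_len(s)) E <- E %*% E
    E
  }
  E1 <- expm_taylor(A)  # propagator over one time unit
  p <- p0
  times <- 1:5
  sol <- fsp_solve(theta, times, n_max = n_max)
  for (l in seq_along(times)) {
    p <- E1 %*% p
    pn_oracle <- (p[1:ns] + p[(ns + 1):(2 * ns)]) / sum(p)
    pn_fsp <- (sol$prob[1:ns, l] + sol$prob[(ns + 1):(2 * ns), l]) /
      sum(sol$prob[, l])
    expect_lt(max(abs(pn_oracle - pn_fsp)), 1e-8)
  }
  # and the derived central moments agree
  Mo <- moments_wide(fsp_moments(sol, 4))
  n <- 0:n_max
  m1 <- sum(n * pn_oracle)
  expect_equal(Mo$mu1[5], m1, tolerance = 1e-8)
  expect_equal(Mo$mu4[5], sum((n - m1)^4 * pn_oracle), tolerance = 1e-7)
})

test_that("moments from a hand-built two-point distribution are exact", {
  # distribution {n = 0: 1/2, n = 2: 1/2} -> mean 1, mu2 = 1, mu3 = 0, mu4 = 1
  sol <- structure(list(
    prob = matrix(c(0.5, 0, 0.5, rep(0, 3)), ncol = 1),
    n_max = 2L, times = 1, leak = 0,
    params = theta_ref()), class = "fsp_solution")
  M <- moments_wide(fsp_moments(sol, 4))
  expect_equal(unlist(M[1, c("mu1", "mu2", "mu3", "mu4")], use.names = FALSE),
               c(1, 1, 0, 1))
})

test_that("doubling the truncation does not move the moments", {
  theta <- theta_ref()
  tg <- c(1, 5, 10)
  m1 <- moments_wide(fsp_moments(fsp_solve(theta, tg, n_max = 390), 2))
  m2 <- moments_wide(fsp_moments(fsp_solve(theta, tg, n_max = 780), 2))
  expect_lt(max(abs(m2$mu1 / m1$mu1 - 1)), 1e-3)
  expect_lt(max(abs(m2$mu2 / m1$mu2 - 1)), 1e-3)
})

test_that("gene-ON probability is a proper probability and feedback lowers it", {
  tg <- c(5, 20)
  p_weak <- fsp_gene_on_probability(
    fsp_solve(feedback_params(13, 3, 1, 1e-4, 0.1), tg))
  p_strong <- fsp_gene_on_probability(
    fsp_solve(feedback_params(13, 3, 1, 1e-2, 0.1), tg))
  expect_true(all(p_weak$p_on > 0 & p_weak$p_on < 1))
  expect_true(all(p_strong$p_on < p_weak$p_on))
})

test_that("an undersized truncation is doubled until the leak passes", {
  theta <- theta_ref()
  sol <- fsp_solve(theta, c(1, 5), n_max = 40)  # far below the mean + tails
  expect_gte(sol$n_max, 80)
  expect_true(all(sol$leak <= 1e-8))
})
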