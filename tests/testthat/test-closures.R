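test_that("all closures are exact for the feedback-free (linear) network", {
  theta <- theta_linear()
  tg <- tg_short()
  M <- moments_wide(cached_fsp_moments(theta, tg, 3))
  for (cl in closure_ids()) {
    P <- moments_wide(predict_moments(theta, tg, cl, k_max = 3))
    expect_lt(max(abs(P$mu1 / M$mu1 - 1)), 1e-4)
    expect_lt(max(abs(P$mu2 / M$mu2 - 1)), 1e-4)
    if (!cl %in% c("LNA", "CG")) {
      expect_lt(max(abs(P$mu3 / M$mu3 - 1)), 1e-4)
    }
    expect_false(isTRUE(attr(P, "flagged")))
  }
})

test_that("the linear noise approximation has identically zero third moments", {
  P <- moments_wide(predict_moments(theta_ref(), tg_short(), "LNA", k_max = 3))
  expect_true(all(P$mu3 == 0))
})

test_that("closures track the master equation at short times", {
  # before feedback develops (few binding events) every scheme is accurate
  theta <- theta_ref()
  tg <- c(0.02, 0.05, 0.1)
  M <- moments_wide(fsp_moments(fsp_solve(theta, tg), 2))
  for (cl in closure_ids()) {
    P <- moments_wide(predict_moments(theta, tg, cl))
    expect_lt(max(abs(P$mu1 / M$mu1 - 1)), 0.01)
    expect_lt(max(abs(P$mu2 / M$mu2 - 1)), 0.01)
  }
})

test_that("closure systematic error grows with the binding rate", {
  # summed relative moment error vs the master equation, over the grid
  tg <- time_grid(15)
  err <- function(cl, sb) {
    theta <- feedback_params(13, 3, 1, sb, 0.1)
    M <- moments_wide(cached_fsp_moments(theta, tg, 2))
    P <- moments_wide(predict_moments(theta, tg, cl))
    # integration breakdown is the extreme of closure failure; score it
    # above any finite error (tie-broken by sb so strict ordering holds)
    if (isTRUE(attr(P, "flagged")) || anyNA(P)) return(1e6 * (1 + sb))
    sum(abs(P$mu1 / M$mu1 - 1)) + sum(abs(P$mu2 / M$mu2 - 1))
  }
  for (cl in c("LNA", "3MA")) {
    e <- vapply(c(1e-4, 1e-3, 1e-2), function(s) err(cl, s), 0)
    expect_true(all(diff(e) > 0))
  }
})

test_that("predictions stay finite over the studied parameter ranges", {
  tg <- time_grid(30)
  grid <- expand.grid(b = c(1, 10), sb = c(1e-4, 1e-2), rho = c(5, 20))
  for (i in seq_len(nrow(grid))) {
    theta <- feedback_params(grid$rho[i], grid$b[i], 1, grid$sb[i], 0.1)
    for (cl in c("LMA", "CDM", "CG", "DM")) {
      P <- predict_moments(theta, tg, cl)
      expect_true(all(is.finite(P$value)),
                  info = paste(cl, "at row", i))
    }
  }
})

test_that("zero-spread heterogeneous predictions equal the homogeneous ones", {
  hp0 <- heterogeneous_params(13, 0, 3, 1, 0.001, 0.1)
  th <- feedback_params(13, 3, 1, 0.001, 0.1)
  for (cl in c("CDM", "3MA", "LMA")) {
    a <- predict_moments(hp0, tg_short(), cl)
    b <- predict_moments(th, tg_short(), cl)
    expect_equal(a$value, b$value)
  }
})

test_that("mixture mean obeys the law of total expectation", {
  hp <- heterogeneous_params(13, 0.3, 5, 1, 0.001, 0.1)
  tg <- tg_short()
  qn <- loopmoments:::lognormal_quadrature(hp, 20)
  mix <- moments_wide(predict_moments(hp, tg, "CDM", quad_nodes = 20))
  manual <- Reduce(`+`, lapply(seq_along(qn$nodes), function(i) {
    th <- feedback_params(qn$nodes[i], hp$b, hp$d, hp$sigma_b, hp$sigma_u)
    qn$weights[i] * moments_wide(predict_moments(th, tg, "CDM"))$mu1
  }))
  expect_equal(mix$mu1, manual, tolerance = 1e-10)
})

test_that("quadrature order is converged at the study settings", {
  hp <- heterogeneous_params(13, 0.3, 5, 1, 0.001, 0.1)
  a <- moments_wide(predict_moments(hp, tg_short(), "CDM", quad_nodes = 20))
  b <- moments_wide(predict_moments(hp, tg_short(), "CDM", quad_nodes = 40))
  expect_lt(max(abs(b$mu1 / a$mu1 - 1)), 1e-4)
  expect_lt(max(abs(b$mu2 / a$mu2 - 1)), 1e-4)
})

test_that("heterogeneous CDM matches a stratified master-equation mixture", {
  # oracle: solve the master equation at each quadrature node and mix
  hp <- heterogeneous_params(13, 0.3, 3, 1, 0.001, 0.1)
  tg <- c(2, 10)
  qn <- loopmoments:::lognormal_quadrature(hp, 8)
  raw1 <- raw2 <- numeric(length(tg))
  for (i in seq_along(qn$nodes)) {
    th <- feedback_params(qn$nodes[i], hp$b, hp$d, hp$sigma_b, hp$sigma_u)
    Mi <- moments_wide(fsp_moments(fsp_solve(th, tg), 2))
    raw1 <- raw1 + qn$weights[i] * Mi$mu1
    raw2 <- raw2 + qn$weights[i] * (Mi$mu2 + Mi$mu1^2)
  }
  oracle_mu1 <- raw1
  oracle_mu2 <- raw2 - raw1^2
  P <- moments_wide(predict_moments(hp, tg, "CDM", quad_nodes = 8))
  expect_lt(max(abs(P$mu1 / oracle_mu1 - 1)), 0.01)
  expect_lt(max(abs(P$mu2 / oracle_mu2 - 1)), 0.01)
})

test_that("unknown closures and unsupported orders are rejected", {
  expect_error(predict_moments(theta_ref(), tg_short(), "2MA"), "unknown closure")
  expect_error(predict_moments(theta_ref(), tg_short(), "LNA", k_max = 4),
               "must be 2 or 3")
})
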