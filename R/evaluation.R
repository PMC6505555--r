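#' Fractional errors between estimates and reference values
#'
#' Computes the per-parameter fractional errors
#' \eqn{FE_{MLE-MAP} = |\theta_{MLE} - \theta_{MAP}| / \theta_{MAP}},
#' \eqn{FE_{MAP-True} = |\theta_{MAP} - \theta_{True}| / \theta_{True}} and
#' \eqn{FE_{MLE-True} = |\theta_{MLE} - \theta_{True}| / \theta_{True}},
#' plus their means over parameters. Any of `mle`/`map` may be omitted;
#' only the errors whose operands are present are reported.
#'
#' @param theta_mle,theta_map Named estimate vectors (or `moment_fit`
#'   objects), may be `NULL`.
#' @param theta_true Reference parameter vector (or parameter object).
#' @return An object of class `error_report`: tibble with one row per
#'   parameter and columns `parameter`, `true`, and the available estimate
#'   and `fe_*` columns; means over parameters are in attribute `"means"`.
#' @examples
#' fractional_errors(theta_mle = c(rho_u = 14.3, b = 3, d = 1,
#'                                 sigma_b = 0.001, sigma_u = 0.1),
#'                   theta_true = feedback_params(13, 3, 1, 0.001, 0.1))
#' @export
fractional_errors <- function(theta_mle = NULL, theta_map = NULL, theta_true) {
  as_vec <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "moment_fit")) return(x$estimate)
    if (inherits(x, c("feedback_params", "heterogeneous_params"))) {
      v <- as.double(x)
      return(v[setdiff(names(v), "rho_u_scale")])
    }
    x
  }
  mle <- as_vec(theta_mle); map <- as_vec(theta_map); tru <- as_vec(theta_true)
  if (any(tru == 0)) stop("zero reference value in `theta_true`", call. = FALSE)
  out <- tibble::tibble(parameter = names(tru), true = unname(tru))
  means <- c()
  if (!is.null(mle)) {
    out$mle <- unname(mle[out$parameter])
    out$fe_mle_true <- abs(out$mle - out$true) / out$true
    means["fe_mle_true"] <- mean(out$fe_mle_true)
  }
  if (!is.null(map)) {
    out$map <- unname(map[out$parameter])
    out$fe_map_true <- abs(out$map - out$true) / out$true
    means["fe_map_true"] <- mean(out$fe_map_true)
  }
  if (!is.null(mle) && !is.null(map)) {
    if (any(map == 0)) stop("zero MAP value", call. = FALSE)
    out$fe_mle_map <- abs(out$mle - out$map) / out$map
    means["fe_mle_map"] <- mean(out$fe_mle_map)
  }
  structure(out, means = means, class = c("error_report", class(out)))
}

#' Mean fractional error, in percent
#'
#' @param report An [fractional_errors()] report.
#' @param which One of `"fe_mle_true"`, `"fe_map_true"`, `"fe_mle_map"`.
#' @return The mean over parameters of the requested fractional error,
#'   times 100.
#' @export
mean_fe_percent <- function(report, which = "fe_mle_true") {
  m <- attr(report, "means")
  if (!which %in% names(m)) stop("error `", which, "` not in report", call. = FALSE)
  100 * unname(m[which])
}

#' Correlation of sample mean and sample variance
#'
#' The moment likelihood factorizes over moment orders, which presumes the
#' sample mean and sample variance are uncorrelated at each time point.
#' This diagnostic computes, per time point, the asymptotically exact
#' correlation
#' \deqn{\rho(t_l) = \frac{\hat\mu_3(t_l)/N}{se_1(t_l)\, se_2(t_l)},}
#' using the exact covariance \eqn{cov(\hat\mu_1, \hat\mu_2) = \mu_3/N} and
#' the exact sampling standard errors \eqn{se_1^2 = \hat\mu_2/N},
#' \eqn{se_2^2 = (\hat\mu_4 - \frac{N-3}{N-1}\hat\mu_2^2)/N}, plus the grid
#' average \eqn{\Lambda}.
#'
#' @param sample A `snapshot_sample` (moments up to order 4 are computed
#'   from its counts as needed).
#' @return A list with `lambda` (grid-averaged correlation) and `per_time`
#'   (tibble with `time`, `rho`, `cov_mean_var`).
#' @export
mean_variance_correlation <- function(sample) {
  stopifnot(inherits(sample, "snapshot_sample"))
  n <- nrow(sample$counts)
  if (n < 4) stop("at least 4 cells are required", call. = FALSE)
  per <- lapply(seq_along(sample$times), function(l) {
    mu <- sample_central_moments(sample$counts[, l], 4)
    se1 <- sqrt(mu[2] / n)
    se2sq <- (mu[4] - (n - 3) / (n - 1) * mu[2]^2) / n
    if (se1 <= 0 || se2sq <= 0) {
      stop("degenerate moments at time ", sample$times[l], call. = FALSE)
    }
    tibble::tibble(time = sample$times[l],
                   rho = unname((mu[[3]] / n) / (se1 * sqrt(se2sq))),
                   cov_mean_var = mu[[3]] / n)
  })
  per <- dplyr::bind_rows(per)
  list(lambda = mean(per$rho), per_time = per)
}

#' Benchmark the closures on one synthetic data set
#'
#' Generates (or accepts) snapshot data at a known ground truth, builds the
#' moment likelihood for each requested closure, fits by maximum likelihood
#' (and optionally MCMC), and reports per-closure parameter estimates with
#' fractional errors — one row per closure.
#'
#' @param theta_true A [feedback_params()] object (the generating truth).
#' @param closures Character vector of [closure_ids()] entries.
#' @param data `"fsp"` (infinite-sample moments from the finite state
#'   projection) or `"ssa"` (simulated population of `n_cells`).
#' @param n_cells Cells for `data = "ssa"`.
#' @param times Measurement grid.
#' @param k_max Moment orders in the likelihood (2 or 3).
#' @param seed Master seed (data generation and fits).
#' @param mcmc Also run [fit_mcmc()] per closure?
#' @param mcmc_iter,mcmc_chains MCMC budget when `mcmc = TRUE`.
#' @param mle_control Passed to [fit_mle()].
#' @return A tibble with one row per closure: estimates, `mean_fe_pct`
#'   (mean FE of the MLE vs truth, percent), objective, and (with MCMC)
#'   `map` columns, `mean_fe_map_pct`, `max_rhat`. Fits are attached in the
#'   attribute `"fits"`.
#' @export
run_closure_benchmark <- function(theta_true, closures = closure_ids(),
                                  data = c("fsp", "ssa"), n_cells = 1e5,
                                  times = time_grid(30), k_max = 2,
                                  seed = 1L, mcmc = FALSE, mcmc_iter = 4e4,
                                  mcmc_chains = 4L, mle_control = list()) {
  data <- match.arg(data)
  if (data == "fsp") {
    mom <- fsp_moments(fsp_solve(theta_true, times), k_max = 2 * k_max)
    n_eff <- Inf
  } else {
    snap <- simulate_population(theta_true, n_cells, times,
                                k_max = 2 * k_max, seed = seed)
    mom <- snap$moments
    n_eff <- n_cells
  }
  fits <- list()
  rows <- lapply(closures, function(cl) {
    lik <- moment_likelihood(mom, n_eff, cl, k_max = k_max)
    fit <- fit_mle(lik, seed = seed, control = mle_control)
    row <- tibble::tibble(closure = toupper(cl), data = data,
                          n_cells = n_eff, k_max = k_max)
    est <- fit$estimate
    for (pn in names(est)) row[[pn]] <- est[[pn]]
    rep_ <- fractional_errors(theta_mle = fit, theta_true = theta_true)
    row$mean_fe_pct <- mean_fe_percent(rep_, "fe_mle_true")
    row$objective <- fit$objective
    fits[[toupper(cl)]] <<- list(mle = fit)
    if (mcmc) {
      mfit <- fit_mcmc(lik, seed = seed + 1L, chains = mcmc_chains,
                       iter = mcmc_iter, init = fit$estimate)
      rep2 <- fractional_errors(theta_mle = fit, theta_map = mfit,
                                theta_true = theta_true)
      row$mean_fe_map_pct <- mean_fe_percent(rep2, "fe_map_true")
      row$mean_fe_mle_map_pct <- mean_fe_percent(rep2, "fe_mle_map")
      row$max_rhat <- max(mfit$rhat)
      fits[[toupper(cl)]]$mcmc <<- mfit
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Systematic-error sweep over the feedback parameter space
#'
#' For every grid cell (`sigma_b`, `b`, `rho_u`), generates infinite-sample
#' moments by finite state projection, fits each closure by maximum
#' likelihood, and records the mean fractional error of the estimate — the
#' systematic (likelihood-approximation) error that survives in the
#' infinite-sample limit. Failures are recorded per cell and the sweep
#' continues.
#'
#' @param sigma_b,b,rho_u Grid values (vectors).
#' @param closures Closures to fit.
#' @param d,sigma_u Fixed parameters.
#' @param times Measurement grid.
#' @param k_max Moment orders in the likelihood.
#' @param seed Seed for the fits.
#' @param mle_control Passed to [fit_mle()].
#' @param n_max Initial truncation for the per-cell master-equation solves
#'   (`NULL` for the per-cell default); the leak guard still doubles it
#'   whenever it is insufficient.
#' @return A tibble with one row per (grid cell, closure): `mean_fe_pct` or
#'   `error` message; complete cells have `ok = TRUE`.
#' @export
run_sweep <- function(sigma_b = c(1e-4, 1e-3, 1e-2), b = c(1, 3, 10),
                      rho_u = 13, closures = c("LNA", "3MA", "CDM", "LMA"),
                      d = 1, sigma_u = 0.1, times = time_grid(30), k_max = 2,
                      seed = 1L, mle_control = list(), n_max = NULL) {
  grid <- tidyr::expand_grid(sigma_b = sigma_b, b = b, rho_u = rho_u)
  rows <- purrr::pmap(grid, function(sigma_b, b, rho_u) {
    theta <- feedback_params(rho_u, b, d, sigma_b, sigma_u)
    cell <- tryCatch({
      mom <- fsp_moments(fsp_solve(theta, times, n_max = n_max),
                         k_max = 2 * k_max)
      purrr::map(closures, function(cl) {
        res <- tryCatch({
          lik <- moment_likelihood(mom, Inf, cl, k_max = k_max)
          fit <- fit_mle(lik, seed = seed, control = mle_control)
          rep_ <- fractional_errors(theta_mle = fit, theta_true = theta)
          tibble::tibble(closure = toupper(cl),
                         mean_fe_pct = mean_fe_percent(rep_), ok = TRUE,
                         error = NA_character_)
        }, error = function(e) {
          tibble::tibble(closure = toupper(cl), mean_fe_pct = NA_real_,
                         ok = FALSE, error = conditionMessage(e))
        })
        res
      }) |> dplyr::bind_rows()
    }, error = function(e) {
      tibble::tibble(closure = toupper(closures), mean_fe_pct = NA_real_,
                     ok = FALSE, error = conditionMessage(e))
    })
    cell$sigma_b <- sigma_b; cell$b <- b; cell$rho_u <- rho_u
    cell
  })
  dplyr::bind_rows(rows)[, c("sigma_b", "b", "rho_u", "closure",
                             "mean_fe_pct", "ok", "error")]
}

#' Six-parameter inference study for heterogeneous populations
#'
#' Simulates a population with lognormal cell-to-cell variation in `rho_u`,
#' fits the six-parameter heterogeneous model per closure, and reports
#' estimates and fractional errors against the generating truth.
#'
#' @param params_true A [heterogeneous_params()] object.
#' @param closures Closures to fit.
#' @param n_cells Population size.
#' @param times Measurement grid.
#' @param k_max Moment orders in the likelihood.
#' @param seed Master seed.
#' @param mcmc Also run MCMC per closure?
#' @param mcmc_iter,mcmc_chains MCMC budget.
#' @param mle_control Passed to [fit_mle()].
#' @param quad_nodes Gauss-Hermite nodes for the mixture predictions.
#' @return A tibble, one row per closure, with the six estimates and
#'   `mean_fe_pct`; fits attached as attribute `"fits"`.
#' @details The six-parameter fit is warm-started from a five-parameter
#'   homogeneous fit of the same data (the heterogeneous model nests the
#'   homogeneous one at `sd_rho_u = 0`), which anchors the search in the
#'   data-consistent basin before the spread parameter is released.
#' @export
run_heterogeneity_study <- function(params_true,
                                    closures = c("3MA", "CDM", "LMA"),
                                    n_cells = 1e5, times = time_grid(30),
                                    k_max = 2, seed = 1L, mcmc = FALSE,
                                    mcmc_iter = 4e4, mcmc_chains = 4L,
                                    mle_control = list(), quad_nodes = 10) {
  stopifnot(inherits(params_true, "heterogeneous_params"))
  snap <- simulate_population(params_true, n_cells, times,
                              k_max = 2 * k_max, seed = seed)
  fits <- list()
  rows <- lapply(closures, function(cl) {
    lik5 <- moment_likelihood(snap$moments, n_cells, cl, k_max = k_max)
    fit5 <- fit_mle(lik5, seed = seed, control = mle_control)
    g5 <- fit5$estimate
    guess <- c(g5[["rho_u"]], 0.1, g5[["b"]], g5[["d"]], g5[["sigma_b"]],
               g5[["sigma_u"]])
    bounds <- list(lower = guess / 1000, upper = guess * 1000, guess = guess)
    lik <- moment_likelihood(snap$moments, n_cells, cl, k_max = k_max,
                             heterogeneous = TRUE,
                             rho_u_scale = params_true$rho_u_scale,
                             quad_nodes = quad_nodes)
    fit <- fit_mle(lik, seed = seed, bounds = bounds, control = mle_control)
    rep_ <- fractional_errors(theta_mle = fit, theta_true = params_true)
    row <- tibble::tibble(closure = toupper(cl), n_cells = n_cells)
    for (pn in names(fit$estimate)) row[[pn]] <- fit$estimate[[pn]]
    row$mean_fe_pct <- mean_fe_percent(rep_)
    fits[[toupper(cl)]] <<- list(mle = fit)
    if (mcmc) {
      mfit <- fit_mcmc(lik, seed = seed + 1L, chains = mcmc_chains,
                       iter = mcmc_iter, init = fit$estimate)
      rep2 <- fractional_errors(theta_mle = fit, theta_map = mfit,
                                theta_true = params_true)
      row$mean_fe_map_pct <- mean_fe_percent(rep2, "fe_map_true")
      row$max_rhat <- max(mfit$rhat)
      fits[[toupper(cl)]]$mcmc <<- mfit
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}
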