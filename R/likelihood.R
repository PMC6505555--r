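#' Sampling variances of the measured central moments
#'
#' For each time point, the Gaussian moment likelihood weights the squared
#' mismatch of the k-th sample moment by a variance \eqn{\sigma_k^2(t_l)}
#' built from higher sample moments:
#' \deqn{\sigma_1^2 = \hat\mu_2^2/N,\quad
#'   \sigma_2^2 = (\hat\mu_4 - \tfrac{N-3}{N-1}\hat\mu_2^2)/N,\quad
#'   \sigma_3^2 = (\hat\mu_6 - \hat\mu_3^2)/N.}
#' The \eqn{\hat\mu_2^2} form of \eqn{\sigma_1^2} (the study's convention,
#' `mean_weight = "relative"`) puts the mean channel on the same squared
#' scale as the variance and skewness channels; `mean_weight = "exact"`
#' instead uses the exact sampling variance of the sample mean,
#' \eqn{\hat\mu_2/N}. For infinite-sample (finite state projection) data the
#' common 1/N factor is dropped — it cancels from the arg-min — and
#' \eqn{(N-3)/(N-1) \to 1}.
#'
#' @param moments Moment-series tibble containing orders up to `2 * k_max`
#'   at every time point.
#' @param n_cells Number of cells behind each moment estimate; `Inf` for
#'   FSP-derived moments.
#' @param k_max Highest moment order entering the likelihood (1 to 3).
#' @param mean_weight `"relative"` (default) or `"exact"`, see Details.
#' @return A tibble with columns `time`, `order`, `sigma2`.
#' @export
sampling_variances <- function(moments, n_cells, k_max = 2,
                               mean_weight = c("relative", "exact")) {
  mean_weight <- match.arg(mean_weight)
  if (!k_max %in% 1:3) stop("`k_max` must be 1, 2 or 3", call. = FALSE)
  w <- moments_wide(moments)
  need <- paste0("mu", seq_len(2 * k_max))
  if (!all(need %in% names(w))) {
    stop("moments up to order ", 2 * k_max,
         " are required to weight a likelihood with k_max = ", k_max,
         call. = FALSE)
  }
  if (!is.infinite(n_cells) && n_cells < 4) {
    stop("`n_cells` must be at least 4 (or Inf)", call. = FALSE)
  }
  inv_n <- if (is.infinite(n_cells)) 1 else 1 / n_cells
  corr <- if (is.infinite(n_cells)) 1 else (n_cells - 3) / (n_cells - 1)
  s1 <- if (mean_weight == "relative") w$mu2^2 * inv_n else w$mu2 * inv_n
  out <- tibble::tibble(time = w$time, order = 1L, sigma2 = s1)
  if (k_max >= 2) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      time = w$time, order = 2L, sigma2 = (w$mu4 - corr * w$mu2^2) * inv_n))
  }
  if (k_max >= 3) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      time = w$time, order = 3L, sigma2 = (w$mu6 - w$mu3^2) * inv_n))
  }
  if (any(out$sigma2 <= 0)) {
    stop("degenerate data: nonpositive sampling variance encountered",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$time, .data$order)
}

#' Specify a moment likelihood
#'
#' Bundles the observed moment series, its sampling variances and the
#' closure used for the model prediction into a likelihood specification
#' consumed by [neg_log_likelihood()], [fit_mle()] and [fit_mcmc()].
#'
#' @param moments Observed moment-series tibble with orders up to
#'   `2 * k_max` (the extra orders feed the sampling variances).
#' @param n_cells Cells per time point behind the moments; `Inf` for FSP
#'   data.
#' @param closure One of [closure_ids()].
#' @param k_max Moment orders used for fitting (2 or 3; 1 is allowed for
#'   identifiability diagnostics only).
#' @param heterogeneous Fit the six-parameter heterogeneous model
#'   (lognormal `rho_u` across cells)?
#' @param rho_u_scale Scale convention for `sd_rho_u` when
#'   `heterogeneous = TRUE`; see [heterogeneous_params()].
#' @param mean_weight Passed to [sampling_variances()].
#' @param quad_nodes Gauss-Hermite nodes for heterogeneous predictions.
#' @param sigma2 Optional tibble (`time`, `order`, `sigma2`) overriding the
#'   sampling variances — e.g. unit weights for closure-self-consistency
#'   studies whose data lack the higher orders.
#' @return An object of class `moment_likelihood`.
#' @export
moment_likelihood <- function(moments, n_cells, closure, k_max = 2,
                              heterogeneous = FALSE,
                              rho_u_scale = c("log", "arithmetic"),
                              mean_weight = c("relative", "exact"),
                              quad_nodes = 20, sigma2 = NULL) {
  rho_u_scale <- match.arg(rho_u_scale)
  mean_weight <- match.arg(mean_weight)
  if (!k_max %in% 1:3) stop("`k_max` must be 1, 2 or 3", call. = FALSE)
  closure <- toupper(closure)
  closure_code(closure)  # validates
  w <- moments_wide(moments)
  sig <- if (is.null(sigma2)) {
    sampling_variances(moments, n_cells, k_max, mean_weight)
  } else {
    sigma2
  }
  sig_w <- tidyr::pivot_wider(sig, names_from = "order",
                              values_from = "sigma2", names_prefix = "s")
  structure(
    list(times = w$time,
         observed = as.matrix(w[, paste0("mu", seq_len(k_max)), drop = FALSE]),
         sigma2 = as.matrix(sig_w[, paste0("s", seq_len(k_max)), drop = FALSE]),
         n_cells = n_cells, closure = closure, k_max = as.integer(k_max),
         heterogeneous = isTRUE(heterogeneous), rho_u_scale = rho_u_scale,
         mean_weight = mean_weight, quad_nodes = quad_nodes),
    class = "moment_likelihood")
}

#' @export
print.moment_likelihood <- function(x, ...) {
  cat(sprintf(
    "<moment_likelihood> closure %s, k_max %d, %d time points, N = %s%s\n",
    x$closure, x$k_max, length(x$times),
    if (is.infinite(x$n_cells)) "Inf (FSP)" else format(x$n_cells),
    if (x$heterogeneous) ", heterogeneous" else ""))
  invisible(x)
}

#' Number of fitted parameters of a likelihood specification
#' @param lik A [moment_likelihood()] object.
#' @return 5 for identical cells, 6 for heterogeneous populations.
#' @export
n_fit_params <- function(lik) if (lik$heterogeneous) 6L else 5L

#' Names of the fitted parameters
#' @param lik A [moment_likelihood()] object.
#' @return Character vector of parameter names in fitting order.
#' @export
fit_param_names <- function(lik) {
  if (lik$heterogeneous) {
    c("mean_rho_u", "sd_rho_u", "b", "d", "sigma_b", "sigma_u")
  } else {
    c("rho_u", "b", "d", "sigma_b", "sigma_u")
  }
}

# closure prediction for a parameter vector under a likelihood spec;
# returns L x k_max matrix of central moments or NULL when flagged
predict_for_likelihood <- function(theta, lik, k_pred = max(lik$k_max, 2L)) {
  if (lik$heterogeneous) {
    qn <- lognormal_quadrature(
      heterogeneous_params(theta[1], theta[2], theta[3], theta[4], theta[5],
                           theta[6], rho_u_scale = lik$rho_u_scale),
      lik$quad_nodes)
    raw <- .closure_predict_mix_cpp(closure_code(lik$closure), qn$nodes,
                                    qn$weights, theta[3:6], lik$times,
                                    as.integer(k_pred), 1e-8, 1e-10)
  } else {
    raw <- .closure_predict_cpp(closure_code(lik$closure), theta, lik$times,
                                as.integer(k_pred), 1e-8, 1e-10)
  }
  if (any(raw[, 4] > 0)) return(NULL)
  raw[, seq_len(lik$k_max), drop = FALSE]
}

#' Negative log-likelihood of a parameter vector
#'
#' Evaluates the weighted squared moment mismatch
#' \deqn{\sum_{k=1}^{K}\sum_{l=1}^{L}
#'   \frac{(\hat\mu_k(t_l) - \tilde\mu_k(t_l, \theta))^2}{\sigma_k^2(t_l)},}
#' twice the negative log of the Gaussian moment likelihood with its
#' constant prefactors dropped. Flagged closure predictions (integration
#' failure, negative variance) give `Inf`, which the optimizers treat as a
#' penalty.
#'
#' @param theta Positive parameter vector in the order of
#'   [fit_param_names()], or a parameter object of the matching kind.
#' @param lik A [moment_likelihood()] object.
#' @return A scalar; `Inf` for flagged predictions.
#' @export
neg_log_likelihood <- function(theta, lik) {
  stopifnot(inherits(lik, "moment_likelihood"))
  if (inherits(theta, c("feedback_params", "heterogeneous_params"))) {
    theta <- unname(as.double(theta))
  }
  if (length(theta) != n_fit_params(lik) || any(!is.finite(theta)) ||
      any(theta < 0)) {
    return(Inf)
  }
  pred <- predict_for_likelihood(theta, lik)
  if (is.null(pred) || any(!is.finite(pred))) return(Inf)
  sum((lik$observed - pred)^2 / lik$sigma2)
}
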