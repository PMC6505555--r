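#' Tidy a fitted moment-based estimate
#'
#' @param x A `moment_fit` from [fit_mle()] or [fit_mcmc()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and for
#'   MCMC fits `std.error` (posterior sd), `conf.low`/`conf.high` (central
#'   95% interval), `rhat`.
#' @export
tidy.moment_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimate),
                        estimate = unname(x$estimate))
  if (x$method == "mcmc") {
    out$std.error <- apply(x$samples, 2, stats::sd)
    qs <- apply(x$samples, 2, stats::quantile, probs = c(0.025, 0.975))
    out$conf.low <- qs[1, ]
    out$conf.high <- qs[2, ]
    out$rhat <- unname(x$rhat)
  }
  out
}

#' One-row summary of a fitted moment-based estimate
#'
#' @param x A `moment_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `closure`, `k_max`, `n_cells`,
#'   `objective` (MLE) or `max_rhat`/`acceptance` (MCMC), `converged`.
#' @export
glance.moment_fit <- function(x, ...) {
  base <- tibble::tibble(method = x$method, closure = x$lik$closure,
                         k_max = x$lik$k_max, n_cells = x$lik$n_cells,
                         heterogeneous = x$lik$heterogeneous,
                         converged = isTRUE(x$converged))
  if (x$method == "mle") {
    base$objective <- x$objective
    base$de_evals <- x$de_evals
  } else {
    base$max_rhat <- max(x$rhat)
    base$acceptance <- x$acceptance
  }
  base
}

#' Plot posterior marginals or an estimate summary
#'
#' For MCMC fits, draws the marginal posterior density of each parameter
#' (log10 axis) with the joint-mode MAP marked; for MLE fits, draws the
#' point estimates.
#'
#' @param object A `moment_fit`.
#' @param true Optional named reference vector to mark (e.g. the generating
#'   truth of a synthetic study).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moment_fit <- function(object, true = NULL, ...) {
  nm <- names(object$estimate)
  if (object$method == "mcmc") {
    samples <- object$samples
    colnames(samples) <- nm
    df <- tibble::as_tibble(samples)
    long <- tidyr::pivot_longer(df, dplyr::all_of(nm),
                                names_to = "parameter", values_to = "value")
    gp <- ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$value))) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::geom_vline(
        data = tibble::tibble(parameter = nm,
                              value = log10(unname(object$estimate))),
        ggplot2::aes(xintercept = .data$value), linetype = 2) +
      ggplot2::labs(x = "log10 parameter value", y = "posterior density")
  } else {
    est <- tibble::tibble(parameter = nm, value = unname(object$estimate))
    gp <- ggplot2::ggplot(est, ggplot2::aes(x = .data$parameter,
                                            y = log10(.data$value))) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = NULL, y = "log10 estimate")
  }
  if (!is.null(true)) {
    gp <- gp + ggplot2::geom_vline(
      data = tibble::tibble(parameter = names(true),
                            value = log10(unname(true))),
      ggplot2::aes(xintercept = .data$value), colour = "red", linetype = 3)
  }
  gp
}

#' Compare moment series from several sources
#'
#' Overlays moment trajectories (one panel per moment order) from any
#' number of moment-series tibbles — sample moments, finite state
#' projection references and closure predictions.
#'
#' @param ... Named moment-series tibbles; the names label the lines.
#' @return A ggplot object.
#' @examples
#' theta <- feedback_params(13, 3, 1, 0.001, 0.1)
#' tg <- time_grid(10)
#' plot_moment_series(
#'   fsp = fsp_moments(fsp_solve(theta, tg), 2),
#'   lna = predict_moments(theta, tg, "LNA"))
#' @export
plot_moment_series <- function(...) {
  series <- list(...)
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- paste0("series", seq_along(series))
  }
  df <- dplyr::bind_rows(lapply(names(series), function(nm) {
    s <- series[[nm]]
    tibble::tibble(time = s$time, order = s$order, value = s$value,
                   series = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~order, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (units of 1/d)", y = "central moment")
}

#' Heat-map of a systematic-error sweep
#'
#' @param sweep A [run_sweep()] result.
#' @return A ggplot object: log10 mean fractional error over the
#'   (`sigma_b`, `b`) grid, one panel per closure.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = factor(.data$sigma_b), y = factor(.data$b),
                               fill = log10(.data$mean_fe_pct / 100))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~closure) +
    ggplot2::scale_fill_viridis_c(name = "log10 mean FE") +
    ggplot2::labs(x = "sigma_b", y = "b")
}
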