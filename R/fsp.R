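#' Solve the feedback-loop master equation by finite state projection
#'
#' Truncates the chemical master equation of the feedback loop to the state
#' space \{ON, OFF\} x \{0..n_max\} and propagates the initial condition
#' (zero proteins, gene ON) to each grid time with uniformization, which
#' resolves the truncated linear system to the tolerance of its Poisson
#' series. Probability flowing beyond the truncation is absorbed and
#' reported as leaked mass; if the leak at any grid time exceeds `tol`,
#' `n_max` is doubled and the solve retried (up to `max_retries` times).
#'
#' The default truncation is `max(200, 10 * rho_u * b / d)` states, a
#' generous multiple of the feedback-free stationary mean.
#'
#' @param params A [feedback_params()] object.
#' @param times Measurement time grid (strictly increasing, >= 0 allowed).
#' @param n_max Truncation bound; `NULL` for the default.
#' @param tol Maximum tolerated leaked mass at any grid time.
#' @param max_retries Number of truncation doublings before giving up.
#' @return An object of class `fsp_solution`: list with `prob` (matrix,
#'   `2 * (n_max + 1)` rows by `length(times)` columns; ON block first),
#'   `n_max`, `times`, `leak` (per time), `params`.
#' @examples
#' theta <- feedback_params(13, 3, 1, 0.001, 0.1)
#' sol <- fsp_solve(theta, time_grid(5))
#' fsp_moments(sol, k_max = 2)
#' @export
fsp_solve <- function(params, times, n_max = NULL, tol = 1e-8,
                      max_retries = 3L) {
  stopifnot(inherits(params, "feedback_params"))
  check_times(times)
  if (is.null(n_max)) {
    n_max <- max(200, ceiling(10 * params$rho_u * params$b / params$d))
  }
  for (attempt in 0:max_retries) {
    prob <- .fsp_propagate_cpp(as.integer(n_max), params$rho_u, params$b,
                               params$d, params$sigma_b, params$sigma_u,
                               as.numeric(times), 1e-12)
    leak <- 1 - colSums(prob)
    if (max(leak) <= tol) {
      return(structure(
        list(prob = prob, n_max = as.integer(n_max),
             times = as.numeric(times), leak = leak, params = params),
        class = "fsp_solution"))
    }
    n_max <- 2L * n_max
  }
  stop(sprintf(
    "finite state projection did not converge: leaked mass %.3g at n_max %d",
    max(leak), n_max %/% 2L), call. = FALSE)
}

#' @export
print.fsp_solution <- function(x, ...) {
  cat(sprintf("<fsp_solution> n_max = %d, %d time points, max leak %.2e\n",
              x$n_max, length(x$times), max(x$leak)))
  invisible(x)
}

#' Central moments of a finite state projection solution
#'
#' Computes central moments of the marginal protein distribution at each
#' grid time from the truncated probability vector, renormalized by its
#' total retained mass.
#'
#' @param solution An [fsp_solve()] result.
#' @param k_max Highest central-moment order, 1 to 6.
#' @return A moment-series tibble (columns `time`, `order`, `value`,
#'   `n_cells = Inf`, `source = "fsp"`).
#' @export
fsp_moments <- function(solution, k_max = 4) {
  stopifnot(inherits(solution, "fsp_solution"))
  if (!k_max %in% 1:6) stop("`k_max` must be between 1 and 6", call. = FALSE)
  ns <- solution$n_max + 1L
  n <- 0:solution$n_max
  rows <- lapply(seq_along(solution$times), function(l) {
    p <- solution$prob[, l]
    pn <- (p[1:ns] + p[(ns + 1):(2 * ns)]) / sum(p)
    m1 <- sum(n * pn)
    vals <- c(m1, vapply(seq_len(k_max)[-1],
                         function(k) sum((n - m1)^k * pn), 0))
    tibble::tibble(time = solution$times[l], order = seq_len(k_max),
                   value = vals)
  })
  out <- dplyr::bind_rows(rows)
  out$n_cells <- Inf
  out$source <- "fsp"
  out
}

#' Marginal protein distribution from an FSP solution
#'
#' @param solution An [fsp_solve()] result.
#' @return A tibble with columns `time`, `gene_state` (`"ON"`/`"OFF"`), `n`,
#'   `probability` (not renormalized; column sums reflect retained mass).
#' @export
fsp_distribution <- function(solution) {
  stopifnot(inherits(solution, "fsp_solution"))
  ns <- solution$n_max + 1L
  n <- 0:solution$n_max
  rows <- lapply(seq_along(solution$times), function(l) {
    p <- solution$prob[, l]
    tibble::tibble(
      time = solution$times[l],
      gene_state = rep(c("ON", "OFF"), each = ns),
      n = rep(n, 2L),
      probability = p)
  })
  dplyr::bind_rows(rows)
}

#' Probability that the gene is ON
#'
#' @param solution An [fsp_solve()] result.
#' @return A tibble with columns `time` and `p_on` (renormalized).
#' @export
fsp_gene_on_probability <- function(solution) {
  stopifnot(inherits(solution, "fsp_solution"))
  ns <- solution$n_max + 1L
  p_on <- vapply(seq_along(solution$times), function(l) {
    p <- solution$prob[, l]
    sum(p[1:ns]) / sum(p)
  }, 0)
  tibble::tibble(time = solution$times, p_on = p_on)
}
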