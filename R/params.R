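#' Kinetic parameters of the negative autoregulatory feedback loop
#'
#' Container for the five rate constants of the bursty negative feedback loop
#' in which a gene in the ON state produces protein in geometric bursts, the
#' protein binds the promoter and switches it OFF, and the OFF state reverts
#' at a constant rate:
#' \deqn{G \to G + mP \;(\rho_u),\quad G + P \to G^* \;(\sigma_b),\quad
#'   G^* \to G \;(\sigma_u),\quad P \to \emptyset \;(d),}
#' with burst size \eqn{m} drawn from the geometric law
#' \eqn{\psi(m) = b^m/(1+b)^{m+1}}. Time is measured in units of the protein
#' lifetime when \eqn{d = 1}; all rates are nondimensional.
#'
#' @param rho_u Burst-firing (protein production) rate in the ON state, 1/time.
#' @param b Mean protein burst size (mean of the geometric burst law),
#'   molecules.
#' @param d Protein degradation rate, 1/time.
#' @param sigma_b Protein-DNA binding rate, 1/(molecule time).
#' @param sigma_u Promoter OFF-to-ON switching rate, 1/time.
#'
#' @return An object of class `feedback_params`: a named list with the five
#'   strictly positive rates.
#' @seealso [heterogeneous_params()] for populations with cell-to-cell
#'   variation in `rho_u`, [reaction_network()] for the reaction channels.
#' @examples
#' theta <- feedback_params(rho_u = 13, b = 3, d = 1, sigma_b = 0.001, sigma_u = 0.1)
#' theta
#' @export
feedback_params <- function(rho_u, b, d, sigma_b, sigma_u) {
  p <- list(rho_u = rho_u, b = b, d = d, sigma_b = sigma_b, sigma_u = sigma_u)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single nonnegative finite number",
           call. = FALSE)
    }
  }
  # b > 0 is required by the burst law; the other rates admit the boundary
  # value 0 (no production / no decay / no feedback / permanent OFF), which
  # the degenerate-limit checks rely on
  if (p$b <= 0) stop("`b` must be strictly positive", call. = FALSE)
  structure(p, class = "feedback_params")
}

#' Feedback-loop parameters for a heterogeneous cell population
#'
#' Same reaction scheme as [feedback_params()], but the production rate
#' `rho_u` varies from cell to cell following a lognormal distribution while
#' the remaining rates are shared. `sd_rho_u` is interpreted on the log scale
#' by default (the standard deviation of `log(rho_u)`); set
#' `rho_u_scale = "arithmetic"` to give the arithmetic standard deviation of
#' `rho_u` instead, in which case the lognormal is moment-matched.
#'
#' @param mean_rho_u Population mean of `rho_u` (arithmetic mean), > 0.
#' @param sd_rho_u Spread of `rho_u` across cells, >= 0. `sd_rho_u = 0`
#'   reduces exactly to the homogeneous model.
#' @param b,d,sigma_b,sigma_u Shared rates, as in [feedback_params()].
#' @param rho_u_scale Either `"log"` (default; `sd_rho_u` is the sd of
#'   `log(rho_u)`) or `"arithmetic"` (`sd_rho_u` is the sd of `rho_u`).
#'
#' @return An object of class `heterogeneous_params`.
#' @examples
#' heterogeneous_params(mean_rho_u = 13, sd_rho_u = 0.3, b = 5, d = 1,
#'                      sigma_b = 0.001, sigma_u = 0.1)
#' @export
heterogeneous_params <- function(mean_rho_u, sd_rho_u, b, d, sigma_b, sigma_u,
                                 rho_u_scale = c("log", "arithmetic")) {
  rho_u_scale <- match.arg(rho_u_scale)
  if (!is.numeric(mean_rho_u) || length(mean_rho_u) != 1L || mean_rho_u <= 0) {
    stop("`mean_rho_u` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd_rho_u) || length(sd_rho_u) != 1L || sd_rho_u < 0) {
    stop("`sd_rho_u` must be a single nonnegative number", call. = FALSE)
  }
  base <- feedback_params(mean_rho_u, b, d, sigma_b, sigma_u)
  structure(
    list(mean_rho_u = mean_rho_u, sd_rho_u = sd_rho_u,
         b = b, d = d, sigma_b = sigma_b, sigma_u = sigma_u,
         rho_u_scale = rho_u_scale, rho_u_law = "lognormal"),
    class = "heterogeneous_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat("<feedback_params>\n")
  cat(sprintf("  rho_u = %g, b = %g, d = %g, sigma_b = %g, sigma_u = %g\n",
              x$rho_u, x$b, x$d, x$sigma_b, x$sigma_u))
  invisible(x)
}

#' @export
print.heterogeneous_params <- function(x, ...) {
  cat("<heterogeneous_params>\n")
  cat(sprintf("  rho_u ~ lognormal(mean = %g, sd = %g [%s scale])\n",
              x$mean_rho_u, x$sd_rho_u, x$rho_u_scale))
  cat(sprintf("  b = %g, d = %g, sigma_b = %g, sigma_u = %g\n",
              x$b, x$d, x$sigma_b, x$sigma_u))
  invisible(x)
}

#' @export
as.double.feedback_params <- function(x, ...) {
  c(rho_u = x$rho_u, b = x$b, d = x$d, sigma_b = x$sigma_b, sigma_u = x$sigma_u)
}

#' @export
as.double.heterogeneous_params <- function(x, ...) {
  c(mean_rho_u = x$mean_rho_u, sd_rho_u = x$sd_rho_u, b = x$b, d = x$d,
    sigma_b = x$sigma_b, sigma_u = x$sigma_u)
}

# lognormal (meanlog, sdlog) for the rho_u law, honouring the scale convention
rho_u_lognormal <- function(params) {
  stopifnot(inherits(params, "heterogeneous_params"))
  m <- params$mean_rho_u
  s <- params$sd_rho_u
  if (s == 0) return(list(meanlog = log(m), sdlog = 0))
  if (params$rho_u_scale == "log") {
    sdlog <- s
  } else {
    sdlog <- sqrt(log1p((s / m)^2))
  }
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Read and write parameter files
#'
#' Parameters are exchanged as flat JSON objects:
#' `{"rho_u": ..., "b": ..., "d": ..., "sigma_b": ..., "sigma_u": ...}` for
#' identical cells, or
#' `{"mean_rho_u": ..., "sd_rho_u": ..., "b": ..., "d": ..., "sigma_b": ...,
#' "sigma_u": ..., "rho_u_scale": "log"|"arithmetic"}` for heterogeneous
#' populations. Round-tripping is lossless.
#'
#' @param params A [feedback_params()] or [heterogeneous_params()] object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly; `read_params_json()`
#'   returns the reconstructed parameter object.
#' @export
write_params_json <- function(params, path) {
  x <- unclass(params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$mean_rho_u)) {
    heterogeneous_params(x$mean_rho_u, x$sd_rho_u, x$b, x$d, x$sigma_b,
                         x$sigma_u, rho_u_scale = x$rho_u_scale %||% "log")
  } else {
    feedback_params(x$rho_u, x$b, x$d, x$sigma_b, x$sigma_u)
  }
}

#' Geometric burst-size distribution
#'
#' Probability mass function of the translational burst size,
#' \eqn{\psi(m) = b^m / (1+b)^{m+1}} for \eqn{m = 0, 1, 2, \ldots}; the mean
#' burst size is \eqn{b}. Computed on the log scale so large `m` does not
#' overflow.
#'
#' @param b Mean burst size, > 0.
#' @param m Vector of nonnegative integers.
#' @return `burst_pmf()`: vector of probabilities.
#' @examples
#' burst_pmf(3, 0)           # 1/(1+b) = 0.25
#' sum(burst_pmf(3, 0:1000)) # ~1
#' @export
burst_pmf <- function(b, m) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single positive number", call. = FALSE)
  }
  if (any(m < 0) || any(m != floor(m))) {
    stop("`m` must contain nonnegative integers", call. = FALSE)
  }
  exp(m * log(b) - (m + 1) * log1p(b))
}

#' @description
#' `burst_raw_moments()` returns the exact raw moments
#' \eqn{E[m^j], j = 1..k} of the burst law, obtained from the factorial
#' moments \eqn{E[m(m-1)\cdots(m-j+1)] = j!\, b^j} of the geometric
#' distribution (orders up to 4 are supported, which is what the moment
#' equations of the closures require).
#'
#' @param k Highest order, 1 to 4.
#' @return `burst_raw_moments()`: named vector `E1`..`Ek`.
#' @rdname burst_pmf
#' @examples
#' burst_raw_moments(3, 2)   # E[m] = 3, E[m^2] = 21
#' @export
burst_raw_moments <- function(b, k = 4) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single positive number", call. = FALSE)
  }
  if (!k %in% 1:4) stop("`k` must be an integer between 1 and 4", call. = FALSE)
  # Stirling-number expansion of powers in falling factorials
  all_m <- c(E1 = b,
             E2 = 2 * b^2 + b,
             E3 = 6 * b^3 + 6 * b^2 + b,
             E4 = 24 * b^4 + 36 * b^3 + 14 * b^2 + b)
  all_m[seq_len(k)]
}

#' Reaction channels of the feedback loop
#'
#' Tabulates the four reaction channels simulated by the stochastic
#' simulation algorithm, with their state changes and propensities. The gene
#' is a single copy, so the state is (gene ON/OFF, protein count n); a
#' production firing adds a geometric burst of `m >= 0` proteins (an `m = 0`
#' firing changes nothing).
#'
#' @param params A [feedback_params()] object.
#' @return A tibble with one row per channel: `reaction`, `delta_protein`
#'   (`NA` for the burst channel, whose increment is random), `gene_from`,
#'   `gene_to`, and `propensity` (a list column of functions
#'   `f(gene_on, n)`).
#' @seealso [propensities()] for direct numeric evaluation.
#' @export
reaction_network <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  p <- params
  tibble::tibble(
    reaction = c("burst production", "binding", "unbinding", "decay"),
    delta_protein = c(NA_integer_, -1L, 0L, -1L),
    gene_from = c("ON", "ON", "OFF", "either"),
    gene_to = c("ON", "OFF", "ON", "unchanged"),
    propensity = list(
      function(gene_on, n) if (gene_on) p$rho_u else 0,
      function(gene_on, n) if (gene_on) p$sigma_b * n else 0,
      function(gene_on, n) if (gene_on) 0 else p$sigma_u,
      function(gene_on, n) p$d * n
    )
  )
}

#' Evaluate all reaction propensities at a state
#'
#' @param params A [feedback_params()] object.
#' @param gene_on Logical; is the gene in the ON state?
#' @param n Protein copy number (nonnegative integer).
#' @return Named numeric vector of the four propensities.
#' @examples
#' theta <- feedback_params(13, 3, 1, 0.001, 0.1)
#' sum(propensities(theta, TRUE, 10))  # total exit rate at (ON, 10)
#' @export
propensities <- function(params, gene_on, n) {
  stopifnot(inherits(params, "feedback_params"), n >= 0)
  c(burst = if (gene_on) params$rho_u else 0,
    binding = if (gene_on) params$sigma_b * n else 0,
    unbinding = if (gene_on) 0 else params$sigma_u,
    decay = params$d * n)
}

#' Default measurement time grid
#'
#' The study design measures population snapshots at unit intervals,
#' `t = 1, 2, ..., t_max` with `t_max = 30` by default.
#'
#' @param t_max Last measurement time.
#' @param dt Grid spacing.
#' @return Strictly increasing numeric vector of measurement times.
#' @export
time_grid <- function(t_max = 30, dt = 1) {
  if (t_max <= 0 || dt <= 0) stop("`t_max` and `dt` must be positive", call. = FALSE)
  seq(dt, t_max, by = dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
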