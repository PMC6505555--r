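#' Simulate a single cell trajectory of the feedback loop
#'
#' Runs the exact stochastic simulation algorithm (Gillespie direct method)
#' for one cell, starting from zero proteins with the gene ON, and records
#' the protein copy number at the requested grid times. Burst sizes are drawn
#' from the geometric law \eqn{\psi(m)} at each production firing (a burst of
#' size 0 changes nothing).
#'
#' @param params A [feedback_params()] object.
#' @param times Strictly increasing, positive measurement times
#'   (see [time_grid()]).
#' @param seed Integer master seed.
#' @param collect_bursts If `TRUE`, also return the burst sizes fired during
#'   the trajectory (used to audit the burst law).
#' @return A tibble with columns `time` and `count`; when
#'   `collect_bursts = TRUE` the burst sizes are attached as attribute
#'   `"bursts"`.
#' @examples
#' theta <- feedback_params(13, 3, 1, 0.001, 0.1)
#' simulate_cell(theta, time_grid(10), seed = 1)
#' @export
simulate_cell <- function(params, times, seed, collect_bursts = FALSE) {
  stopifnot(inherits(params, "feedback_params"))
  check_times(times)
  if (collect_bursts) {
    res <- .ssa_cell_bursts_cpp(params$rho_u, params$b, params$d,
                                params$sigma_b, params$sigma_u,
                                as.numeric(times), as.numeric(seed), 0L)
    out <- tibble::tibble(time = as.numeric(times), count = as.integer(res$counts[1, ]))
    attr(out, "bursts") <- as.integer(res$bursts)
    return(out)
  }
  counts <- .ssa_population_cpp(params$rho_u, params$b, params$d,
                                params$sigma_b, params$sigma_u,
                                as.numeric(times), as.numeric(seed))
  tibble::tibble(time = as.numeric(times), count = as.integer(counts[1, ]))
}

#' Simulate a population snapshot experiment
#'
#' Simulates `n_cells` statistically independent cells with the stochastic
#' simulation algorithm and computes the sample central moments of the
#' protein counts at every grid time. Each cell runs on its own random
#' substream derived from the master seed by a counter scheme, so changing
#' `n_cells` or the grid leaves earlier cells' trajectories unchanged.
#' Moments at different time points are treated as independent downstream,
#' emulating population snapshot (flow cytometry) sampling.
#'
#' For [heterogeneous_params()], each cell's production rate is drawn
#' independently from the configured lognormal before simulation;
#' `sd_rho_u = 0` reproduces the homogeneous run with the same seed exactly.
#'
#' @param params A [feedback_params()] or [heterogeneous_params()] object.
#' @param n_cells Number of cells (>= 2).
#' @param times Measurement time grid.
#' @param k_max Highest central-moment order to compute (1 to 6).
#' @param seed Integer master seed.
#' @return An object of class `snapshot_sample`: a list with `counts`
#'   (integer matrix, cells by time points), `moments` (long tibble, see
#'   [write_moments_csv()]), `times`, `params`, `seed`.
#' @examples
#' theta <- feedback_params(13, 3, 1, 0.001, 0.1)
#' snap <- simulate_population(theta, n_cells = 200, times = time_grid(10),
#'                             k_max = 4, seed = 1)
#' snap$moments
#' @export
simulate_population <- function(params, n_cells, times, k_max = 4, seed = 1L) {
  check_times(times)
  if (n_cells < 2) stop("`n_cells` must be at least 2", call. = FALSE)
  if (!k_max %in% 1:6) stop("`k_max` must be between 1 and 6", call. = FALSE)
  if (inherits(params, "heterogeneous_params")) {
    ln <- rho_u_lognormal(params)
    rho <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
      if (ln$sdlog == 0) rep(params$mean_rho_u, n_cells)
      else stats::rlnorm(n_cells, ln$meanlog, ln$sdlog)
    })
  } else if (inherits(params, "feedback_params")) {
    rho <- rep(params$rho_u, n_cells)
  } else {
    stop("`params` must be feedback_params or heterogeneous_params", call. = FALSE)
  }
  counts <- .ssa_population_cpp(rho, params$b, params$d, params$sigma_b,
                                params$sigma_u, as.numeric(times),
                                as.numeric(seed))
  structure(
    list(counts = counts,
         moments = counts_to_moments(counts, times, k_max, "sample"),
         times = as.numeric(times), params = params, seed = seed),
    class = "snapshot_sample")
}

#' @export
print.snapshot_sample <- function(x, ...) {
  cat(sprintf("<snapshot_sample> %d cells x %d time points\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$params)
  invisible(x)
}

#' Tidy a snapshot sample into long form
#'
#' @param x A `snapshot_sample`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `time`, `count`.
#' @export
tidy.snapshot_sample <- function(x, ...) {
  tibble::tibble(
    cell = rep(seq_len(nrow(x$counts)), times = ncol(x$counts)),
    time = rep(x$times, each = nrow(x$counts)),
    count = as.vector(x$counts))
}

#' Add multiplicative measurement noise to a snapshot sample
#'
#' Perturbs every measurement with independent lognormal multiplicative
#' noise of unit median, `x * exp(e)` with `e ~ N(0, noise_scale^2)`,
#' emulating fluorescence conversion noise on top of the intrinsic
#' stochasticity. `noise_scale = 0` returns the input unchanged. Counts
#' become non-integer; sample moments are recomputed.
#'
#' @param sample A `snapshot_sample`.
#' @param noise_scale Standard deviation of the log-noise, >= 0.
#' @param seed Integer seed for the noise draws.
#' @return A `snapshot_sample` with perturbed measurements.
#' @export
add_measurement_noise <- function(sample, noise_scale, seed = 1L) {
  stopifnot(inherits(sample, "snapshot_sample"))
  if (!is.numeric(noise_scale) || noise_scale < 0) {
    stop("`noise_scale` must be nonnegative", call. = FALSE)
  }
  if (noise_scale == 0) return(sample)
  k_max <- max(sample$moments$order)
  noisy <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    sample$counts * exp(stats::rnorm(length(sample$counts), 0, noise_scale))
  })
  out <- sample
  out$counts <- noisy
  out$moments <- counts_to_moments(noisy, sample$times, k_max, "sample")
  out
}

check_times <- function(times) {
  if (length(times) < 1L || any(times < 0) || any(diff(times) <= 0)) {
    stop("`times` must be nonnegative and strictly increasing", call. = FALSE)
  }
  invisible(times)
}
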