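#' Sample central moments of protein counts
#'
#' Computes the mean and central moments
#' \deqn{\hat\mu_1 = \frac1N \sum_i x_i, \qquad
#'   \hat\mu_k = \frac1N \sum_i (x_i - \hat\mu_1)^k, \; k \ge 2,}
#' with the population (1/N) normalization used throughout the moment
#' likelihood; no small-sample correction is applied.
#'
#' @param x Numeric vector of measurements from one time point (N >= 1).
#' @param k_max Highest central-moment order (>= 1).
#' @return Named numeric vector `mu1`..`muK` (`mu1` is the mean).
#' @examples
#' sample_central_moments(c(1, 2, 3), k_max = 2)  # mean 2, mu2 = 2/3
#' @export
sample_central_moments <- function(x, k_max) {
  if (length(x) < 1L) stop("`x` must contain at least one value", call. = FALSE)
  if (k_max < 1L) stop("`k_max` must be at least 1", call. = FALSE)
  m1 <- mean(x)
  out <- c(m1, vapply(seq_len(k_max)[-1], function(k) mean((x - m1)^k), 0))
  stats::setNames(out, paste0("mu", seq_len(k_max)))
}

# long moment tibble from a counts matrix (cells x times)
counts_to_moments <- function(counts, times, k_max, source, n_cells = nrow(counts)) {
  per_time <- lapply(seq_along(times), function(l) {
    mu <- sample_central_moments(counts[, l], k_max)
    tibble::tibble(time = times[l], order = seq_len(k_max), value = unname(mu))
  })
  out <- dplyr::bind_rows(per_time)
  out$n_cells <- n_cells
  out$source <- source
  out
}

#' Reshape a moment series to wide form
#'
#' Moment series are exchanged as long tibbles with columns `time`, `order`,
#' `value`, `n_cells`, `source`. This helper pivots to one column per order
#' (`mu1`, `mu2`, ...), one row per time point.
#'
#' @param moments A moment-series tibble.
#' @return A wide tibble with columns `time`, `mu1`, `mu2`, ...
#' @export
moments_wide <- function(moments) {
  out <- tidyr::pivot_wider(
    dplyr::select(moments, "time", "order", "value"),
    names_from = "order", values_from = "value", names_prefix = "mu")
  dplyr::arrange(out, .data$time)
}

#' Read and write moment-series CSV files
#'
#' The on-disk format is a flat CSV with columns
#' `time, order, value, n_cells, source`, shared by sample moments, finite
#' state projection moments and closure predictions.
#'
#' @param moments A moment-series tibble.
#' @param path File path.
#' @return `write_moments_csv()` returns `path` invisibly;
#'   `read_moments_csv()` returns the tibble.
#' @export
write_moments_csv <- function(moments, path) {
  readr::write_csv(moments[, c("time", "order", "value", "n_cells", "source")],
                   path)
  invisible(path)
}

#' @rdname write_moments_csv
#' @export
read_moments_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    time = "d", order = "i", value = "d",
                    n_cells = "d", source = "c"))
}

# raw moments (orders 1..3) from central ones and back; used when mixture
# moments over heterogeneous rho_u must be averaged on the raw scale
central_to_raw <- function(m1, mu2, mu3 = NULL) {
  r2 <- mu2 + m1^2
  if (is.null(mu3)) return(cbind(r1 = m1, r2 = r2))
  cbind(r1 = m1, r2 = r2, r3 = mu3 + 3 * m1 * r2 - 2 * m1^3)
}

raw_to_central <- function(r1, r2, r3 = NULL) {
  mu2 <- r2 - r1^2
  if (is.null(r3)) return(cbind(mu1 = r1, mu2 = mu2))
  cbind(mu1 = r1, mu2 = mu2, mu3 = r3 - 3 * r1 * r2 + 2 * r1^3)
}
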