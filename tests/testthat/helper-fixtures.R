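# Shared fixtures: the reference parameter set of the study design and a few
# cached expensive objects (FSP solutions) reused across test files.

theta_ref <- function() feedback_params(13, 3, 1, 0.001, 0.1)

# no-feedback parameter set (linear network: every closure is exact)
theta_linear <- function() feedback_params(13, 3, 1, 0, 0.1)

# small time grid used by most unit tests
tg_short <- function() time_grid(10)

# memoized FSP moments to avoid recomputing across test files
.fsp_cache <- new.env(parent = emptyenv())
cached_fsp_moments <- function(params, times, k_max) {
  key <- paste(c(unlist(unclass(params)), times, k_max), collapse = "|")
  if (is.null(.fsp_cache[[key]])) {
    .fsp_cache[[key]] <- fsp_moments(fsp_solve(params, times), k_max = k_max)
  }
  .fsp_cache[[key]]
}

# scale-aware likelihood weights for closure-self-generated data (which has
# no fourth moments): sigma_1^2 = mu2^2, sigma_2^2 = 2 mu2^2 (the Gaussian
# value of mu4 - mu2^2), keeping both channels on the relative scale the
# moment likelihood uses
scale_weights <- function(pred) {
  w <- moments_wide(pred)
  dplyr::bind_rows(
    tibble::tibble(time = w$time, order = 1L, sigma2 = w$mu2^2),
    tibble::tibble(time = w$time, order = 2L, sigma2 = 2 * w$mu2^2))
}

# independent brute-force implementation of the sample central moments
brute_central_moments <- function(x, k_max) {
  n <- length(x)
  m1 <- sum(x) / n
  out <- numeric(k_max)
  out[1] <- m1
  for (k in seq_len(k_max)[-1]) out[k] <- sum((x - m1)^k) / n
  out
}
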