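# loopmoments

Moment-based parameter inference for the stochastic negative autoregulatory
transcriptional feedback loop — the workhorse motif of gene regulation — and
a test bench for how accurate such inference actually is.

The model is the bursty feedback loop

    G  --rho_u-->  G + mP      (burst size m ~ psi(m) = b^m / (1+b)^(m+1))
    G + P  --sigma_b-->  G*    (protein binds and silences the promoter)
    G*  --sigma_u-->  G
    P  --d-->  0

with five rate constants theta = (rho_u, b, d, sigma_b, sigma_u), or six
when the production rate varies across cells with a lognormal law. Given
population snapshot data (protein counts for N cells at L time points), the
package

* simulates exact synthetic data with a C++ Gillespie engine
  (`simulate_population()`), including lognormal cell-to-cell variability
  and optional multiplicative measurement noise;
* computes ground-truth moments by finite state projection of the chemical
  master equation (`fsp_solve()`, `fsp_moments()`), propagated by
  uniformization with certified probability leak;
* approximates the moment likelihood with six closure schemes
  (`predict_moments()`): the linear noise approximation (LNA), the
  multivariate three-moment zero-cumulant expansion (3MA), derivative
  matching (DM), conditional derivative matching (CDM), the conditional
  Gaussian scheme (CG), and the linear-mapping approximation (LMA);
* estimates parameters by maximizing the Gaussian moment likelihood

      sum_k sum_l ( mu_k(t_l) - mu_k(t_l; theta) )^2 / sigma_k^2(t_l)

  with a self-adaptive differential evolution search (`fit_mle()`), or by
  adaptive Metropolis MCMC with Gelman–Rubin diagnostics (`fit_mcmc()`);
* quantifies accuracy with the standard fractional errors and experiment
  drivers (`fractional_errors()`, `run_closure_benchmark()`, `run_sweep()`,
  `run_heterogeneity_study()`).

Everything is tibble-first and pipe-friendly; fits support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Infinite-sample benchmark: generate exact moments at a known truth, fit
each closure, and read off the systematic error that survives unlimited
data.

```r
library(loopmoments)

theta <- feedback_params(rho_u = 13, b = 3, d = 1,
                         sigma_b = 0.001, sigma_u = 0.1)
bench <- run_closure_benchmark(theta,
                               closures = c("LMA", "CDM", "LNA", "3MA"),
                               data = "fsp", seed = 1)
bench[, c("closure", "mean_fe_pct", "rho_u", "b", "d", "sigma_b", "sigma_u")]
#>   closure mean_fe_pct rho_u     b      d   sigma_b sigma_u
#> 1     LMA       1.315 13.21 2.956 1.0050 0.0009810 0.09892
#> 2     CDM       0.005 13.00 3.000 1.0000 0.0010000 0.10000
#> 3     LNA      22.309 12.28 2.970 0.8824 0.0007421 0.03259
#> 4     3MA       3.942 12.55 3.013 0.9644 0.0010451 0.10771
```

`mean_fe_pct` is the mean over the five parameters of
|estimate − truth| / truth, in percent, for the maximum-likelihood fit. The
conditional and mapping closures (CDM, LMA) recover the rates essentially
exactly; the unconditional expansions (LNA, 3MA) carry large systematic
biases — note the LNA's binding rate at 0.74e-3 against a truth of 1e-3 and
its OFF→ON switching rate at a third of the true value — because their
likelihood approximation cannot represent the promoter-state mixture that
strong feedback creates. This gap is the package's central measurement: it
is invisible at sigma_b → 0 (all closures become exact; the network is
linear) and grows with binding rate, burst size and cell-to-cell
heterogeneity.

A stochastic-data fit works the same way from a snapshot sample:

```r
snap <- simulate_population(theta, n_cells = 1e5,
                            times = time_grid(30), k_max = 4, seed = 1)
lik  <- moment_likelihood(snap$moments, n_cells = 1e5, closure = "CDM")
fit  <- fit_mle(lik, seed = 2)
tidy(fit)
```

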