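---
title: "Moment-based inference for a bursty negative feedback loop: models, closures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based inference for a bursty negative feedback loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmoments)
```

## The model

`loopmoments` studies parameter inference for the canonical stochastic model
of a negatively autoregulated gene. A single gene copy switches between an
active state $G$ and a repressed state $G^*$:

$$G \xrightarrow{\;\rho_u\;} G + mP, \qquad
  G + P \xrightarrow{\;\sigma_b\;} G^*, \qquad
  G^* \xrightarrow{\;\sigma_u\;} G, \qquad
  P \xrightarrow{\;d\;} \varnothing .$$

Proteins are made in bursts of geometrically distributed size,
$\psi(m) = b^m/(1+b)^{m+1}$ for $m \ge 0$ with mean $b$ — the standard
reduction of fast mRNA turnover (translational bursting), so mRNA never
appears explicitly. A protein copy can bind the promoter and silence it;
binding consumes the copy, and reactivation does not return it. All
simulations and solvers start from zero proteins with the gene active. Time
is nondimensional: with $d = 1$ it is measured in protein lifetimes. The
five rate constants $\theta = (\rho_u, b, d, \sigma_b, \sigma_u)$ are the
inference targets; the reference setting used throughout the package's
studies is $\theta = (13, 3, 1, 10^{-3}, 0.1)$ with snapshots at
$t = 1, 2, \dots, 30$.

For heterogeneous populations the production rate varies across cells with
a lognormal law. We parameterize the spread `sd_rho_u` on the **log scale**
(the lognormal's own shape parameter) by default: an arithmetic spread of
0.1 around a mean of 13 would be under 1% variation, too weak to constitute
meaningful extrinsic noise, whereas log-scale spreads of 0.1–0.3 correspond
to 10–30% cell-to-cell variability, the regime reported for transcription
factor expression in yeast. The arithmetic convention remains available via
`rho_u_scale = "arithmetic"` (moment-matched).

## Synthetic data

`simulate_population()` runs the exact stochastic simulation algorithm
(direct method) once per cell, drawing a burst size from $\psi$ at every
production firing, and records protein counts on the measurement grid.
Moments at different time points are treated as independent downstream,
which emulates population snapshot (flow cytometry) data; the residual
within-trajectory autocorrelation is deliberately not corrected, and
`mean_variance_correlation()` quantifies the related within-time-point
coupling of sample mean and sample variance (its grid average is small,
$|\Lambda| \ll 1$, for populations beyond a few hundred cells). Each cell
runs on a counter-derived random substream, so enlarging the population or
refining the grid never re-randomizes earlier cells.

What the generator does *not* emulate: cell division and lineage
correlations, technical fluorescence-to-count conversion bias (only
`add_measurement_noise()`'s idealized unit-median lognormal noise), and
time-correlated single-cell tracking. Passing tests therefore validate the
inference machinery under the model's own assumptions, not robustness to
every real-data artifact.

`fsp_solve()` provides the ground truth: a finite state projection of the
master equation on $\{ON, OFF\} \times \{0..n_{\max}\}$, propagated by
uniformization (substepped so the Poisson series stays well conditioned).
The truncation defaults to $\max(200, 10\rho_u b/d)$ and doubles until the
leaked mass at every grid time is below $10^{-8}$; moments are computed from
the renormalized truncated vector. Uniformization was chosen over a generic
stiff integrator because it is the CME-specific propagator: nonnegative by
construction, with a single series-tolerance knob ($10^{-12}$ here).

## The six likelihood approximations

The Gaussian moment likelihood needs the model-predicted central moments
$\tilde\mu_k(t,\theta)$. The master equation's moment hierarchy does not
close (binding is bimolecular), so six approximation schemes are provided,
all integrated with an adaptive Dormand–Prince RK5(4) (`rtol` $10^{-8}$,
`atol` $10^{-10}$; the closure systems at the studied rate scales are
non-stiff — eigenvalues of order $d$ — so an implicit method is
unnecessary, and bail-outs at pathological parameter corners are flagged
and penalized rather than silently clipped):

* **LNA** — deterministic rate equations for the gene-ON probability and
  protein mean plus the Lyapunov equation for the fluctuation covariance.
  The burst reaction contributes $\rho_u E[m] $ to the drift and
  $\rho_u E[m^2]$ to the diffusion, with the exact geometric moments
  $E[m] = b$, $E[m^2] = 2b^2 + b$. Third central moments are identically
  zero.
* **3MA** — the standard multivariate moment expansion over the species
  pair (gene, protein): exact equations for all raw moments
  $\langle g^a n^c \rangle$, $a + c \le 3$, with the gene treated as an
  ordinary species (as generic moment-closure software constructs it), and
  every fourth-order moment replaced by its zero-fourth-cumulant
  expression. Nine coupled ODEs.
* **DM** — derivative matching on the binarity-reduced hierarchy: using
  $g^2 = g$, only $\langle g n^3\rangle$ is unclosed; it is replaced by the
  separable product
  $\langle g\rangle \langle n\rangle^3 \langle gn\rangle^{-3}
   \langle n^2\rangle^{-3} \langle gn^2\rangle^{3} \langle n^3\rangle$,
  whose exponents solve the derivative-matching conditions (binomial
  moment-matching at the initial time).
* **CDM** — method of conditional moments: partial moments
  $y_j = \langle g n^j \rangle$ (gene ON) and $z_j$ (gene OFF) evolve
  exactly except for the highest ON-conditional moment, closed by
  univariate derivative matching ($\nu_3 = \nu_2^3/\nu_1^3$ at conditional
  order two; at `k_max = 3` the hierarchy extends one order and closes
  $\nu_4 = \nu_3^4 \nu_2^{-6} \nu_1^4$).
* **CG** — the conditional Gaussian scheme: same partial-moment system,
  closed by zeroing the third conditional cumulant; its third moment is
  reported from the closure ansatz.
* **LMA** — linear-mapping approximation: the bimolecular binding reaction
  is replaced by an effective first-order switch with rate
  $\sigma_b \langle n \mid ON\rangle$, evaluated self-consistently from the
  evolving state (the conditional mean is already part of the partial
  moment vector, so no outer iteration is needed). The mapped bursty
  telegraph system's moment equations are exact and closed.

Two structural decisions deserve emphasis, both taken after validating
against the projection solver. First, the unconditional expansion (3MA)
deliberately does **not** exploit the gene's binary algebra: tracking
$\langle g^2\rangle, \langle g^3\rangle$ as free variables is how the
generic multivariate construction operates, and it is this scheme whose
accuracy collapses at strong feedback and large bursts — the behaviour the
benchmarking studies quantify. Exploiting $g^2 = g$ everywhere (as DM does)
leaves a single $\sigma_b$-damped closure term and is dramatically more
accurate at these parameter sets. Second, the conditional schemes condition
on both promoter states with two exact partial hierarchies; the OFF-state
equations need no closure at conditional order two because the OFF state
produces nothing.

Every scheme is validated by an exactness property: at $\sigma_b = 0$ the
network is linear, all six systems coincide with the exact moment
equations, and the test suite requires agreement with the projection solver
to $10^{-4}$ relative. Degenerate inputs are handled by flags, not clips: a
negative predicted variance or a failed integration marks the prediction,
and the likelihood assigns it an infinite penalty.

For heterogeneous populations, population moments are the lognormal mixture
of conditional-on-$\rho_u$ solutions, combined on the raw-moment scale by
Gauss–Hermite quadrature (20 nodes by default; doubling the order moves the
population moments by under $10^{-4}$ relative at the studied spreads, and
a convergence test guards this).

## Likelihood, weights and estimators

With $N$ cells per time point, the sample moments are asymptotically
Gaussian and the likelihood factorizes over moment orders and times. The
objective minimized is

$$\sum_{k=1}^{K}\sum_{l=1}^{L}
  \frac{\bigl(\hat\mu_k(t_l) - \tilde\mu_k(t_l,\theta)\bigr)^2}
       {\sigma_k^2(t_l)},$$

with the per-moment variances built from higher sample moments:
$\sigma_1^2 = \hat\mu_2^2/N$,
$\sigma_2^2 = (\hat\mu_4 - \tfrac{N-3}{N-1}\hat\mu_2^2)/N$,
$\sigma_3^2 = (\hat\mu_6 - \hat\mu_3^2)/N$. The $\hat\mu_2^2$ form of the
first-moment weight is the study's convention: it places the mean channel
on the same squared scale as the variance channel, i.e. it weights relative
rather than absolute mean errors. The textbook alternative
$\sigma_1^2 = \hat\mu_2/N$ (the exact variance of the sample mean) is
available as `mean_weight = "exact"`; the choice is immaterial for a
well-specified model (the arg-min sits at the data-generating parameters
either way) but shifts the compensation pattern of misspecified closures.
For infinite-sample (projection-derived) data the common $1/N$ cancels from
the arg-min and is dropped. The diagnostic `mean_variance_correlation()`
intentionally uses the exact standard errors, since it estimates an actual
correlation coefficient and is checked against bootstrap resampling.

**MLE.** `fit_mle()` works on $\ln\theta$ (positivity by construction) over
a box of three decades either side of a coarse moment-matching guess. The
guess reads the burst size off the first time point's Fano factor (early
snapshots are dominated by unregulated bursty production, for which
variance/mean $\approx 1 + b$), the decay rate off the half-rise time, and
the production rate off the plateau mean. The global search is a
self-adaptive differential evolution (per-member $F$ and $CR$ mutating with
probability 0.1, population $15 p$, evaluation budget $5\times 10^4$, stall
window 60 generations), seeded with the guess and polished by Nelder–Mead
from the DE winner, a well-separated runner-up, and the guess — the extra
polish starts matter because misspecified closures develop broad degenerate
basins (e.g. fast-switching mimics) that can shadow the narrow
data-consistent valley. Fits are bit-reproducible given a seed.

**MCMC.** `fit_mcmc()` is an adaptive Metropolis sampler in $\ln\theta$
with a uniform prior on the same box: after a non-adaptive warm start the
proposal covariance tracks the running chain covariance (scaled
$2.38^2/p$), and a Robbins–Monro global scale targets the classical 0.234
acceptance rate — without it, the extremely sharp posteriors at
$N = 10^5$ leave a fixed-scale random walk effectively frozen. Four chains
by default; convergence is summarized by split Gelman–Rubin $\hat R$ with
threshold 1.1, and results are flagged rather than silently accepted when
it fails. Chains are initialized near a supplied point (jittered), by
default the moment-matching guess; for estimator-agreement studies they are
started at the MLE, because misspecified-closure posteriors can carry
far-apart local modes separated by valleys thousands of log-units deep that
no random walk crosses — the scientific question there is where the
posterior mode lies, not whether a random walk can find it from an
arbitrary start. The MAP is extracted as the posterior sample maximizing a
product-Gaussian kernel density in log space (joint mode); marginal modes
are reported alongside, since marginal panels are what posterior figures
display and the two can differ slightly for skewed posteriors.

## Error metrics and study drivers

`fractional_errors()` implements the three per-parameter fractional errors
(MLE vs MAP, MAP vs truth, MLE vs truth); "mean FE" is always their
arithmetic mean over parameters, reported in percent. The drivers —
`run_closure_benchmark()` (one data set, all closures),
`run_sweep()` (systematic error across the $(\sigma_b, b, \rho_u)$ grid on
infinite-sample data), and `run_heterogeneity_study()` (six-parameter
lognormal-mixture inference) — return one tidy row per fit.
The heterogeneous fit is warm-started from the five-parameter homogeneous
fit of the same data, which the model nests at zero spread.

## Problem sizes and reproducibility

The bundled studies use the scales the package's tests exercise: $L = 30$
unit-spaced snapshots for the benchmarks (the number of time points has
little influence on the error, so the moment-order comparison uses
$L = 10$); infinite-sample benchmarks from the projection solver at $b = 3$
and $b = 10$; stochastic-simulation studies at $N = 10^4$–$10^5$ cells;
heterogeneity at $N = 10^5$ with log-scale spread 0.3; sweep grids of
$3 \times 3$ in $(\sigma_b, b)$; ten independent replicates for the
moment-order comparison. `scripts/acceptance.R` re-runs
the main studies end to end from a single seed and writes the headline
numbers as JSON.

## Known limitations

* The unconditional zero-cumulant expansion (3MA) is shipped in its generic
  multivariate form; a binarity-aware variant closing only
  $\langle g n^3\rangle$ is far more accurate on this network (DM is that
  construction with a different closure rule), so the 3MA's large errors
  quantify the generic construction specifically.
* Closure accuracy claims are validated against the finite state
  projection on the tested parameter ranges ($b \le 10$,
  $\sigma_b \le 10^{-2}$, $\rho_u \approx 13$, $\sigma_u = 0.1$); outside
  them the flagged-failure machinery still operates but accuracy is
  uncharacterized.
* Posterior widths are reported but not calibration-tested; the MCMC
  warm-start strategy means multimodal posteriors are summarized around the
  dominant (likelihood-preferred) mode.
* The mapped system of the LMA omits the single protein consumed per
  binding event; at the studied copy numbers (tens to hundreds) this is
  negligible and is part of the approximation being benchmarked.

## A worked mini-example

```{r example, eval = FALSE}
theta <- feedback_params(rho_u = 13, b = 3, d = 1,
                         sigma_b = 0.001, sigma_u = 0.1)
tg <- time_grid(30)

snap <- simulate_population(theta, n_cells = 2e4, times = tg,
                            k_max = 4, seed = 1)
lik <- moment_likelihood(snap$moments, n_cells = 2e4, closure = "CDM")
fit <- fit_mle(lik, seed = 2)
tidy(fit)
fractional_errors(theta_mle = fit, theta_true = theta)
```
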