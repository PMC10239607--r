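---
title: "Behaviour-dependent habitat selection with state-switching step selection functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour-dependent habitat selection with state-switching step selection functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchSSF)
```

## The model

Animal telemetry delivers locations $y_1, \dots, y_T$ at a regular interval.
A *step selection function* (SSF) models the density of a step's endpoint
given its start,

$$
p(y_{t+1} \mid y_t) \;=\;
\frac{\exp\{c(y_t, y_{t+1}) \cdot \beta\}}
     {\int_{z \in \Omega} \exp\{c(y_t, z) \cdot \beta\} \, dz},
$$

where $c(\cdot,\cdot)$ collects habitat covariates at the endpoint and
movement covariates of the step, and $\Omega$ is the study area. With the
movement covariates $(L, \log L, \cos\theta)$ — step length, its log, and the
cosine of the turning angle — the exponential form encodes a gamma
distribution of step lengths and a von Mises distribution of turning angles:

* gamma shape $= \beta_{\log L} + 2$, rate $= -\beta_L$, hence mean
  $\mu_L = (\beta_{\log L} + 2)/(-\beta_L)$ and standard deviation
  $\sigma_L = \sqrt{\beta_{\log L} + 2}/(-\beta_L)$
  (`gamma_from_coeffs()`);
* von Mises concentration $\kappa = |\beta_\theta|$ with angular mean $0$
  (persistence) for $\beta_\theta \ge 0$ and $\pi$ (reversals) otherwise
  (`vonmises_from_coeff()`).

Because the coefficients are estimated unconstrained, the implied gamma
parameters can be invalid ($\beta_{\log L} + 2 \le 0$ or $\beta_L \ge 0$);
the transform then flags the state instead of erroring. Constrained
estimation is deliberately not implemented.

The package embeds this SSF as the observation model of a hidden Markov
model: each latent behavioural state $S_t \in \{1,\dots,K\}$ carries its own
coefficient vector $\beta^{(k)}$, so states are defined jointly by movement
*and* habitat selection. The state process is a first-order Markov chain
whose transition probabilities may depend on covariates through a
multinomial logit,

$$
\gamma^{(t)}_{ij} = \frac{\exp(\eta^{(t)}_{ij})}{\sum_k \exp(\eta^{(t)}_{ik})},
\qquad
\eta^{(t)}_{ij} = \alpha_0^{(ij)} + \textstyle\sum_p \alpha_p^{(ij)} \omega_p^{(t)}
\ (i \ne j), \qquad \eta^{(t)}_{ii} = 0 .
$$

The structural zero on the diagonal anchors the scale of each row; it is
load-bearing (tested) — adding a constant to the off-diagonal predictors
changes the matrix. Time of day enters as the cyclic pair
$(\cos 2\pi\tau/24,\ \sin 2\pi\tau/24)$ (`cyclic_time_covariates()`). The
number of states $K$ is fixed by the analyst, never estimated.

## Likelihood approximation

The normalising integral is intractable and is approximated by Monte Carlo
over $N$ control endpoints per observed step (a case–control design). With
controls drawn from an importance density $h$,

$$
\tilde p(y_{t+1} \mid S_t = k, y_t) =
\frac{\exp\{c(y_t, z_{0t}) \cdot \beta^{(k)}\}}
     {\frac{1}{N+1} \sum_{i=0}^{N}
       \exp\{c(y_t, z_{it}) \cdot \beta^{(k)}\} / h(y_t, z_{it})},
$$

where $z_{0t} = y_{t+1}$ is the observed endpoint. Two schemes are provided:

* `uniform_disc`: uniform on a disc of radius $R$ about $y_t$,
  $h = 1/(\pi R^2)$ — plain Monte Carlo up to the constant disc area;
* `gamma_radial` (default, $N = 25$): distance drawn from a gamma
  distribution moment-matched to the pooled observed step lengths (all
  individuals, no state stratification), direction uniform. The planar
  density is $h(z) = f_\Gamma(r)/(2\pi r)$; the $1/(2\pi r)$ factor is the
  polar-coordinates Jacobian of the uniform angle. A histogram-versus-density
  test pins the implementation of $h$ to the sampler.

Numerical conventions worth knowing:

* everything is computed on the log scale with grouped log-sum-exp (C++);
* the observed endpoint always contributes to the denominator; its weight
  uses $h$ at the observed step length, and a disc that excludes an observed
  step is an error (increase $R$);
* controls with unextractable covariates (off the raster, missing cells) are
  dropped and the divisor becomes the per-step count of valid endpoints; a
  step whose *observed* endpoint is invalid is dropped whole, with a warning;
* the per-step normalising constant of the approximation is shared across
  states, so rescaling all $h$ by a constant shifts the total negative
  log-likelihood by exactly (number of steps) × log(constant) while leaving
  estimates, standard errors and decoding untouched. The tests assert the
  exact shift and the invariance of the between-state density ratios rather
  than pretending the likelihood value itself is invariant.

**A caveat on importance-weight tails.** The weight ratio behaves like
$r^{a_k - a_h}$ near $r = 0$, where $a_k$ is the gamma shape implied by the
state's coefficients and $a_h$ the pooled importance shape. A state with a
much lower shape than the pooled distribution (very slow, tortuous movement
pooled with fast movement) makes the importance weights heavy-tailed near
the origin and inflates Monte Carlo error. The oracle tests therefore
moment-match their kernels to the fixture tracks; for real analyses with
very distinct states, raising `N` is the simple remedy.

## Fitting

The likelihood combines the per-step densities and transition matrices
through the scaled forward algorithm (the standard underflow-safe
recursion, renormalising the forward vector at every step; C++ inner
loop). Per track, the initial distribution is the
stationary distribution of that track's first transition matrix, solved as
a linear system. The first step of each track (no previous bearing, so no
turning angle) and steps involving missing locations contribute identity
matrices and are excluded from decoding output. Multiple individuals are
completely pooled: one parameter set, summed negative log-likelihoods.

`fit_hmmssf()` minimises the negative log-likelihood with BFGS
(finite-difference gradients, relative tolerance `1e-8`, up to 1000
iterations — the optimiser settings are package decisions, exposed as
arguments). Starting values follow a two-stage idea used only for starts:
observed steps are split into $K$ speed classes by step-length quantiles,
each class is moment-fitted (gamma for lengths, mean-cosine inversion for
the concentration), transition intercepts start at $-2$, everything else at
zero; `n_starts` (default 10) perturbs this heuristic with Gaussian noise
and the best optimum is kept, with the per-start negative log-likelihoods
reported. After fitting, states are relabelled by ascending implied mean
step length (slow state first) — a deterministic resolution of label
switching; the Hessian, covariance and summary are permuted consistently.

Standard errors come from the inverse of a finite-difference Hessian at the
optimum; the covariance is an eigenvalue pseudo-inverse with a conditioning
warning when the smallest eigenvalue drops below $10^{-10}$ of the largest,
in which case the affected standard errors are reported as unavailable
rather than silently wrong. Confidence bands for transition probabilities
(`transition_cis()`) are built on the linear-predictor scale with the
delta method and mapped through the multinomial-logit link, so they stay in
$[0, 1]$; a parametric-bootstrap oracle in the tests confirms the widths to
within 15%. Bands for stationary state probabilities (`stationary_cis()`)
use a finite-difference gradient of the stationary distribution.

## Decoding and space use

`viterbi_states()` (global decoding, log space, ties broken toward the
lower state index) and `local_probs()` (scaled forward–backward) both run
per track. The locally most probable sequence is also returned; it is
usually close to, but not identical with, the Viterbi sequence, and the
tests assert agreement, not equality. `stationary_probs()` evaluates the
stationary distribution over a covariate grid — e.g. the long-run
probability of each state by time of day.

`simulate_track()` simulates from a (fitted or specified) model: a state
sequence from the transition model, then at each step `n_proposals`
(default 10,000) endpoints uniform on a disc of radius `r` (default
$\mu_L + 5\sigma_L$ of the fastest state, which covers the vast majority of
kernel mass; with data, 1.1 × the maximum observed step is the conventional
choice), weighted by the state's selection function, with weight zero
outside the study-area boundary (reflective by rejection). The utilisation
distribution (`estimate_ud()`) is a Gaussian-kernel density on the
landscape lattice — histogram plus separable Gaussian blur, renormalised
over the grid; the kernel is an assumption, as is common. State-specific
distributions keep only the endpoints of steps in one state.

**A caveat on proposal discretisation.** The 2D step density contains a
$1/L$ Jacobian, so for gamma shapes below 2 it diverges (integrably) at the
origin, and a finite uniform proposal set under-represents the shortest
steps: simulated slow states then look slightly faster than specified.
Shape ≥ 2 keeps the selection weights bounded and the scheme accurate at
desk-scale proposal counts; the proposal count is exposed precisely because
this bias shrinks with coverage.

## The synthetic world

`generate_landscape()` produces continuous layers (Gaussian-smoothed white
noise with a tunable autocorrelation range `patch_scale`) and categorical
layers (a smoothed field thresholded at the quantiles that hit target
proportions), reproducibly from a seed. The recovery harness
(`recovery_study()`) runs the simulate → refit loop with sub-seeds derived
deterministically from a master seed and reports per-parameter mean error,
RMSE and 95% CI coverage.

The acceptance-scale world is one individual, 30-minute interval, a smooth
continuous covariate with autocorrelation range (0.5 map units) comparable
to the movement scale, two shape-2 gamma states (mean steps 0.1 and 0.5
units, concentrations 0.2 and 1.5, selection +1 and −0.5) and a diel
transition cycle with published-scale coefficients. Shape-2 states were
chosen once, for the discretisation reason above, and are realistic for
movement data. Known bias regimes are deliberately reachable: covariate
autocorrelation much larger than the movement scale biases habitat
coefficients, which `patch_scale` lets tests probe; no automatic guard is
applied.

What a green test establishes — and what it does not: the generator
emulates gamma/von Mises movement, smooth or patchy habitat, diel switching
and missing fixes; it does not emulate GPS measurement error, irregular
sampling, individual heterogeneity (the model pools completely), or
temporally varying rasters. Parameter recovery on this world validates the
estimation machinery, not the model's adequacy for any particular species.

## Interfaces and environment notes

Rasters are read and written as ESRI ASCII grids; cell values apply to
half-open squares $[x_0, x_0 + \mathrm{res})$, categorical extraction is
strictly nearest-cell, and continuous layers offer bilinear interpolation
as an option (nearest-cell is the default and the convention used
throughout the fitting pipeline). GeoTIFF is not supported in this build —
no raster backend is available in the target environment — and the reader
says so explicitly. All geometry is in projected planar map units;
geographic coordinates are out of scope because the SSF needs a metric
plane.

The command-line workflows (`cmd_fit()`, `cmd_decode()`, `cmd_simulate()`,
`cmd_simdata()`, and the `inst/cli/switchssf` script) are driven by a JSON
config (JSON rather than YAML: no YAML parser in the target environment)
with fail-fast validation that names the offending field. Every command
writes a manifest with the config checksum, seed and package version; all
randomness flows from the config's master seed. Zero-length steps are a
hard error naming the offending rows — silently dropping or absorbing them
would bias the gamma fit — with `jitter_track()` as the opt-in remedy.

## Known limitations

* Exponential-form SSFs only: no wrapped-Cauchy or multimodal turning
  angles, no Weibull/half-normal step lengths.
* No EM fitting, no random effects, no estimation of $K$.
* Importance sampling is not state-specific (a single pooled $h$), which is
  the main Monte Carlo accuracy limit when states differ strongly.
* The delta-method bands are pointwise and rely on asymptotic normality of
  the working-scale estimates.
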