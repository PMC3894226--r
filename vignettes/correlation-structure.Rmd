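---
title: "Pairwise correlations in finite binary-neuron networks: model, solvers, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise correlations in finite binary-neuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binnet)
```

## The model

binnet studies a recurrent network of stochastic binary neurons: two local
populations, excitatory ($E$) and inhibitory ($I$), receive input from each
other, from themselves, and from a *finite* external population ($X$) of
pairwise-uncorrelated binary sources. Neuron $i$ carries a state
$n_i \in \{0, 1\}$. Update times form independent Poisson processes with rate
$1/\tau$; at an update the neuron becomes active iff its summed synaptic
input, delayed by a short transmission delay, exceeds a hard threshold
$\theta$ (Heaviside gain, with the tie $h = \theta$ resolved to inactive).
Every neuron in population $\alpha$ receives $K_{\alpha\beta}$ randomly drawn
inputs of weight $J_{\alpha\beta}$ from population $\beta$ — exactly that
many under the fixed in-degree rule, or binomially distributed under the
Erdős–Rényi rule. Because the external pool is finite, two local neurons
share on average $K_{\alpha X}^2/N_X$ external afferents; $N_X$ therefore
dials the strength of externally imposed input correlations, from identical
input ($K_{\alpha X} = N_X$) through weakly shared input (large $N_X$) to a
constant, fluctuation-free drive (dc mode).

The scientific question the package addresses is how the *structure* of
zero-lag pairwise covariances — the population-averaged $c_{EE}$, $c_{EI}$,
$c_{II}$ and the local–external $c_{EX}$, $c_{IX}$ — emerges from the
interplay of shared input and recurrent (chiefly inhibitory) feedback, at
finite network size.

## Mean-field working point

With many weak afferents the summed input is approximately Gaussian with
moments
$$\mu_\alpha = \sum_\beta K_{\alpha\beta} J_{\alpha\beta} m_\beta, \qquad
  \sigma^2_\alpha = \sum_\beta K_{\alpha\beta} J^2_{\alpha\beta}
  m_\beta (1 - m_\beta),$$
and the stationary activity solves $m_\alpha = \Phi\!\big((\mu_\alpha -
\theta_\alpha)/\sigma_\alpha\big)$ self-consistently
(`solve_mean_field()`, a damped Newton iteration with finite-difference
Jacobian started from the balance condition $\mu = \theta$). The
susceptibility $S_\alpha$ — the Gaussian input density at threshold — is the
derivative of the activity with respect to the mean input and sets the
linearized population coupling $w_{\alpha\beta} = S_\alpha K_{\alpha\beta}
J_{\alpha\beta}$. Note the self-regulation $S \propto 1/\sigma$: rescaling
all weights leaves $S\sigma$, and with it the covariance structure, largely
unchanged; effective couplings grow only like $\sqrt{K}$.

## The covariance system

Linearizing the master equation of the binary dynamics around the working
point and averaging over disjoint neuron pairs closes the moment hierarchy at
second order and yields a linear system for the five covariances, driven by
the single-neuron variances $a_\alpha = m_\alpha(1 - m_\alpha)$:

* the local–external pair ($c_{EX}, c_{IX}$) solves a closed $2\times 2$
  system driven by $a_X/N_X$ alone — it is independent of the local
  covariances (`solve_external_block()`);
* the local block ($c_{EE}, c_{EI}, c_{II}$) solves a $3\times 3$ system
  driven by the intrinsic sources $a_E/N_E$, $a_I/N_I$ and by
  ($c_{EX}, c_{IX}$) (`solve_internal_block()`).

A convention had to be fixed for the diagonal "self" term that accounts for
one neuron of a pair being among the other's afferents: binnet uses the
source form $w_{\alpha\beta}\, a_\beta/N_\beta$, i.e. it approximates the
covariance matrix of population-averaged activities as
$C = \mathrm{diag}(a/N) + c$. This choice makes two structural statements of
the theory *exact* rather than $O(c/N)$-approximate: the external pool size
shifts all three local covariances by a common offset without changing their
differences (for homogeneous connectivity the splitting
$c_{EE} - c_{EI} = c_{EI} - c_{II}$ is exactly $N_X$-independent), and the
perfect-tracking covariance structure satisfies the input-cancellation
identity exactly (below). The alternative counting (subtracting $c_{\beta\beta}/N$)
differs by terms two orders below the covariances themselves.

Solutions are linear in the sources, so the full solution splits exactly into
an **external** contribution ($\propto a_X/N_X$) and an **intrinsic** one
($\propto a_E/N_E, a_I/N_I$): `solve_correlations(sources=)` and
`decompose_contributions()`. In dc mode $a_X = 0$ and the external
covariances vanish identically.

### Finite-size iteration

The plain mean field ignores afferent correlations when computing
$\sigma^2$. `input_variance_with_correlations()` adds the exact cross terms
— $K(K-1)$ ordered within-block pairs and $K_\beta K_\gamma$ cross-block
pairs, so that a perfectly correlated block reproduces the variance
$(KJ)^2 a$ of identical signals — and `iterate_self_consistent()` alternates
covariance and mean-field solves until the joint fixed point is reached
(default tolerance $10^{-10}$, damping 0.5 engaged only if the alternation
oscillates; in practice 3–5 sweeps suffice). In inhibition-dominated
networks the correction *lowers* the input variance (the dominant afferent
covariances are negative), raises the susceptibility, and measurably
improves the predicted input distribution and covariances.

## Cancellation of input correlations

The covariance between the summed inputs of two neurons splits into a
shared-afferent part and an afferent-correlation part,
$$q^{shared} = \sum_\beta J^2_{\alpha\beta} \frac{K^2_{\alpha\beta}}{N_\beta}
  a_\beta, \qquad
  q^{corr} = \sum_{\beta\gamma} J_{\alpha\beta} J_{\alpha\gamma}
  K_{\alpha\beta} K_{\alpha\gamma}\, c_{\beta\gamma},$$
whose sum equals, algebraically, the variance of the population-averaged
input signal (`input_correlation_theory()` verifies the identity to machine
precision on every call, and `population_average_identity_check()` does the
same for recorded data, exactly under exhaustive pair enumeration). Negative
feedback suppresses fluctuations of the population-averaged input; by the
identity this *is* the cancellation of input correlations: the two parts are
large, of opposite sign, and cancel to within $\sim 15\text{–}20\%$ of the
smaller part on the canonical fixtures. The mechanism needs no
excitatory–inhibitory balance: a purely inhibitory population shows it too,
with the closed form $c = (w\,a/N)/(1 - w)$, $w = SKJ < 0$, giving
$q^{corr}/q^{shared} = w/(1-w) \to -1$ at strong coupling while the total
input covariance $\propto 1/(1-w)$ stays positive.

## Infinite-size limits and fast tracking

On a ladder that scales all populations at fixed connection probability
(in-degrees grow with $N$; thresholds are re-derived each rung to hold the
working activity), effective couplings grow as $\sqrt{N}$ and the two
contributions scale differently:

* **invertible structural coupling** (weights depend on source *and*
  target): the external/tracking part carries the leading $1/N$ behaviour,
  approaching $c^{ext}_{\alpha\beta} = u_\alpha u_\beta\, a_X/N_X -
  \delta_{\alpha\beta} a_\alpha/N_\alpha$ with $u$ the susceptibility-free
  tracking gain $(KJ)_{local}^{-1}(KJ)_X$ (`limit_inhomogeneous()`); the
  intrinsic part decays faster than $1/N$ (asymptotically $N^{-3/2}$,
  because the feedback suppressing it grows as $\sqrt{N}$). Convergence is
  slow: over $N = 2^9\ldots2^{15}$ per population the fitted intrinsic slope
  is only $\approx -1.2$ and the external slope $\approx -1.07$, with the
  $N^{-1/2}$ prefactor drift still visible throughout. The default
  attribution of the diagonal $a/N$ term to the external part follows this
  limit; `self_term = "intrinsic"` attributes it to the locally generated
  fluctuations instead (then dc mode yields an exactly zero external part).
* **homogeneous (degenerate) coupling** (weights depend only on the source
  type): the coupling matrix has exactly one zero eigenvalue — a
  feedback-free direction along which intrinsic fluctuations persist — and
  *both* contributions scale as $1/N$ (`limit_homogeneous()`, in which all
  susceptibilities cancel). The equidistant splitting between $c_{EE}$,
  $c_{EI}$, $c_{II}$ is intrinsic and survives at every size.

`fast_tracking_prediction()` gives the covariance structure implied by
assuming the local population average perfectly follows the external signal.
It satisfies the cancellation identity exactly, yet at finite size predicts
the wrong structure (it even reverses the sign of the $c_{EE} - c_{EI}$
splitting): cancellation constrains the covariances but does not determine
them.

## Heterogeneous in-degrees

Under the binomial rule the time-averaged activity varies across neurons.
`solve_heterogeneous()` solves the coupled moment system for the population
mean $M$ and second moment $q$: the across-neuron variance of the mean input
sums an in-degree term $J^2 N p(1-p) M^2$ (droppable via
`include_indegree_term`, and kept by default — the realization-ensemble test
adjudicates it) and a rate-spread term $J^2 K (q - M^2)$; the time variance
uses the population-averaged single-neuron variance $a = M - q$, which is
also the bridge into the covariance solver. The density of time-averaged
activities is the Gaussian input distribution pushed through the single-cell
gain (`activity_distribution()`); its quadrature moments reproduce $(M, q)$,
integrals are taken over $\pm 8$ input standard deviations.

## Simulator and estimators

The simulator (Rcpp) realizes the dynamics on a grid of step
$dt = \tau/100$: per-neuron exponential update intervals rounded to the grid
(at most one update per neuron per step), state flips propagated to the
input accumulators of all targets with a delay of one grid step (zero-lag
statistics are insensitive to small delays), external sources activating
with probability $m_X$ per update. Runs start from the mean-field activity
and discard a $50\tau$ transient; states are sampled every $\tau/10$ for
statistics in the larger runs. Pairwise covariances use the plug-in
estimator over disjoint pairs (at most $N/2$ per same-population label);
standard errors are taken across pairs, which dominate the uncertainty.
For large networks, per-pair coincidence counts are accumulated inside the
C++ loop so the full state matrix is never stored.

## What the validation does and does not show

All validation data come from the package's own simulator, under the exact
model assumptions of the theory (Poisson updates, hard threshold, random
graphs). Passing tests therefore demonstrate the internal correctness of
the solvers and the accuracy of the Gaussian/linearized approximation for
this model class — not the fidelity of binary neurons to biological
networks (no conductances, refractoriness, synaptic dynamics, or spatial
structure). Within the model, the residual systematic error of the theory
is visible in the mean activities: at the default working point
($m \approx 0.2$, $K = 100$) the simulated means deviate from the iterated
self-consistent values by $\sim 0.2\text{–}0.3\%$ relative — smaller than
the statistical error of short runs but resolvable in long ones; it stems
from the linearization and the Gaussian input assumption (agreement is best
near $m = 0.5$, where the gain is locally symmetric) and is independent of
the grid step. Covariance predictions agree with simulation within their
(pair-dominated) statistical errors on all tested conditions.

Problem sizes used by the test suite were chosen to make every stochastic
comparison sign- and structure-resolving while keeping a full run in the
minutes range: the flagship comparisons pool 5 seeds of $2000\tau$ with 1000
pairs per label at $N_E = N_I = 2000$; scaling studies are theory-only on
$N = 2^9\ldots2^{15}$; exact identities run on 20+20-neuron networks with
exhaustive pair enumeration.

## Worked example

```{r example, eval = FALSE}
spec <- fixture_spec("three_population", N_X = 400)
th <- network_theory(spec)          # mean field + iterated covariances
summary(th)
est <- simulate(th, nsim = 1, seed = 1, duration = 1000 * spec$tau)
est                                  # empirical covariances with SEs
plot(th, empirical = est)
```

The fixture families (`fixture_spec()`, `make_fixtures()`) encode the
canonical scenarios: the external-pool sweep on the homogeneous
three-population network, the invertible-coupling variant, its
binomial-in-degree version, the purely inhibitory network without external
fluctuations, and the base network of the structural sweeps, in which the
two weight combinations that shift and split the coupling eigenvalues are
varied at a re-balanced working point of $m = 0.5$ up to the degenerate-row
endpoint (largest covariances) and down to the purely cross-coupled,
oscillatory (complex-eigenvalue) configuration.
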