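---
title: "Takeover times of a contact infection: models, limits and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Takeover times of a contact infection: models, limits and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(takeover)
```

## The model

The package simulates the simplest contact process with permanent,
infinitely transmissible infection on an undirected connected graph of
$V$ nodes. Time is discrete. At each step a node $i$ is drawn uniformly
from the whole graph, then one of its neighbors $j$ uniformly from
$i$'s adjacency list. If $i$ is infected and $j$ susceptible, $j$
becomes infected; in every other case nothing changes, but the step
still counts — *wasted steps advance the clock*. Starting from a single
infected source, the takeover time $T$ is the number of steps until all
$V$ nodes are infected, and the partial takeover time $T_\theta$ the
number of steps until $\lfloor \theta V \rfloor$ nodes are infected
(the source counts; if $\lfloor \theta V \rfloor \le 1$ the answer is 0
by definition — the model itself never considers that corner, so we fix
it by convention).

Three deliberate simplifications define the scope: transmission always
succeeds on an infected–susceptible contact, infection is permanent (no
SIS/SIR recovery), and updates are asynchronous (one pair per step).
Under these rules the infected set only grows and always forms a
contiguous region.

## Geometric-chain reduction

When the probability $p_m$ that the next step creates an infection
depends only on the number $m$ of infected nodes, the stage durations
are independent geometric variables $X(p_m)$ on $\{1, 2, \dots\}$ and
$T = \sum_m X(p_m)$. The package carries these stage rates as
`rate_vector` tibbles:

* ring: $p_m = 1/N$ for every stage — mean $N(N-1)$, variance
  $N(N-1)^2$;
* star (source at the hub, $m$ infected spokes):
  $p_m = \frac{1}{N+1}\frac{N-m}{N}$, the coupon collector's factor
  $(N-m)/N$ damped by the chance $1/(N+1)$ of drawing the hub — mean
  $N(N+1)H_N$;
* complete graph: $p_m = \frac{m}{N}\frac{N-m}{N-1}$, a palindrome
  ($p_m = p_{N-m}$), so the endgame replays the opening in reverse.

`chain_moments()` returns the exact mean, variance and skewness from
the geometric cumulants ($\kappa_3 = q(1+q)/p^3$). On lattices with
$d \ge 2$ and on random graphs $p_m$ is *not* well defined (the success
probability depends on the cluster's shape), and `graph_rates()`
refuses rather than approximate.

## Limit laws

* **Ring.** All stages are iid; a triangular-array central limit
  theorem applies and $(T - N(N-1)) / ((N-1)\sqrt N)$ tends to
  Normal(0, 1). The inline normalizer is implemented as
  $(N-1)\sqrt N$, the unique reading consistent with the exact variance
  $N(N-1)^2$.
* **Star.** Replacing geometric waits by exponentials of equal rate
  (`sample_chain(..., method = "exponential")`) turns $T/L$ with
  $L = N(N+1)$ into a sum of exponentials with rates $1, \dots, N$,
  whose density has both a partial-fraction product form
  (`dsumexp_product()`) and the stable closed form
  $g_N(x) = N e^{-x}(1 - e^{-x})^{N-1}$ (`dsumexp_closed()`). Centered
  by $H_N$ and taken to large $N$ this is the Gumbel density
  $e^{-(x+\gamma)}\exp(-e^{-(x+\gamma)})$, i.e.
  $(T - \mu)/L \to \mathrm{Gumbel}(-\gamma, 1)$.
* **Complete graph.** The palindrome splits $T$ into front and back
  halves that are asymptotically independent coupon-collector runs:
  $(T - \mu)/N \to G + G$, the convolution of two
  $\mathrm{Gumbel}(-\gamma, 1)$ variables. The convolution density has
  no elementary form; the package computes it once by grid convolution
  (step $\approx 10^{-3}$, support out to $10^{-12}$ tail mass, checked
  against adaptive quadrature to $10^{-6}$; the CDF uses trapezoidal
  accumulation and agrees with quadrature to $\sim 10^{-8}$). The
  sampler never uses the grid — it adds two component draws.
* **Lattices.** On a $d$-dimensional torus the growing cluster is a
  compact blob whose boundary scales as $m^\eta$ with
  $\eta = (d-1)/d$, so the opening behaves like exponentials with rates
  $m^\eta$. The standardized family
  $F' = \sum_{m \le M} (E(m^\eta) - m^{-\eta})/\sqrt H$,
  $H = \sum_{m \le M} m^{-2\eta}$, combined as $(F'_1 + F'_2)/\sqrt 2$,
  matches $(T - \mu)/\sigma$ with *empirical* $\mu, \sigma$ (unknown
  proportionality constants are absorbed by the empirical scale). The
  displayed normalizer is written as $H$ while $H$ is defined as the
  sum of variances; we divide by $\sqrt H$, the only choice that makes
  $F'$ unit-variance and comparable to an empirically standardized $T$.
  The critical dimension is 2: for $d \le 2$, $H$ diverges and the
  limit is normal; for $d \ge 3$, $H$ converges, the third moment
  survives, and the family interpolates up to the two-Gumbel
  convolution as $d \to \infty$. The truncation $M$ defaults to $N$;
  modest tuning sharpens finite-size fits but is never required by the
  tests.
* **Erdős–Rényi.** A dense connected $G(N, \rho)$ behaves as
  effectively infinite-dimensional: with one fixed realization and a
  fixed source, $(T - \mu)/\sigma \sim G' + G'$, where $G'$ is the
  Gumbel with mean 0 and variance 1/2. The printed parameter glyphs are
  ambiguous; the moment constraints are not, and force
  $\mathrm{Gumbel}(-\gamma\sqrt 3/\pi, \sqrt 3/\pi)$, which is what
  `gumbel_prime()` returns (and what the tests verify).
* **Partial takeover.** Truncating the chain at
  $\lfloor \theta N \rfloor$ removes the endgame's extreme-value phase;
  on dense graphs the limit reverts from the two-Gumbel convolution
  (skewness $\approx 0.81$) to a single Gumbel (skewness
  $\approx 1.14$). Because a tuned three-parameter lognormal imitates a
  Gumbel to high accuracy (`fit_lognormal3_gumbel()` reaches sup-norm
  $\approx 0.003$), these right-skewed laws offer a mechanistic reading
  of lognormal-looking incubation-period fits; the fitting helper is a
  demonstration, not a claim.

## Samplers and randomness

The event-level samplers are compiled. `method = "direct"` replays the
rule literally — two uniform draws per step — and is the ground truth.
`method = "accelerated"` is exact in distribution but event-driven:
with infected set $I$, the per-step success probability is
$p = \frac{1}{V}\sum_{j \notin I} w_j$ with
$w_j = \sum_{i \in I,\, i \sim j} 1/\deg i$; the wait to the next
infection is drawn as a geometric variable by inverse CDF
($\lceil \log u / \log(1 - p) \rceil$, so wasted steps are counted
exactly), and the infectee is chosen with probability $\propto w_j$.
Boundary weights update in $O(\deg)$ per infection and the total weight
is re-accumulated at each event to avoid floating-point drift, for
$O(\sum_j \deg j)$ total cost per run instead of the $O(N^2)$ steps the
direct walk needs on a ring. Distributional equality of the two routes,
and of both against the geometric chain on stage-tractable topologies,
is asserted by two-sample Kolmogorov–Smirnov tests; that cross-check is
the package's central correctness argument, because it ties the
analytic rates to the event-level rule they summarize.

All randomness flows through R's RNG (`set.seed()` or the `seed`
arguments, which restore the caller's state). Erdős–Rényi construction
takes its own `graph_seed` and draws by rejection: sample
$G(N, \rho)$, keep the first connected realization — the literal form
of conditioning on connectivity. The same `(N, \rho, graph_seed)`
always returns the same edge set, so an experiment can hold the graph
fixed while varying the dynamics stream.

## Goodness of fit

`gof_report()` normalizes samples either by analytic center and scale
("analytic" mode, for topologies with closed forms) or by sample mean and
standard deviation ("empirical" mode, for lattices and random graphs),
then records moments, adjusted Fisher–Pearson skewness and the KS
distance. Discreteness of $T$ is ignored after normalization: at the
scales of interest the step size is $10^{-3}$ standard deviations or
smaller, far below every tolerance used. KS thresholds are stated per
test rather than converted to p-values, because convergence is
asymptotic in $N$ — finite systems are asserted *close*, not equal.

## Problem sizes and what the tests show

The test suite reproduces each distributional claim at desk scale:
rings at $N = 750$, stars at $N = 120$ and complete graphs at
$N = 450$ via the exact chain ($10^5$ draws), a $30 \times 30$ torus
and a $9^3$ torus via the accelerated sampler ($2 \times 10^4$ runs
against $10^6$ family draws), and one fixed connected $G(200, 0.5)$
($2 \times 10^4$ direct runs). These sizes keep the whole suite in the
minutes range while leaving every KS comparison with comfortable
statistical resolution; they are the package's own choices of
demonstration scale.

One honest finite-size caveat is visible in the numbers: the *exact*
skewness of the ring takeover time is
$2N^{3/2}/(N-1)^2 \approx 0.073$ at $N = 750$ — small, but not yet
within the 0.05 band one might hope for; normality is approached
slowly, from the right. The KS distance to the normal at the same size
is below 0.01, so the distribution is already normal for any practical
purpose even while its third moment lags.

Because every input is generated by the package itself, passing tests
demonstrate internal consistency of model, reductions and limits — not
fidelity to any empirical epidemic. The model's idealizations (perfect
transmission, no recovery, asynchronous single contacts, homogeneous
topologies) are exactly the features real incubation or fixation data
would violate first.

## Known limitations

* Directed, weighted or time-varying graphs are out of scope, as are
  SIS/SIR variants and synchronous updating.
* The product-form hypoexponential density is guarded to 25 distinct
  rates; beyond that the alternating products lose precision, and the
  closed form (or simulation) should be used.
* The `f_prime` family is simulation-defined: it exposes a sampler but
  no analytic CDF, so comparisons against it are two-sample.
* Very sparse Erdős–Rényi parameters can exhaust the rejection cap for
  connected realizations; the constructor fails loudly rather than
  silently biasing the ensemble.
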