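# takeover

Distributions of network takeover times for the simplest contact
infection process.

## The problem

Take an undirected connected graph of $V$ nodes, one of which is
infected. At every discrete time step a node is chosen uniformly at
random, then one of its neighbors uniformly at random; if the first is
infected and the second susceptible, the infection spreads — otherwise
the step is wasted, but it still counts. How many steps $T$ until the
whole network (or a fraction $\theta$ of it) is infected?

This minimal model — equivalently, a Moran birth–death process in the
infinite-fitness limit, or first-passage percolation with geometric
edge weights — turns out to have sharply topology-dependent answers.
On topologies where the success probability $p_m$ depends only on the
infected count $m$, the takeover time is an exact sum of geometric
waits, $T = \sum_m X(p_m)$, and a coupon-collector analysis gives the
large-$N$ limits:

| topology | stage rates $p_m$ | limit of normalized $T$ |
|---|---|---|
| ring | $1/N$ | Normal(0, 1) |
| star ($N$ spokes) | $\frac{1}{N+1}\frac{N-m}{N}$ | Gumbel$(-\gamma, 1)$ |
| complete | $\frac{m}{N}\frac{N-m}{N-1}$ | $G + G$ (two-Gumbel convolution) |
| torus, $d = 2$ | — (shape-dependent) | Normal(0, 1) |
| torus, $d \ge 3$ | — | $(F'_1 + F'_2)/\sqrt 2$, skewed intermediate family |
| dense Erdős–Rényi | — | $G' + G'$, $G' \sim$ Gumbel with mean 0, variance 1/2 |

with $\gamma \approx 0.5772$ the Euler–Mascheroni constant and
$F' = \sum_{m=1}^{M}(E(m^\eta) - m^{-\eta})/\sqrt{H}$,
$\eta = (d-1)/d$. Partial takeover ($\theta < 1$) removes the endgame
and restores a single Gumbel on dense graphs — right-skewed laws that
closely imitate the three-parameter lognormals traditionally fit to
disease incubation periods.

The package is for anyone who wants to simulate this process exactly
(event-level or accelerated samplers, compiled), work with the
geometric-chain reductions and their closed-form moments, evaluate the
limit densities (including the numerically convolved two-Gumbel law and
the stable hypoexponential closed form), and quantify agreement with
moments, skewness and Kolmogorov–Smirnov distances.

## Worked example

Star graph with 120 spokes, infection started at the hub:

```r
library(takeover)
set.seed(1)

g <- graph_star(120)
g
#> <takeover_graph: star, 121 nodes, 120 edges>

s <- simulate_takeover(g, runs = 20000)   # accelerated, exact in distribution
mean(s$time)
#> [1] 77977.2

mu <- chain_moments(star_rates(120))$mean # exact mean N(N+1) * H_N
mu
#> [1] 77955.97

gof <- gof_report(s, limit_model("std_gumbel"), mode = "analytic",
                  mu = mu, scale = 120 * 121)
glance(gof)
#> # A tibble: 1 × 7
#>   sample_size    mean variance skewness ks_statistic target     normalization
#>         <int>   <dbl>    <dbl>    <dbl>        <dbl> <chr>      <chr>
#> 1       20000 0.00146     1.65     1.13      0.00279 std_gumbel analytic_scale
```

The simulated mean matches the closed form to 0.03%; after centering by
$\mu$ and scaling by $L = N(N+1)$ the sample skewness (1.13) sits at
the Gumbel value $12\sqrt6\,\zeta(3)/\pi^3 \approx 1.14$, and the KS
distance to Gumbel$(-\gamma, 1)$ is 0.003. `autoplot(gof)` draws the
histogram with the limit density overlaid; `autoplot(s)` shows the raw
times.

A thin command-line front end over the same functions lives at
`inst/scripts/takeover-cli.R` (subcommands `simulate`, `compare`,
`rates`, `snapshot`).

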