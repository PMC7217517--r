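#' Per-stage infection rates for tractable topologies
#'
#' On the ring, star and complete graph the probability that the next time
#' step infects a new node depends only on how many nodes are currently
#' infected, so the whole takeover time reduces to a sum of independent
#' geometric waits, one per stage. These constructors return that rate
#' vector as a tibble with one row per stage:
#'
#' * `ring_rates(n)`: all stages have \eqn{p_m = 1/N} (the infected arc has
#'   two boundary nodes, each with one susceptible neighbor out of two).
#' * `star_rates(n_spokes)`: with `m` infected spokes and the infection
#'   started at the hub, \eqn{p_m = \frac{1}{N+1}\,\frac{N-m}{N}} for
#'   \eqn{m = 0, \dots, N-1} — the coupon collector's factor
#'   \eqn{(N-m)/N} times the chance of drawing the hub.
#' * `complete_rates(n)`: \eqn{p_m = \frac{m}{N}\,\frac{N-m}{N-1}} for
#'   \eqn{m = 1, \dots, N-1}, a palindrome in `m` — the endgame mirrors
#'   the opening, which is why the limit is a sum of two Gumbels.
#'
#' @param n,n_spokes Topology size (for the star, the number of spokes;
#'   the graph then has `n_spokes + 1` nodes).
#' @param p Numeric vector of per-stage success probabilities in (0, 1]
#'   (for `custom_rates`).
#'
#' @return A `rate_vector`: a tibble with columns `stage` (the number of
#'   infected nodes the stage's convention counts), `p` (per-step success
#'   probability) and `infected_after` (total infected nodes once the
#'   stage completes), plus attributes `n_nodes` and `topology`.
#' @name rates
#' @examples
#' ring_rates(5)
#' chain_moments(ring_rates(750))   # mean N(N-1) = 561750
NULL

new_rate_vector <- function(stage, p, infected_after, n_nodes, topology) {
  if (any(p <= 0 | p > 1)) abort("rates must lie in (0, 1]")
  out <- tibble(stage = as.integer(stage), p = as.numeric(p),
                infected_after = as.integer(infected_after))
  structure(out,
            n_nodes = as.integer(n_nodes),
            topology = topology,
            class = c("rate_vector", class(out)))
}

#' @rdname rates
#' @export
ring_rates <- function(n) {
  n <- check_count(n, min = 3L, "n")
  m <- 1:(n - 1L)
  new_rate_vector(m, rep(1 / n, n - 1L), m + 1L, n, "ring")
}

#' @rdname rates
#' @export
star_rates <- function(n_spokes) {
  N <- check_count(n_spokes, min = 1L, "n_spokes")
  m <- 0:(N - 1L)
  p <- (1 / (N + 1)) * ((N - m) / N)
  # hub is infected from the start: m infected spokes = m + 1 nodes
  new_rate_vector(m, p, m + 2L, N + 1L, "star")
}

#' @rdname rates
#' @export
complete_rates <- function(n) {
  n <- check_count(n, min = 2L, "n")
  m <- 1:(n - 1L)
  p <- (m / n) * ((n - m) / (n - 1))
  new_rate_vector(m, p, m + 1L, n, "complete")
}

#' @rdname rates
#' @export
custom_rates <- function(p) {
  s <- seq_along(p)
  new_rate_vector(s, p, s + 1L, length(p) + 1L, "custom")
}

#' Restrict a rate vector to a partial-takeover threshold
#'
#' Keeps only the stages needed until `floor(theta * n_nodes)` nodes are
#' infected, so that summing the retained waits gives the partial takeover
#' time \eqn{T_\theta}. With `theta = 1` the input is returned unchanged.
#' Truncating the endgame removes one of the two extreme-value phases: on
#' the complete graph the limit law moves from the two-Gumbel convolution
#' back to a single Gumbel.
#'
#' @param rates A `rate_vector`.
#' @param theta Takeover fraction in (0, 1].
#' @return A `rate_vector` with the trailing stages dropped.
#' @export
#' @examples
#' nrow(partial_rates(complete_rates(450), 0.9))   # 404 stages
partial_rates <- function(rates, theta) {
  check_theta(theta)
  V <- attr(rates, "n_nodes")
  target <- floor(theta * V)
  keep <- rates$infected_after <= target
  new_rate_vector(rates$stage[keep], rates$p[keep],
                  rates$infected_after[keep], V, attr(rates, "topology"))
}

#' Exact moments of the geometric-chain takeover time
#'
#' The wait at a stage with success probability \eqn{p} is geometric with
#' mean \eqn{1/p} and variance \eqn{1/p^2 - 1/p}; stages are independent,
#' so the moments add. For the ring this gives mean \eqn{N(N-1)} and
#' variance \eqn{N(N-1)^2}; for the star, mean \eqn{N(N+1) H_N} with
#' \eqn{H_N} the harmonic number.
#'
#' @param rates A `rate_vector`.
#' @return A one-row tibble with columns `mean`, `variance`, `sd` and
#'   `skewness` (from the third cumulant \eqn{q(1+q)/p^3} of each wait).
#' @export
#' @examples
#' chain_moments(star_rates(120))
chain_moments <- function(rates) {
  p <- rates$p
  q <- 1 - p
  k2 <- sum(q / p^2)
  k3 <- sum(q * (1 + q) / p^3)
  tibble(mean = sum(1 / p), variance = k2, sd = sqrt(k2),
         skewness = if (k2 > 0) k3 / k2^1.5 else NaN)
}

#' Rate vectors from graph topologies
#'
#' Maps a `takeover_graph` with a stage-tractable topology onto its rate
#' vector; errors for topologies where the per-stage probability is not a
#' function of the infected count alone (lattices with `d >= 2`,
#' Erdos-Renyi, custom graphs).
#'
#' @param graph A `takeover_graph`.
#' @return A `rate_vector`.
#' @export
graph_rates <- function(graph) {
  switch(graph$topology,
    ring = ring_rates(graph$n_nodes),
    star = star_rates(graph$n_nodes - 1L),
    complete = complete_rates(graph$n_nodes),
    abort(sprintf(
      "per-stage rates are not well defined on topology '%s': the success probability depends on the cluster's shape, not just its size",
      graph$topology))
  )
}

#' Read / write rate vectors as two-column CSV
#'
#' @param rates A `rate_vector`.
#' @param path File path; columns `stage` and `p`.
#' @return `read_rates()` returns a `rate_vector` (topology `custom`);
#'   `write_rates()` returns `path` invisibly.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(tibble(stage = rates$stage, p = rates$p), path)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  s <- as.integer(tab$stage)
  new_rate_vector(s, tab$p, s + 1L, length(s) + 1L, "custom")
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta > 1)
    abort("`theta` must lie in (0, 1]")
  invisible(theta)
}
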