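#' Simulate takeover times of the contact process
#'
#' Runs the discrete-time update rule on a graph: at each step a node is
#' drawn uniformly at random, then one of its neighbors uniformly at
#' random; the infection spreads only if the first is infected and the
#' second susceptible, and every step — wasted or not — advances the
#' clock. The recorded time is the first step at which at least
#' `floor(theta * n_nodes)` nodes are infected (`theta = 1`: complete
#' takeover). If that threshold is already met by the initially infected
#' source, the time is 0.
#'
#' Methods:
#' * `"direct"` replays the update rule literally, one step at a time.
#' * `"accelerated"` (default) is exact in distribution but event-driven:
#'   given the current infected set the per-step success probability is
#'   \eqn{p = \frac{1}{V}\sum_{(i,j)} \frac{1}{\deg i}} over
#'   infected-to-susceptible adjacent pairs, the wait to the next
#'   infection is drawn geometrically (wasted steps included), and the
#'   infectee is chosen with probability proportional to its boundary
#'   weight. Cost is O(events), not O(steps), which matters because mean
#'   takeover times grow like \eqn{N^2} on rings.
#' * `"geometric_chain"` / `"exponential_approx"` dispatch to
#'   [sample_chain()] and are only available on topologies whose
#'   per-stage rates are well defined (ring, star, complete).
#'
#' @param graph A `takeover_graph`.
#' @param runs Number of independent takeover times to draw.
#' @param theta Takeover fraction in (0, 1]; the threshold is
#'   `floor(theta * n_nodes)` and the count includes the source.
#' @param source 0-based id of the initially infected node. Defaults to
#'   the topology's conventional source (hub for the star, node 0
#'   otherwise; the choice is immaterial on vertex-transitive graphs, but
#'   for a fixed Erdos-Renyi realization keep it fixed across runs).
#' @param method Sampling method, see Details.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A `takeover_samples` tibble with columns `run` and `time` plus
#'   provenance attributes (`topology`, `params`, `theta`, `source`,
#'   `method`, `seed`).
#' @export
#' @examples
#' set.seed(42)
#' g <- graph_star(30)
#' s <- simulate_takeover(g, runs = 500)
#' mean(s$time)   # near 31 * 30 * sum(1 / (1:30))
simulate_takeover <- function(graph, runs, theta = 1, source = NULL,
                              method = c("accelerated", "direct",
                                         "geometric_chain",
                                         "exponential_approx"),
                              seed = NULL) {
  method <- match.arg(method)
  runs <- check_count(runs, min = 0L, "runs")
  check_theta(theta)
  source <- if (is.null(source)) graph$default_source else check_node(graph, source)

  if (method %in% c("geometric_chain", "exponential_approx")) {
    rates <- partial_rates(graph_rates(graph), theta)
    out <- sample_chain(rates, runs,
                        method = if (method == "geometric_chain") "geometric"
                                 else "exponential",
                        seed = seed)
    attr(out, "params") <- graph$params
    attr(out, "source") <- source
    return(out)
  }

  target <- floor(theta * graph$n_nodes)
  csr <- graph_csr(graph)
  runner <- if (method == "direct") cpp_run_direct else cpp_run_accel
  values <- with_seed_local(seed, {
    vapply(seq_len(max(runs, 0L)), function(r) {
      if (target <= 1L) return(0)
      runner(csr$offsets, csr$nbrs, source, target, FALSE)$steps
    }, numeric(1))
  })
  new_takeover_samples(values, topology = graph$topology,
                       params = graph$params, theta = theta,
                       method = method, seed = seed, source = source)
}

#' Run a single takeover and return the time or final state
#'
#' `run_takeover()` returns one draw of the (partial) takeover time.
#' `takeover_state()` stops once `floor(theta * n_nodes)` nodes are
#' infected and returns the infected membership, for inspecting the
#' growing cluster (see [snapshot_grid()]).
#'
#' @inheritParams simulate_takeover
#' @return `run_takeover()`: a single nonnegative number of steps.
#'   `takeover_state()`: a list with `steps` and `infected` (logical
#'   vector indexed by `id + 1`).
#' @export
run_takeover <- function(graph, source = NULL, theta = 1,
                         method = c("direct", "accelerated"), seed = NULL) {
  method <- match.arg(method)
  s <- simulate_takeover(graph, 1L, theta = theta, source = source,
                         method = method, seed = seed)
  s$time[[1L]]
}

#' @rdname run_takeover
#' @export
takeover_state <- function(graph, source = NULL, theta = 1,
                           method = c("accelerated", "direct"),
                           seed = NULL) {
  method <- match.arg(method)
  check_theta(theta)
  source <- if (is.null(source)) graph$default_source else check_node(graph, source)
  target <- floor(theta * graph$n_nodes)
  if (target <= 1L) {
    infected <- logical(graph$n_nodes)
    infected[source + 1L] <- TRUE
    return(list(steps = 0, infected = infected))
  }
  csr <- graph_csr(graph)
  runner <- if (method == "direct") cpp_run_direct else cpp_run_accel
  res <- with_seed_local(seed, runner(csr$offsets, csr$nbrs, source, target, TRUE))
  list(steps = res$steps, infected = as.logical(res$infected))
}

#' One explicit step of the update rule
#'
#' A literal, R-level implementation of the per-step dynamics, mainly for
#' small demonstrations and tests: the compiled samplers behind
#' [simulate_takeover()] are the workhorses.
#'
#' @param graph A `takeover_graph`.
#' @param state A list with `infected` (logical by `id + 1`),
#'   `step_count`, `source`; create one with `infection_init()`.
#' @return An updated state; `step_count` always increments, the infected
#'   set grows by at most one node.
#' @export
#' @examples
#' g <- graph_ring(5)
#' st <- infection_init(g, 0)
#' st <- infection_step(g, st)
#' st$step_count
infection_init <- function(graph, source = NULL) {
  source <- if (is.null(source)) graph$default_source else check_node(graph, source)
  infected <- logical(graph$n_nodes)
  infected[source + 1L] <- TRUE
  list(infected = infected, step_count = 0L, source = source)
}

#' @rdname infection_init
#' @export
infection_step <- function(graph, state) {
  i <- sample.int(graph$n_nodes, 1L) - 1L
  nb <- graph$adj[[i + 1L]]
  j <- nb[[sample.int(length(nb), 1L)]]
  state$step_count <- state$step_count + 1L
  if (state$infected[i + 1L] && !state$infected[j + 1L])
    state$infected[j + 1L] <- TRUE
  state
}

#' Lattice snapshot as a d-dimensional binary array
#'
#' Reshapes an infected-membership vector on a periodic lattice into an
#' `n x ... x n` array (1 = infected), using the little-endian coordinate
#' encoding of [graph_lattice()]; axis k of the array is coordinate k.
#'
#' @param infected Logical or 0/1 vector indexed by `id + 1`, e.g. from
#'   [takeover_state()].
#' @param graph The lattice (`graph_lattice()`) the state lives on.
#' @return An integer array of dim `rep(n, d)`.
#' @export
snapshot_grid <- function(infected, graph) {
  if (!graph$topology %in% c("lattice", "ring"))
    abort("`snapshot_grid()` requires a lattice graph")
  n <- graph$params$n %||% graph$params$N
  d <- graph$params$d %||% 1L
  if (length(infected) != n^d) abort("state length does not match the lattice")
  array(as.integer(infected), dim = rep(n, d))
}

new_takeover_samples <- function(values, topology, params, theta, method,
                                 seed = NULL, source = NULL) {
  out <- tibble(run = seq_along(values), time = as.numeric(values))
  structure(out,
            topology = topology, params = params, theta = theta,
            method = method, seed = seed, source = source,
            class = c("takeover_samples", class(out)))
}

#' @export
print.takeover_samples <- function(x, ...) {
  cat(sprintf("<takeover_samples: %d draws, topology %s, theta %g, method %s>\n",
              nrow(x), attr(x, "topology") %||% "?",
              attr(x, "theta") %||% 1, attr(x, "method") %||% "?"))
  NextMethod()
}
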