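# Shared fixtures and independent oracles for the test suite.

# Exact one-step success probability by enumerating every equally likely
# (node, neighbor) pick: P = sum over infected i, susceptible j ~ i of
# (1/V) * (1/deg(i)). Independent of the samplers under test.
step_success_prob <- function(graph, infected_ids) {
  V <- graph$n_nodes
  inf <- logical(V)
  inf[infected_ids + 1L] <- TRUE
  total <- 0
  for (i in which(inf) - 1L) {
    nb <- graph$adj[[i + 1L]]
    total <- total + sum(!inf[nb + 1L]) / (V * length(nb))
  }
  total
}

# Exact cumulants of a sum of independent geometric waits on {1,2,...}
# (kappa1 = 1/p, kappa2 = q/p^2, kappa3 = q(1+q)/p^3), summed across
# stages; used as the moment/skewness oracle for chain samplers.
geom_sum_cumulants <- function(p) {
  q <- 1 - p
  c(k1 = sum(1 / p), k2 = sum(q / p^2), k3 = sum(q * (1 + q) / p^3))
}

geom_sum_skewness <- function(p) {
  k <- geom_sum_cumulants(p)
  unname(k["k3"] / k["k2"]^1.5)
}

# connectivity of the infected set as an induced subgraph, by traversal
infected_set_connected <- function(graph, infected) {
  ids <- which(infected) - 1L
  if (length(ids) <= 1L) return(TRUE)
  seen <- c(ids[[1L]])
  queue <- c(ids[[1L]])
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    nb <- intersect(graph$adj[[i + 1L]], ids)
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == length(ids)
}

expect_valid_graph <- function(graph) {
  V <- graph$n_nodes
  for (i in seq_len(V)) {
    nb <- graph$adj[[i]]
    expect_false(any(nb == i - 1L))          # no self-loops
    expect_equal(anyDuplicated(nb), 0L)      # no duplicate neighbors
    for (j in nb) expect_true((i - 1L) %in% graph$adj[[j + 1L]])  # symmetry
  }
  # connectivity, checked with igraph as an independent traversal
  ig <- igraph::graph_from_edgelist(as.matrix(tibble::as_tibble(graph)) + 1L,
                                    directed = FALSE)
  expect_true(igraph::is_connected(ig))
}

harmonic <- function(n) sum(1 / seq_len(n))
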