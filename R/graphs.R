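#' Network constructors for the contact process
#'
#' Build the undirected, connected topologies the takeover-time analysis
#' covers: the ring (1D periodic lattice), the star, the complete graph,
#' the d-dimensional periodic (torus) lattice, a connected Erdos-Renyi
#' realization, and arbitrary graphs from an edge list. Node ids are
#' 0-based integers; lattice ids encode coordinates in little-endian mixed
#' radix so that `graph_lattice(n, 1)` carries exactly the labels of
#' `graph_ring(n)`. The star's hub is node 0.
#'
#' Every constructor enforces the structural invariants the dynamics rely
#' on: symmetry of adjacency, no self-loops or duplicate edges, and
#' connectivity (so complete takeover is certain).
#'
#' @param n Number of nodes (ring, complete, Erdos-Renyi) or side length
#'   (lattice).
#' @param n_spokes Number of spoke nodes of the star; the graph has
#'   `n_spokes + 1` nodes in total.
#' @param d Lattice dimension (`d >= 1`).
#' @param rho Edge probability of the Erdos-Renyi model, in (0, 1].
#' @param graph_seed Integer seed fixing the Erdos-Renyi realization;
#'   the same `(n, rho, graph_seed)` always yields the same edge set.
#'   `NULL` draws from the current RNG stream.
#' @param max_tries Cap on rejection-sampling attempts before giving up on
#'   drawing a connected realization (only binding for very sparse graphs).
#' @param edges Two-column matrix or data frame of undirected edges
#'   (0-based node ids). Duplicate edges are collapsed; self-loops are an
#'   error.
#'
#' @return A `takeover_graph`: a list with elements `n_nodes`, `adj`
#'   (per-node integer vectors of 0-based neighbor ids), `topology`,
#'   `params`, and `default_source` (the conventional infection source:
#'   the hub for a star, node 0 otherwise).
#' @name graphs
#' @examples
#' g <- graph_ring(8)
#' neighbors_of(g, 0)      # 1 and 7: periodic wraparound
#' graph_star(3)           # hub 0 with three spokes
NULL

new_takeover_graph <- function(adj, topology, params, default_source = 0L) {
  adj <- lapply(adj, function(v) as.integer(sort(v)))
  g <- structure(
    list(
      n_nodes = length(adj),
      adj = adj,
      topology = topology,
      params = params,
      default_source = as.integer(default_source)
    ),
    class = "takeover_graph"
  )
  validate_takeover_graph(g)
  g
}

validate_takeover_graph <- function(g) {
  V <- g$n_nodes
  for (i in seq_len(V)) {
    nb <- g$adj[[i]]
    if (anyDuplicated(nb)) abort("duplicate neighbors detected")
    if (any(nb == i - 1L)) abort("self-loop detected")
    if (length(nb) == 0L && V > 1L) abort("graph is not connected (isolated node)")
    if (any(nb < 0L | nb >= V)) abort("neighbor id out of range")
  }
  # symmetry
  for (i in seq_len(V)) {
    for (j in g$adj[[i]]) {
      if (!((i - 1L) %in% g$adj[[j + 1L]])) abort("adjacency is not symmetric")
    }
  }
  if (!is_connected_adj(g$adj)) abort("graph is not connected")
  invisible(g)
}

# breadth-first traversal over the adjacency list
is_connected_adj <- function(adj) {
  V <- length(adj)
  if (V == 0L) return(FALSE)
  seen <- logical(V)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    nxt <- adj[[i]] + 1L
    new <- nxt[!seen[nxt]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' @rdname graphs
#' @export
graph_ring <- function(n) {
  n <- check_count(n, min = 3L, "n")
  ids <- 0:(n - 1L)
  adj <- lapply(ids, function(i) c((i - 1L) %% n, (i + 1L) %% n))
  new_takeover_graph(adj, "ring", list(N = n))
}

#' @rdname graphs
#' @export
graph_star <- function(n_spokes) {
  N <- check_count(n_spokes, min = 1L, "n_spokes")
  adj <- c(list(1:N), as.list(rep(0L, N)))
  new_takeover_graph(adj, "star", list(N = N), default_source = 0L)
}

#' @rdname graphs
#' @export
graph_complete <- function(n) {
  n <- check_count(n, min = 2L, "n")
  ids <- 0:(n - 1L)
  adj <- lapply(ids, function(i) setdiff(ids, i))
  new_takeover_graph(adj, "complete", list(N = n))
}

#' @rdname graphs
#' @export
graph_lattice <- function(n, d) {
  n <- check_count(n, min = 3L, "n")
  d <- check_count(d, min = 1L, "d")
  V <- n^d
  if (V > 5e6) abort("lattice too large")
  # id = sum_k coord_k * n^k (little-endian); column-major array order
  strides <- n^(0:(d - 1L))
  adj <- vector("list", V)
  for (id in 0:(V - 1L)) {
    coords <- (id %/% strides) %% n
    nb <- integer(2L * d)
    for (k in seq_len(d)) {
      up <- coords; up[k] <- (coords[k] + 1L) %% n
      dn <- coords; dn[k] <- (coords[k] - 1L) %% n
      nb[2L * k - 1L] <- sum(up * strides)
      nb[2L * k] <- sum(dn * strides)
    }
    adj[[id + 1L]] <- nb
  }
  new_takeover_graph(adj, if (d == 1L) "ring" else "lattice",
                     list(n = n, d = d, N = V))
}

#' @rdname graphs
#' @export
graph_er <- function(n, rho, graph_seed = NULL, max_tries = 1000L) {
  n <- check_count(n, min = 2L, "n")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    abort("`rho` must be a probability in (0, 1]")
  draw <- function() {
    for (t in seq_len(max_tries)) {
      ig <- igraph::sample_gnp(n, rho)
      if (igraph::is_connected(ig)) return(ig)
    }
    abort(sprintf("no connected G(%d, %g) realization in %d tries", n, rho, max_tries))
  }
  ig <- with_seed_local(graph_seed, draw())
  adj <- lapply(igraph::as_adj_list(ig), function(v) as.integer(v) - 1L)
  new_takeover_graph(adj, "erdos_renyi",
                     list(N = n, rho = rho, graph_seed = graph_seed))
}

#' @rdname graphs
#' @export
graph_custom <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  if (any(edges < 0L)) abort("node ids must be nonnegative integers")
  if (any(edges[, 1L] == edges[, 2L])) abort("self-loops are not allowed")
  V <- max(edges) + 1L
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  adj <- vector("list", V)
  for (i in seq_len(V)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a + 1L]] <- c(adj[[a + 1L]], b)
    adj[[b + 1L]] <- c(adj[[b + 1L]], a)
  }
  new_takeover_graph(adj, "custom", list(N = V))
}

#' Read / write plain-text edge lists
#'
#' Two whitespace-separated integer columns, one undirected edge per line;
#' lines starting with `#` are comments. Node ids are 0-based.
#'
#' @param path File path.
#' @param graph A `takeover_graph`.
#' @return `read_edgelist()` returns a `takeover_graph`; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("from", "to"))
  graph_custom(tab)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(graph, path) {
  ed <- as_tibble(graph)
  writeLines(c("# undirected edge list (0-based node ids)",
               paste(ed$from, ed$to)), path)
  invisible(path)
}

#' @method as_tibble takeover_graph
#' @export
as_tibble.takeover_graph <- function(x, ...) {
  pairs <- do.call(rbind, lapply(seq_along(x$adj), function(i) {
    nb <- x$adj[[i]]
    nb <- nb[nb > i - 1L]
    if (length(nb)) cbind(i - 1L, nb) else NULL
  }))
  tibble(from = as.integer(pairs[, 1]), to = as.integer(pairs[, 2]))
}

#' Neighbors and degrees
#'
#' @param graph A `takeover_graph`.
#' @param node A 0-based node id.
#' @return `neighbors_of()`: sorted integer vector of neighbor ids;
#'   `graph_degrees()`: integer vector of degrees indexed by `id + 1`.
#' @export
neighbors_of <- function(graph, node) {
  check_node(graph, node)
  graph$adj[[node + 1L]]
}

#' @rdname neighbors_of
#' @export
graph_degrees <- function(graph) {
  vapply(graph$adj, length, integer(1))
}

#' @export
print.takeover_graph <- function(x, ...) {
  n_edges <- sum(graph_degrees(x)) / 2
  cat(sprintf("<takeover_graph: %s, %d nodes, %d edges>\n",
              x$topology, x$n_nodes, n_edges))
  invisible(x)
}

# CSR view consumed by the compiled samplers
graph_csr <- function(graph) {
  deg <- graph_degrees(graph)
  list(offsets = as.integer(c(0L, cumsum(deg))),
       nbrs = as.integer(unlist(graph$adj, use.names = FALSE)))
}

check_count <- function(x, min, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_node <- function(graph, node) {
  if (!is.numeric(node) || length(node) != 1L || is.na(node) ||
      node != round(node) || node < 0 || node >= graph$n_nodes)
    abort("`node` / `source` must be a valid 0-based node id")
  invisible(as.integer(node))
}
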