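test_that("one-step success probability matches pair enumeration", {
  # oracle: sum over infected->susceptible ordered pairs of 1/(V deg(i))
  cases <- list(
    list(g = graph_complete(2), infected = 0L, p = 1 / 2),
    list(g = graph_ring(6), infected = c(0L, 1L), p = 1 / 6),
    list(g = graph_star(4), infected = 0L, p = 1 / 5)
  )
  for (cs in cases) {
    expect_equal(step_success_prob(cs$g, cs$infected), cs$p)
  }
  # Monte Carlo on the literal R stepper agrees with the enumeration
  set.seed(11)
  g <- graph_lattice(3, 2)
  st0 <- infection_init(g, 0)
  st0 <- infection_step(g, st0)  # arbitrary evolved state
  infected_ids <- which(st0$infected) - 1L
  p_exact <- step_success_prob(g, infected_ids)
  trials <- 4000
  hits <- 0
  for (t in seq_len(trials)) {
    st <- infection_step(g, st0)
    hits <- hits + (sum(st$infected) > sum(st0$infected))
  }
  se <- sqrt(p_exact * (1 - p_exact) / trials)
  expect_lt(abs(hits / trials - p_exact), 4 * se)
})

test_that("steps on a fully infected graph are wasted but still counted", {
  g <- graph_ring(4)
  st <- infection_init(g, 0)
  st$infected[] <- TRUE
  st2 <- infection_step(g, st)
  expect_equal(st2$infected, st$infected)
  expect_equal(st2$step_count, st$step_count + 1L)
})

test_that("tiny-graph takeover means match geometric closed forms", {
  set.seed(5)
  # two nodes joined by an edge: T ~ Geometric(1/2), mean 2
  pair <- graph_star(1)
  t2 <- simulate_takeover(pair, 4000, method = "direct")$time
  expect_lt(abs(mean(t2) - 2), 4 * sd(t2) / sqrt(4000))
  # triangle: two geometric stages with p = 1/3, mean 6
  tri <- simulate_takeover(graph_ring(3), 4000, method = "direct")$time
  expect_lt(abs(mean(tri) - 6), 4 * sd(tri) / sqrt(4000))
})

test_that("threshold at or below one node is met by the source at time 0", {
  g <- graph_ring(10)
  s <- simulate_takeover(g, 5, theta = 0.1, method = "direct")
  expect_true(all(s$time == 0))
  expect_equal(run_takeover(g, theta = 0.05), 0)
})

test_that("every sampling method is deterministic given a seed", {
  g <- graph_ring(12)
  for (m in c("direct", "accelerated", "geometric_chain", "exponential_approx")) {
    a <- simulate_takeover(g, 50, method = m, seed = 17)
    b <- simulate_takeover(g, 50, method = m, seed = 17)
    expect_identical(a$time, b$time)
  }
})

test_that("partial takeover times are monotone in theta under a shared stream", {
  g <- graph_er(30, 0.3, graph_seed = 2)
  thetas <- c(0.3, 0.5, 0.8, 1)
  times <- vapply(thetas, function(th)
    run_takeover(g, theta = th, method = "direct", seed = 99), numeric(1))
  expect_true(all(diff(times) >= 0))
})

test_that("direct and accelerated samplers agree in distribution", {
  set.seed(31)
  g <- graph_lattice(4, 2)
  a <- simulate_takeover(g, 2000, method = "direct")$time
  b <- simulate_takeover(g, 2000, method = "accelerated")$time
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("accelerated means reproduce the ring and star closed forms", {
  set.seed(8)
  n_runs <- 10000
  ring <- simulate_takeover(graph_ring(30), n_runs)$time
  expect_lt(abs(mean(ring) - 30 * 29), 4 * sd(ring) / sqrt(n_runs))
  star <- simulate_takeover(graph_star(30), n_runs)$time
  mu <- 31 * 30 * harmonic(30)
  expect_lt(abs(mean(star) - mu), 4 * sd(star) / sqrt(n_runs))
})

test_that("every takeover time covers at least one step per infection", {
  set.seed(4)
  s <- simulate_takeover(graph_complete(15), 500)
  expect_true(all(s$time >= 14))
})

test_that("the infected set stays contiguous and snapshots reshape it", {
  set.seed(21)
  g <- graph_lattice(6, 2)
  # seed only
  st <- takeover_state(g, theta = 1 / 36)
  expect_equal(sum(st$infected), 1)
  expect_equal(sum(snapshot_grid(st$infected, g)), 1)
  # mid-run: a single connected blob under torus adjacency
  for (rep in 1:5) {
    st <- takeover_state(g, theta = 0.5)
    expect_equal(sum(st$infected), 18)
    expect_true(infected_set_connected(g, st$infected))
  }
  # fully infected
  st <- takeover_state(g, theta = 1)
  expect_true(all(snapshot_grid(st$infected, g) == 1))

  expect_error(snapshot_grid(st$infected, graph_complete(36)), "lattice")
})

test_that("chain methods refuse topologies without well-defined stage rates", {
  g <- graph_lattice(3, 3)
  expect_error(simulate_takeover(g, 10, method = "geometric_chain"),
               "not well defined")
})

test_that("sources are validated and the provenance is attached", {
  g <- graph_ring(8)
  expect_error(simulate_takeover(g, 2, source = 8), "node id")
  s <- simulate_takeover(g, 3, source = 5, method = "direct", seed = 1)
  expect_equal(attr(s, "source"), 5L)
  expect_equal(attr(s, "topology"), "ring")
  expect_equal(attr(s, "method"), "direct")
})
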