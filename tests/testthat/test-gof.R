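test_that("normalization conventions behave as documented", {
  set.seed(14)
  s <- sample_chain(ring_rates(40), 500)
  z <- normalize_takeover(s)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  zp <- normalize_takeover(s, mode = "analytic", mu = 40 * 39,
                           scale = 39 * sqrt(40))
  expect_equal(zp, (s$time - 40 * 39) / (39 * sqrt(40)))

  expect_error(normalize_takeover(rep(5, 10)), "zero sample")
  expect_error(normalize_takeover(s, mode = "analytic"), "needs")
  expect_error(normalize_takeover(s, mode = "analytic", mu = 0, scale = 0),
               "nonzero")
})

test_that("sample skewness is affine-equivariant and matches Gumbel theory", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)

  set.seed(6)
  x <- rgumbel(2000)
  expect_equal(sample_skewness(3 + 2 * x), sample_skewness(x))
  expect_equal(sample_skewness(-x), -sample_skewness(x))

  # skewness of a skewed law estimates noisily; 4e6 draws keep the
  # estimator's sd a few times below the asserted band
  g <- rgumbel(4e6)
  expect_lt(abs(sample_skewness(g) - gumbel_skewness()), 0.01)

  expect_error(sample_skewness(c(1, 2)), "three")
  expect_error(sample_skewness(rep(1, 5)), "degenerate")
})

test_that("KS distance detects fit and misfit at the expected scale", {
  set.seed(9)
  # drawn from the target itself: below the 99% Kolmogorov quantile
  z <- rnorm(1e5)
  expect_lt(ks_stat(z, limit_model("normal")), 0.006)

  # a fixed distributional gap stays visible
  expect_gt(ks_stat(z, limit_model("std_gumbel")), 0.05)

  # identical sample two-sample distance is zero
  x <- rgumbel(500)
  expect_equal(suppressWarnings(ks_stat(x, x)), 0)

  # invariant under a common affine rescaling (two-sample route)
  y <- rnorm(2000)
  ref <- rnorm(2000, 0.2, 1.1)
  expect_equal(ks_stat(2 + 3 * y, 2 + 3 * ref), ks_stat(y, ref))

  expect_error(ks_stat(numeric(0), limit_model("normal")), "empty")
})

test_that("gof reports collect moments, skewness and KS with tidiers", {
  set.seed(10)
  s <- sample_chain(star_rates(60), 5000)
  mu <- chain_moments(star_rates(60))$mean
  g <- gof_report(s, limit_model("std_gumbel"), mode = "analytic",
                  mu = mu, scale = 60 * 61)
  expect_s3_class(g, "takeover_gof")
  expect_true(g$ks_statistic >= 0 && g$ks_statistic <= 1)
  expect_gt(g$skewness, 0.5)   # star times are strongly right-skewed

  gl <- glance(g)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("sample_size", "mean", "variance", "skewness",
                     "ks_statistic", "target", "normalization"))
  expect_equal(gl$normalization, "analytic_scale")

  td <- tidy(g)
  expect_equal(td$value[td$statistic == "ks_statistic"], g$ks_statistic)

  path <- withr::local_tempfile(fileext = ".json")
  write_gof_json(g, path)
  blob <- jsonlite::fromJSON(path)
  expect_equal(blob$ks_statistic, g$ks_statistic)
  expect_equal(blob$target, "std_gumbel")
})

test_that("plots are buildable ggplot objects", {
  set.seed(13)
  s <- sample_chain(ring_rates(20), 300)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")

  g <- gof_report(s, limit_model("normal"))
  expect_s3_class(ggplot2::autoplot(g), "ggplot")

  lat <- graph_lattice(5, 2)
  st <- takeover_state(lat, theta = 0.4, seed = 2)
  expect_s3_class(plot_snapshot(st$infected, lat), "ggplot")
})

test_that("sample sets round-trip through CSV plus provenance sidecar", {
  s <- simulate_takeover(graph_star(6), 40, theta = 0.8,
                         method = "direct", seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, path)
  s2 <- read_samples(path)
  expect_equal(s2$time, s$time)
  expect_equal(attr(s2, "topology"), "star")
  expect_equal(attr(s2, "theta"), 0.8)
  expect_equal(attr(s2, "method"), "direct")
  expect_equal(attr(s2, "seed"), 23)

  # zero runs still produce a readable header-only CSV
  empty <- simulate_takeover(graph_star(6), 0, method = "direct")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(empty, path2)
  expect_equal(readLines(path2)[1], "run_id,T")
  expect_equal(nrow(read_samples(path2)), 0)
})
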