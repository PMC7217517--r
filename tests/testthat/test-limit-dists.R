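test_that("Gumbel density, CDF and moments are mutually consistent", {
  expect_equal(dgumbel(0.3, loc = 0.3), exp(-1))
  expect_equal(pgumbel(qgumbel(0.37, 2, 1.5), 2, 1.5), 0.37)

  # mean alpha + gamma*beta: the standard takeover Gumbel is centered
  p <- std_takeover_gumbel()
  expect_equal(p$loc + euler_gamma * p$scale, 0)
  # G-prime has mean 0 and variance 1/2 by construction
  gp <- gumbel_prime()
  expect_equal(gp$loc + euler_gamma * gp$scale, 0)
  expect_equal(gp$scale^2 * pi^2 / 6, 1 / 2)

  # numerical derivative of the CDF recovers the density
  x <- seq(-2, 6, by = 0.05)
  h <- 1e-5
  num <- (pgumbel(x + h, -euler_gamma, 1) - pgumbel(x - h, -euler_gamma, 1)) / (2 * h)
  expect_lt(max(abs(num - dgumbel(x, -euler_gamma, 1))), 1e-4)

  set.seed(2)
  draws <- rgumbel(1e5, -euler_gamma, 1)
  expect_lt(abs(mean(draws)), 4 * sd(draws) / sqrt(1e5))
  expect_lt(abs(var(draws) - pi^2 / 6), 0.02)

  expect_error(dgumbel(0, scale = -1), "positive")
})

test_that("two-Gumbel convolution matches quadrature, moments and cumulants", {
  m <- limit_model("gumbel_conv2", loc = -euler_gamma, scale = 1)

  # density integrates to one
  g <- integrate(function(x) model_pdf(m, x), -8, 40, rel.tol = 1e-9)
  expect_lt(abs(g$value - 1), 1e-6)

  # grid density against direct adaptive quadrature of the convolution
  pdf_oracle <- function(q) integrate(function(x)
    dgumbel(x, -euler_gamma, 1) * dgumbel(q - x, -euler_gamma, 1),
    -10, 40, rel.tol = 1e-10)$value
  for (q in c(-2, -0.5, 0, 1.5, 4)) {
    expect_lt(abs(model_pdf(m, q) - pdf_oracle(q)), 1e-6)
  }

  # CDF from the grid against quadrature
  cdf_oracle <- function(q) integrate(function(x)
    dgumbel(x, -euler_gamma, 1) * pgumbel(q - x, -euler_gamma, 1),
    -10, 40, rel.tol = 1e-10)$value
  for (q in c(-1, 0, 2)) {
    expect_lt(abs(model_cdf(m, q) - cdf_oracle(q)), 1e-6)
  }

  # sampler: mean 0, variance pi^2/3, skewness of the half-scaled sum
  set.seed(3)
  s <- model_sample(m, 1e6)
  expect_lt(abs(mean(s)), 4 * sd(s) / sqrt(1e6))
  expect_lt(abs(var(s) - pi^2 / 3), 0.02)
  expect_lt(abs(sample_skewness(s) - gumbel_skewness(2)), 0.01)

  mm <- model_moments(m)
  expect_equal(mm$mean, 0)
  expect_equal(mm$variance, pi^2 / 3)
})

test_that("hypoexponential product and closed forms agree", {
  x <- c(0.5, 1, 2)
  expect_equal(dsumexp_product(x, 1), exp(-x))
  expect_equal(dsumexp_closed(x, 1), exp(-x))
  expect_equal(dsumexp_product(x, c(1, 2)), 2 * exp(-x) * (1 - exp(-x)))

  for (n in c(5, 10, 20)) {
    grid <- seq(0.05, 6, by = 0.05)
    expect_lt(max(abs(dsumexp_product(grid, 1:n) - dsumexp_closed(grid, n))),
              1e-8)
  }

  # it is a density even at coupon-collector scale
  total <- integrate(function(x) dsumexp_closed(x, 120), 0, Inf,
                     rel.tol = 1e-10)
  expect_lt(abs(total$value - 1), 1e-8)

  expect_error(dsumexp_product(1, c(1, 1, 2)), "distinct")
  expect_error(dsumexp_product(1, 1:30), "25")
  expect_error(dsumexp_product(-1, 1:3), "nonnegative")
  expect_error(dsumexp_closed(-1, 3), "nonnegative")
})

test_that("centered hypoexponential converges to the takeover Gumbel density", {
  n <- 1e4
  x <- seq(-2, 8, by = 0.01)
  centered <- dsumexp_closed(x + harmonic(n), n)
  expect_lt(max(abs(centered - dgumbel(x, -euler_gamma, 1))), 1e-3)
})

test_that("three-parameter lognormal density behaves at and below threshold", {
  expect_equal(dlnorm3(1, 0, 1, 0), 1 / sqrt(2 * pi))
  x <- c(2.2, 3.7)
  expect_equal(dlnorm3(x, 0.4, 0.8, 1.5), dlnorm3(x - 1.5, 0.4, 0.8, 0))
  expect_equal(dlnorm3(c(-1, 0.5), 0, 1, 0.5), c(0, 0))
  expect_error(dlnorm3(1, 0, -1), "positive")
})

test_that("a tuned lognormal3 impersonates the takeover Gumbel", {
  fit <- fit_lognormal3_gumbel()
  expect_lt(fit$sup_error, 0.01)
  expect_lt(fit$c, 0)  # support must start left of the Gumbel bulk
})

test_that("F-prime draws are standardized and interpolate normal to Gumbel", {
  expect_equal(surface_exponent(1), 0)
  expect_equal(surface_exponent(2), 1 / 2)
  expect_equal(lattice_h(3, 40), sum((1:40)^(-4 / 3)))

  set.seed(12)
  f <- sample_f_prime(3, 40, 1e5)
  expect_lt(abs(mean(f)), 4 / sqrt(1e5))
  expect_lt(abs(var(f) - 1), 4 * sqrt(2 / 1e5) * 2)

  z <- sample_lattice_limit(3, 40, 1e5)
  expect_lt(abs(var(z) - 1), 0.02)
  expect_gt(sample_skewness(z), 0)  # d > 2 keeps a third moment

  # eta -> 1 recovers the standardized coupon-collector Gumbel
  f_inf <- sample_f_prime(1000, 500, 1e5)
  ref <- rgumbel(1e5, -euler_gamma, 1) / sqrt(pi^2 / 6)
  expect_lt(unname(stats::ks.test(f_inf, ref)$statistic), 0.03)
})

test_that("limit models serialize to JSON and rebuild identically", {
  m <- limit_model("gumbel", loc = 2.5, scale = 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2$kind, m$kind)
  expect_equal(m2$params, m$params)
  expect_equal(model_pdf(m2, 1.3), model_pdf(m, 1.3))

  expect_error(limit_model("gumbel", scale = 0), "positive")
  expect_error(model_cdf(limit_model("f_prime", d = 3, M = 10), 0), "CDF")
})
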