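#' Normalize takeover samples
#'
#' Two normalization conventions are used when comparing takeover times
#' with their limit laws:
#'
#' * `"analytic"` — center by an analytic mean and divide by an analytic
#'   scale, e.g. \eqn{(T - N(N-1)) / ((N-1)\sqrt N)} on the ring or
#'   \eqn{(T - \mu) / (N(N+1))} on the star. Use when the topology's
#'   closed forms are available.
#' * `"empirical"` — standardize by the sample mean and standard
#'   deviation; the convention for lattices and Erdos-Renyi graphs, where
#'   the proportionality constants of the heuristic rates are unknown and
#'   get absorbed by the empirical scale.
#'
#' @param samples A `takeover_samples` tibble or a numeric vector.
#' @param mode `"empirical"` or `"analytic"`.
#' @param mu,scale Analytic center and scale, required for
#'   `mode = "analytic"`; `scale` must be nonzero.
#' @return A numeric vector of normalized values.
#' @export
#' @examples
#' set.seed(1)
#' z <- normalize_takeover(sample_chain(ring_rates(50), 2000))
#' round(c(mean(z), sd(z)), 10)   # exactly 0 and 1 by construction
normalize_takeover <- function(samples, mode = c("empirical", "analytic"),
                               mu = NULL, scale = NULL) {
  mode <- match.arg(mode)
  x <- sample_values(samples)
  if (length(x) < 2L) abort("need at least two samples to normalize")
  if (mode == "empirical") {
    s <- sd(x)
    if (!is.finite(s) || s == 0) abort("zero sample standard deviation")
    (x - mean(x)) / s
  } else {
    if (is.null(mu) || is.null(scale)) abort("analytic-scale normalization needs `mu` and `scale`")
    if (scale == 0) abort("`scale` must be nonzero")
    (x - mu) / scale
  }
}

#' Kolmogorov-Smirnov distance to a limit model
#'
#' The sup-norm distance between the empirical CDF of the normalized
#' samples and the target law — the quantitative surrogate for the
#' visual histogram-vs-curve comparisons the limits are usually judged
#' by. Targets with an analytic or grid CDF (Gumbel, normal, two-Gumbel
#' convolution, lognormal3) are compared one-sample; the
#' simulation-defined `f_prime` family (or an explicit numeric vector of
#' target draws) is compared two-sample against `target_draws` draws.
#'
#' @param z Numeric vector of (normalized) sample values.
#' @param target A [limit_model()] or a numeric vector of target draws.
#' @param target_draws Number of target draws for the two-sample route.
#' @return The KS statistic, a number in \[0, 1\].
#' @export
#' @examples
#' set.seed(1)
#' ks_stat(rnorm(2000), limit_model("normal"))
ks_stat <- function(z, target, target_draws = 1e6) {
  if (length(z) == 0L) abort("empty sample")
  if (is.numeric(target))
    return(unname(stats::ks.test(z, target)$statistic))
  stopifnot(inherits(target, "limit_model"))
  if (target$kind == "f_prime") {
    ref <- model_sample(target, target_draws)
    return(unname(stats::ks.test(z, ref)$statistic))
  }
  x <- sort(z)
  n <- length(x)
  Fx <- model_cdf(target, x)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' \deqn{g_1 = \frac{n}{(n-1)(n-2)} \sum_i
#'       \left(\frac{x_i - \bar x}{s}\right)^3,}
#' with `s` the sample standard deviation. Skewness separates the limit
#' laws cleanly: 0 for the normal (ring, 2D lattice), about 1.14 for the
#' Gumbel (star, partial takeover), about 0.81 for the two-Gumbel
#' convolution (complete graph, dense Erdos-Renyi), strictly between 0
#' and 1.14 for lattices with `d >= 3`.
#'
#' @param x Numeric vector with at least 3 values and positive spread.
#' @return A length-one numeric.
#' @export
#' @examples
#' sample_skewness(c(-1, 0, 1))   # 0
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) abort("need at least three values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("degenerate sample")
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Goodness-of-fit report against a limit model
#'
#' Normalizes the samples, then records sample size, moments, skewness
#' and the KS distance to the target. `glance()` returns the one-row
#' summary; `tidy()` returns one row per statistic; `autoplot()` overlays
#' the target density on the normalized histogram (density scale, with
#' `ceiling(2 * n^(1/3))` bins).
#'
#' @inheritParams normalize_takeover
#' @param target A [limit_model()] or numeric vector of target draws.
#' @param target_draws Draws for two-sample KS targets.
#' @return A `takeover_gof` object.
#' @export
#' @examples
#' set.seed(1)
#' s <- sample_chain(star_rates(60), 3000)
#' mu <- chain_moments(star_rates(60))$mean
#' g <- gof_report(s, limit_model("std_gumbel"), mode = "analytic",
#'                 mu = mu, scale = 60 * 61)
#' glance(g)
gof_report <- function(samples, target, mode = c("empirical", "analytic"),
                       mu = NULL, scale = NULL, target_draws = 1e6) {
  mode <- match.arg(mode)
  z <- normalize_takeover(samples, mode = mode, mu = mu, scale = scale)
  structure(
    list(
      z = z,
      target = target,
      normalization = if (mode == "analytic") "analytic_scale" else "empirical",
      sample_size = length(z),
      mean = mean(z),
      variance = var(z),
      skewness = sample_skewness(z),
      ks_statistic = ks_stat(z, target, target_draws = target_draws)
    ),
    class = "takeover_gof"
  )
}

#' @export
print.takeover_gof <- function(x, ...) {
  kind <- if (is.numeric(x$target)) "empirical target" else x$target$kind
  cat(sprintf(
    "<takeover_gof: n = %d vs %s (%s normalization)>\n  mean %.4f  var %.4f  skew %.4f  KS %.4f\n",
    x$sample_size, kind, x$normalization,
    x$mean, x$variance, x$skewness, x$ks_statistic))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method glance takeover_gof
#' @export
glance.takeover_gof <- function(x, ...) {
  tibble(
    sample_size = x$sample_size,
    mean = x$mean,
    variance = x$variance,
    skewness = x$skewness,
    ks_statistic = x$ks_statistic,
    target = if (is.numeric(x$target)) "empirical" else x$target$kind,
    normalization = x$normalization
  )
}

#' @method tidy takeover_gof
#' @export
tidy.takeover_gof <- function(x, ...) {
  tibble(
    statistic = c("mean", "variance", "skewness", "ks_statistic"),
    value = c(x$mean, x$variance, x$skewness, x$ks_statistic)
  )
}

#' Serialize a goodness-of-fit report as JSON
#'
#' Writes the summary statistics (not the raw normalized values) together
#' with the target description.
#'
#' @param gof A `takeover_gof`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gof_json <- function(gof, path) {
  blob <- as.list(glance(gof))
  if (!is.numeric(gof$target)) blob$target_params <- gof$target$params
  jsonlite::write_json(blob, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sample_values <- function(samples) {
  if (is.numeric(samples)) return(as.numeric(samples))
  if (is.data.frame(samples) && "time" %in% names(samples))
    return(as.numeric(samples$time))
  abort("`samples` must be numeric or a takeover_samples tibble")
}
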