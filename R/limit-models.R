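#' Named limiting distributions for takeover times
#'
#' A `limit_model` packages one of the analytical limit laws with its
#' parameters, exposing a density, a CDF and a sampler through
#' [model_pdf()], [model_cdf()] and [model_sample()]:
#'
#' * `"std_gumbel"` — Gumbel(\eqn{-\gamma}, 1), the star-graph /
#'   coupon-collector limit.
#' * `"gumbel"` — Gumbel(`loc`, `scale`).
#' * `"gumbel_conv2"` — the sum of two iid Gumbels (complete graph and
#'   dense Erdos-Renyi limits). Its density has no elementary closed form
#'   and is computed once by grid convolution of the component density
#'   (Riemann/FFT product on a grid wide enough that the truncated tail
#'   mass is below 1e-9; absolute density error well under 1e-6). The
#'   sampler never touches the grid: it adds two component draws.
#' * `"normal"` — Normal(`mean`, `sd`) (ring and 2D-lattice limit).
#' * `"f_prime"` — the d-dimensional lattice family
#'   \eqn{(F'_1 + F'_2)/\sqrt 2} with parameters `d` and `M`
#'   (see [sample_f_prime()]); simulation-defined, so it has a sampler
#'   but no analytic CDF — goodness-of-fit against it uses the
#'   two-sample route in [ks_stat()].
#' * `"lognormal3"` — the three-parameter lognormal with parameters
#'   `a`, `b`, `c` (see [dlnorm3()]), included because right-skewed
#'   incubation-period data are traditionally fit with it.
#'
#' @param kind One of the kinds above.
#' @param ... Parameters of the chosen kind (`loc`, `scale`; `mean`,
#'   `sd`; `d`, `M`; `a`, `b`, `c`).
#' @return A `limit_model` object.
#' @export
#' @examples
#' m <- limit_model("gumbel_conv2", loc = -euler_gamma, scale = 1)
#' model_cdf(m, 0)
#' model_sample(limit_model("std_gumbel"), 3)
limit_model <- function(kind = c("std_gumbel", "gumbel", "gumbel_conv2",
                                 "normal", "f_prime", "lognormal3"),
                        ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    std_gumbel = std_takeover_gumbel(),
    gumbel = list(loc = 0, scale = 1),
    gumbel_conv2 = std_takeover_gumbel(),
    normal = list(mean = 0, sd = 1),
    f_prime = list(d = 3L, M = 1000L),
    lognormal3 = list(a = 0, b = 1, c = 0)
  )
  params <- utils::modifyList(defaults, params)
  if (!is.null(params$scale)) check_scale(params$scale)
  if (!is.null(params$sd)) check_scale(params$sd)
  if (!is.null(params$b)) check_scale(params$b)
  structure(list(kind = kind, params = params, cache = new.env(parent = emptyenv())),
            class = "limit_model")
}

#' @export
print.limit_model <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 5),
             sep = " = ", collapse = ", ")
  cat(sprintf("<limit_model: %s (%s)>\n", x$kind, p))
  invisible(x)
}

conv2_grid <- function(model) {
  if (!is.null(model$cache$grid)) return(model$cache$grid)
  loc <- model$params$loc; scale <- model$params$scale
  # component support out to 1e-12 tail mass on both sides
  lo <- qgumbel(1e-12, loc, scale)
  hi <- qgumbel(1 - 1e-12, loc, scale)
  dx <- (hi - lo) / 2^15
  x <- seq(lo, hi, by = dx)
  h <- dgumbel(x, loc, scale)
  dens <- stats::convolve(h, rev(h), type = "open") * dx
  xs <- seq(2 * lo, by = dx, length.out = length(dens))
  dens[dens < 0] <- 0
  k <- length(dens)
  cdf <- c(0, cumsum((dens[-1] + dens[-k]) / 2)) * dx
  cdf <- pmin(cdf / cdf[k], 1)
  grid <- list(x = xs, pdf = dens / (sum(dens) * dx), cdf = cdf)
  model$cache$grid <- grid
  grid
}

#' Density, CDF and sampler of a limit model
#'
#' @param model A [limit_model()].
#' @param x Numeric vector of evaluation points.
#' @param n Number of draws.
#' @return `model_pdf()` / `model_cdf()`: numeric vector;
#'   `model_sample()`: `n` draws.
#' @export
model_pdf <- function(model, x) {
  p <- model$params
  switch(model$kind,
    std_gumbel = ,
    gumbel = dgumbel(x, p$loc, p$scale),
    gumbel_conv2 = {
      g <- conv2_grid(model)
      out <- approx(g$x, g$pdf, xout = x, yleft = 0, yright = 0)$y
      out
    },
    normal = dnorm(x, p$mean, p$sd),
    f_prime = abort("the f_prime family has no analytic density; use model_sample()"),
    lognormal3 = dlnorm3(x, p$a, p$b, p$c)
  )
}

#' @rdname model_pdf
#' @export
model_cdf <- function(model, x) {
  p <- model$params
  switch(model$kind,
    std_gumbel = ,
    gumbel = pgumbel(x, p$loc, p$scale),
    gumbel_conv2 = {
      g <- conv2_grid(model)
      approx(g$x, g$cdf, xout = x, yleft = 0, yright = 1)$y
    },
    normal = pnorm(x, p$mean, p$sd),
    f_prime = abort("the f_prime family has no analytic CDF; use model_sample()"),
    lognormal3 = {
      out <- numeric(length(x))
      ok <- x > p$c
      out[ok] <- stats::plnorm(x[ok] - p$c, meanlog = p$a, sdlog = p$b)
      out
    }
  )
}

#' @rdname model_pdf
#' @export
model_sample <- function(model, n) {
  p <- model$params
  switch(model$kind,
    std_gumbel = ,
    gumbel = rgumbel(n, p$loc, p$scale),
    gumbel_conv2 = rgumbel(n, p$loc, p$scale) + rgumbel(n, p$loc, p$scale),
    normal = stats::rnorm(n, p$mean, p$sd),
    f_prime = sample_lattice_limit(p$d, p$M, n),
    lognormal3 = p$c + stats::rlnorm(n, meanlog = p$a, sdlog = p$b)
  )
}

#' Analytic mean and variance of a limit model
#'
#' @param model A [limit_model()].
#' @return A one-row tibble with `mean` and `variance` (`NA` for the
#'   simulation-defined `f_prime` family, whose construction fixes them
#'   at 0 and 1).
#' @export
model_moments <- function(model) {
  p <- model$params
  g <- pi^2 / 6
  switch(model$kind,
    std_gumbel = ,
    gumbel = tibble(mean = p$loc + euler_gamma * p$scale,
                    variance = p$scale^2 * g),
    gumbel_conv2 = tibble(mean = 2 * (p$loc + euler_gamma * p$scale),
                          variance = 2 * p$scale^2 * g),
    normal = tibble(mean = p$mean, variance = p$sd^2),
    f_prime = tibble(mean = 0, variance = 1),
    lognormal3 = {
      w <- exp(p$b^2)
      tibble(mean = p$c + exp(p$a + p$b^2 / 2),
             variance = (w - 1) * exp(2 * p$a + p$b^2))
    }
  )
}

#' Serialize a limit model to / from JSON
#'
#' Only `kind` and the parameters travel; grids and caches are rebuilt on
#' demand, so the blob is small and stable.
#'
#' @param model A [limit_model()].
#' @param path File path; for `model_from_json()` a path or a JSON string.
#' @return `model_to_json()`: the path, invisibly; `model_from_json()`:
#'   a `limit_model`.
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(list(kind = model$kind, params = model$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  blob <- jsonlite::fromJSON(path)
  do.call(limit_model, c(list(kind = blob$kind), as.list(blob$params)))
}
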