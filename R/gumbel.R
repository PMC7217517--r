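#' The Gumbel distribution
#'
#' Density, distribution function, quantile function and random draws for
#' the Gumbel (type-I extreme value) distribution with location `loc` and
#' scale `scale`:
#' \deqn{h(x) = \beta^{-1} e^{-(x-\alpha)/\beta}
#'       \exp\!\left(-e^{-(x-\alpha)/\beta}\right),}
#' with mean \eqn{\alpha + \gamma\beta} and variance
#' \eqn{\beta^2 \pi^2 / 6}. Two members recur throughout the takeover-time
#' limits: `std_takeover_gumbel()`, the coupon-collector limit
#' Gumbel(\eqn{-\gamma}, 1) with mean 0, and `gumbel_prime()`,
#' Gumbel(\eqn{-\gamma\sqrt{3}/\pi}, \eqn{\sqrt{3}/\pi}) with mean 0 and
#' variance 1/2, whose two-copy sum has unit variance.
#'
#' @param x,q,p Numeric vectors of quantiles / probabilities.
#' @param n Number of draws.
#' @param loc,scale Location and scale (`scale > 0`).
#' @return Numeric vector; `std_takeover_gumbel()` and `gumbel_prime()`
#'   return a list with elements `loc` and `scale`.
#' @name gumbel
#' @examples
#' dgumbel(-euler_gamma, loc = -euler_gamma)   # peak density exp(-1)
#' p <- gumbel_prime()
#' p$scale^2 * pi^2 / 6                        # variance 1/2
NULL

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    abort("`scale` must be a positive number")
  invisible(scale)
}

#' @rdname gumbel
#' @export
dgumbel <- function(x, loc = 0, scale = 1) {
  check_scale(scale)
  z <- (x - loc) / scale
  exp(-z - exp(-z)) / scale
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, loc = 0, scale = 1) {
  check_scale(scale)
  exp(-exp(-(q - loc) / scale))
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, loc = 0, scale = 1) {
  check_scale(scale)
  loc - scale * log(-log(p))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, loc = 0, scale = 1) {
  check_scale(scale)
  loc - scale * log(stats::rexp(n))
}

#' @rdname gumbel
#' @export
std_takeover_gumbel <- function() list(loc = -euler_gamma, scale = 1)

#' @rdname gumbel
#' @export
gumbel_prime <- function() {
  s <- sqrt(3) / pi
  list(loc = -euler_gamma * s, scale = s)
}

#' Theoretical skewness of the Gumbel and its two-copy sum
#'
#' The Gumbel skewness is \eqn{12\sqrt{6}\,\zeta(3)/\pi^3 \approx 1.1395};
#' cumulants add under independent summation, so the convolution of two
#' identical Gumbels has skewness \eqn{1.1395/\sqrt 2 \approx 0.8058}.
#' These two values bracket the partial- vs complete-takeover behavior on
#' dense graphs.
#'
#' @param copies 1 for a single Gumbel, 2 for the two-copy convolution.
#' @return A length-one numeric.
#' @export
#' @examples
#' gumbel_skewness()
#' gumbel_skewness(2)
gumbel_skewness <- function(copies = 1) {
  apery <- 1.202056903159594  # zeta(3)
  12 * sqrt(6) * apery / pi^3 / sqrt(copies)
}
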