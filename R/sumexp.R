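#' Density of a sum of independent exponentials (hypoexponential)
#'
#' The star-graph takeover time, rescaled, is a sum of independent
#' exponential variables with rates \eqn{k = 1, \dots, N}. Its density is
#' available two ways:
#'
#' * `dsumexp_product(x, rates)` — the general partial-fraction (product)
#'   form for any distinct positive rates \eqn{\lambda_k}:
#'   \deqn{g(x) = \sum_k \lambda_k e^{-\lambda_k x}
#'         \prod_{r \ne k} \frac{\lambda_r}{\lambda_r - \lambda_k}.}
#'   The alternating products cancel catastrophically as the number of
#'   rates grows, so this form is guarded to at most 25 rates.
#' * `dsumexp_closed(x, n)` — for the specific rates \eqn{1, \dots, n}
#'   the sum telescopes to the numerically stable closed form
#'   \deqn{g_n(x) = n e^{-x} (1 - e^{-x})^{n-1}, \quad x \ge 0.}
#'
#' Centering `dsumexp_closed` by the harmonic number \eqn{H_n} and letting
#' `n` grow recovers the standard takeover Gumbel density
#' \eqn{e^{-(x+\gamma)} \exp(-e^{-(x+\gamma)})}.
#'
#' @param x Nonnegative evaluation points (negative `x` is an error: the
#'   support is \eqn{[0, \infty)}).
#' @param rates Distinct positive rates (at most 25).
#' @param n Number of unit-spaced rates \eqn{1, \dots, n}.
#' @return Numeric vector of density values.
#' @name dsumexp
#' @examples
#' dsumexp_product(1, c(1, 2))        # 2 e^{-1} (1 - e^{-1})
#' dsumexp_closed(1, 2)               # identical
NULL

#' @rdname dsumexp
#' @export
dsumexp_product <- function(x, rates) {
  if (any(x < 0)) abort("`x` must be nonnegative")
  rates <- as.numeric(rates)
  if (any(rates <= 0)) abort("rates must be positive")
  if (anyDuplicated(rates)) abort("rates must be distinct")
  if (length(rates) > 25L)
    abort("product form is numerically unstable beyond 25 rates; use dsumexp_closed() for unit-spaced rates")
  vapply(x, function(xi) {
    terms <- vapply(seq_along(rates), function(k) {
      lk <- rates[k]
      others <- rates[-k]
      lk * exp(-lk * xi) * prod(others / (others - lk))
    }, numeric(1))
    sum(terms)
  }, numeric(1))
}

#' @rdname dsumexp
#' @export
dsumexp_closed <- function(x, n) {
  n <- check_count(n, min = 1L, "n")
  if (any(x < 0)) abort("`x` must be nonnegative")
  # log-space keeps (1 - e^{-x})^{n-1} stable for large n and small x
  out <- exp(log(n) - x + (n - 1) * log1p(-exp(-x)))
  out[x == 0 & n > 1] <- 0
  out[x == 0 & n == 1] <- 1
  out
}

#' Three-parameter lognormal density
#'
#' \deqn{h(x) = \frac{1}{(x - c)\sqrt{2\pi b^2}}
#'       \exp\!\left(-\frac{[\log(x - c) - a]^2}{2 b^2}\right),
#'       \quad x > c,}
#' and 0 for \eqn{x \le c} by convention. This is the shape traditionally
#' fit to right-skewed incubation-period data ("Sartwell's law"); a
#' suitably tuned member imitates a Gumbel closely, which is why
#' extreme-value takeover-time limits can masquerade as lognormal fits.
#'
#' @param x Evaluation points.
#' @param a,b Log-scale mean and standard deviation (`b > 0`).
#' @param c Threshold (left endpoint of the support).
#' @return Numeric vector of density values.
#' @seealso [fit_lognormal3_gumbel()]
#' @export
#' @examples
#' dlnorm3(1, 0, 1, 0)    # 1 / sqrt(2*pi)
dlnorm3 <- function(x, a, b, c = 0) {
  check_scale(b)
  out <- numeric(length(x))
  ok <- x > c
  out[ok] <- dlnorm(x[ok] - c, meanlog = a, sdlog = b)
  out
}

#' Tune a three-parameter lognormal to imitate a Gumbel
#'
#' Demonstration utility: minimizes the sup-norm difference between the
#' lognormal3 density and a Gumbel density on a fixed grid, with a
#' derivative-free (Nelder-Mead) search started from moment matching.
#' A good fit (sup-norm below 0.01 against Gumbel(\eqn{-\gamma}, 1))
#' shows how easily coupon-collector limits are mistaken for lognormals
#' in empirical incubation data; it is a convenience, not a claim of
#' equivalence.
#'
#' @param loc,scale Gumbel parameters to imitate.
#' @param grid Evaluation grid for the sup-norm.
#' @return A list with `a`, `b`, `c` and the achieved `sup_error`.
#' @export
fit_lognormal3_gumbel <- function(loc = -euler_gamma, scale = 1,
                                  grid = seq(loc - 3 * scale, loc + 12 * scale,
                                             length.out = 600)) {
  target <- dgumbel(grid, loc, scale)
  # start from matching mean, variance and skewness of the Gumbel
  skew <- gumbel_skewness()
  w <- uniroot(function(w) (w + 2) * sqrt(w - 1) - skew,
               c(1 + 1e-8, 4))$root
  b0 <- sqrt(log(w))
  v <- scale^2 * pi^2 / 6
  a0 <- 0.5 * log(v / ((w - 1) * w))
  c0 <- (loc + euler_gamma * scale) - exp(a0 + b0^2 / 2)
  obj <- function(par) {
    if (par[2] <= 0) return(Inf)
    max(abs(dlnorm3(grid, par[1], par[2], par[3]) - target))
  }
  fit <- optim(c(a0, b0, c0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(a = fit$par[1], b = fit$par[2], c = fit$par[3],
       sup_error = fit$value)
}
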