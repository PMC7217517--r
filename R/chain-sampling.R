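#' Sample takeover times from a stage-rate chain
#'
#' Draws takeover times as sums of independent per-stage waits, either
#' exactly (geometric waits on \{1, 2, ...\}, so wasted steps are counted)
#' or in the exponential approximation used by the analytical limits
#' (each geometric wait replaced by an exponential with the same rate;
#' the two agree in distribution as the system grows because every
#' individual rate is small).
#'
#' @param rates A `rate_vector` (see [ring_rates()] and friends).
#' @param runs Number of independent draws (`runs = 0` gives an empty
#'   sample set).
#' @param method `"geometric"` for the exact discrete chain,
#'   `"exponential"` for the continuous approximation.
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards. `NULL` uses the current stream.
#' @return A `takeover_samples` tibble with columns `run` and `time`, and
#'   provenance attributes (`topology`, `params`, `theta`, `method`,
#'   `seed`).
#' @export
#' @examples
#' set.seed(1)
#' s <- sample_chain(ring_rates(50), 1000)
#' mean(s$time)    # close to 50 * 49 = 2450
sample_chain <- function(rates, runs,
                         method = c("geometric", "exponential"),
                         seed = NULL) {
  method <- match.arg(method)
  runs <- check_count(runs, min = 0L, "runs")
  draw <- function() {
    if (runs == 0L) return(numeric(0))
    if (method == "geometric") {
      cpp_sample_geom_chain(rates$p, runs)
    } else {
      total <- numeric(runs)
      for (p in rates$p) total <- total + rexp(runs, rate = p)
      total
    }
  }
  values <- with_seed_local(seed, draw())
  theta <- attr(rates, "n_nodes")
  theta <- if (nrow(rates) > 0) max(rates$infected_after) / theta else 1
  new_takeover_samples(
    values,
    topology = attr(rates, "topology"),
    params = list(n_nodes = attr(rates, "n_nodes"), n_stages = nrow(rates)),
    theta = theta,
    method = if (method == "geometric") "geometric_chain" else "exponential_approx",
    seed = seed
  )
}

#' The lattice limit family F' and its two-copy convolution
#'
#' On a d-dimensional periodic lattice the infected cluster grows as a
#' compact blob whose boundary scales as volume to the power
#' \eqn{\eta = (d-1)/d}, so the opening of the takeover behaves like a sum
#' of exponential waits with rates \eqn{m^\eta}. `sample_f_prime()` draws
#' that sum, centered and scaled to unit variance:
#' \deqn{F' = \sum_{m=1}^{M} \frac{E(m^\eta) - m^{-\eta}}{\sqrt{H}},
#'       \quad H = \sum_{m=1}^{M} m^{-2\eta}.}
#' Because the endgame replays the opening in reverse, the standardized
#' takeover time is matched by `(F'_1 + F'_2) / sqrt(2)` with two
#' independent copies (`sample_lattice_limit()`).
#'
#' The family interpolates between the known extremes: `d = 1` gives
#' \eqn{\eta = 0} (identical waits, normal limit), `d = 2` gives
#' \eqn{\eta = 1/2} (H diverges, still normal), while for `d >= 3` H
#' converges, the third moment survives, and the limit is a distinct
#' skewed law approaching the two-Gumbel convolution as d grows.
#'
#' @param d Lattice dimension (`d >= 1`).
#' @param M Truncation length of the sum; for finite systems `M = N` is
#'   the default choice, and modest tuning of `M` sharpens finite-size
#'   agreement.
#' @param runs Number of draws.
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return A numeric vector of draws (zero mean, unit variance by
#'   construction).
#' @seealso [surface_exponent()], [lattice_h()]
#' @export
#' @examples
#' set.seed(1)
#' z <- sample_lattice_limit(3, M = 40, runs = 5000)
#' round(c(mean(z), var(z)), 2)
sample_f_prime <- function(d, M, runs, seed = NULL) {
  d <- check_count(d, min = 1L, "d")
  M <- check_count(M, min = 1L, "M")
  runs <- check_count(runs, min = 0L, "runs")
  if (runs == 0L) return(numeric(0))
  with_seed_local(seed, cpp_sample_fprime(surface_exponent(d), M, runs))
}

#' @rdname sample_f_prime
#' @export
sample_lattice_limit <- function(d, M, runs, seed = NULL) {
  d <- check_count(d, min = 1L, "d")
  M <- check_count(M, min = 1L, "M")
  runs <- check_count(runs, min = 0L, "runs")
  if (runs == 0L) return(numeric(0))
  eta <- surface_exponent(d)
  with_seed_local(seed, {
    (cpp_sample_fprime(eta, M, runs) + cpp_sample_fprime(eta, M, runs)) / sqrt(2)
  })
}

#' Surface exponent and variance sum of the lattice family
#'
#' `surface_exponent(d)` returns \eqn{\eta = (d-1)/d}, the exponent tying
#' the boundary of a compact m-node cluster to its volume on a
#' d-dimensional lattice. `lattice_h(d, M)` returns
#' \eqn{H = \sum_{m=1}^{M} m^{-2\eta}}, the variance of the uncentered
#' exponential sum; it diverges with M exactly when `d <= 2`, which is
#' why 2 is the critical dimension separating normal from skewed limits.
#'
#' @inheritParams sample_f_prime
#' @return A length-one numeric.
#' @export
#' @examples
#' surface_exponent(2)   # 1/2
#' lattice_h(3, 40)
surface_exponent <- function(d) {
  d <- check_count(d, min = 1L, "d")
  (d - 1) / d
}

#' @rdname surface_exponent
#' @export
lattice_h <- function(d, M) {
  M <- check_count(M, min = 1L, "M")
  sum((1:M)^(-2 * surface_exponent(d)))
}
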