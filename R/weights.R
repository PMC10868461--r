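#' Order-statistic spacing weights
#'
#' Generates a random probability-weight vector from the spacings of Beta
#' order statistics: draw `n - 1` values from `Beta(alpha, beta)`, sort
#' them, and take consecutive differences with boundaries
#' \eqn{U_{(0)} = 0}, \eqn{U_{(n)} = 1}, so
#' \eqn{W_i = U_{(i)} - U_{(i-1)}} and \eqn{W_n = 1 - \sum_{i<n} W_i}.
#' With `alpha = beta = 1` these are classic uniform spacings, each
#' marginally `Beta(1, n - 1)` with \eqn{E(\sum_i W_i^2) = 2/(n+1)}; the
#' asymptotic relative efficiency of the resulting randomly weighted
#' correlation is 1/2.
#'
#' @param n Number of weights (`n >= 1`).
#' @param alpha,beta Positive shape parameters of the Beta distribution.
#' @param seed Optional integer seed; the caller's RNG stream is restored
#'   afterwards when given.
#' @return A length-`n` vector of strictly positive weights summing to 1.
#' @examples
#' w <- beta_spacing_weights(10, 1, 1, seed = 42)
#' sum(w)
#' @export
beta_spacing_weights <- function(n, alpha = 1, beta = 1, seed = NULL) {
  if (n < 1) {
    stop("invalid size: `n` must be at least 1", call. = FALSE)
  }
  if (alpha <= 0 || beta <= 0) {
    stop("invalid shape: `alpha` and `beta` must be positive",
         call. = FALSE)
  }
  if (n == 1) {
    return(1)
  }
  .with_seed(seed, {
    repeat {
      u <- sort(rbeta(n - 1, alpha, beta))
      w <- diff(c(0, u, 1))
      if (all(w > 0)) break  # redraw on (measure-zero) ties or boundary hits
    }
    w
  })
}

#' Leverage-based weights
#'
#' Down-weights high-leverage observations: with the simple-regression
#' design matrix `[1, x]`, the hat-matrix diagonal is
#' \eqn{h_{ii} = 1/n + (x_i - \bar x)^2 / \sum_j (x_j - \bar x)^2} and the
#' weights are \eqn{w_i = (1 - h_{ii}) / \sum_j (1 - h_{jj})}.  Since
#' \eqn{h_{ii} < 1} for `n > 2`, all weights are strictly positive.  These
#' weights are random (functions of the data), which the studentized
#' permutation tests tolerate.
#'
#' @param x Numeric vector (`n >= 3`).
#' @return A probability-weight vector summing to 1.  When `x` is constant
#'   (rank-deficient design) equal weights are returned with a warning.
#' @export
leverage_weights <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) {
    stop("invalid size: leverage weights require n >= 3", call. = FALSE)
  }
  ssx <- sum((x - mean(x))^2)
  if (ssx == 0) {
    warning("constant `x`: rank-deficient design, falling back to equal weights",
            call. = FALSE)
    return(rep.int(1 / n, n))
  }
  h <- 1 / n + (x - mean(x))^2 / ssx
  (1 - h) / sum(1 - h)
}
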