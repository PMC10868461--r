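#' Bivariate data-generating scenarios
#'
#' Six zero-correlation bivariate distributions spanning normal,
#' heavy-tailed, bounded, and dependent-but-uncorrelated behaviour, used to
#' probe type-I error control of correlation tests:
#'
#' * `"mvn"` — standard bivariate normal with `rho = 0`.
#' * `"exponential"` — `(X, Y) = r S u` with `S = diag(2, 1)`, `u` uniform
#'   on the unit circle and `r ~ Exp(1)`; elliptical but heavy-tailed, with
#'   dependent components.
#' * `"circular"` — uniform on the unit circle, so `x^2 + y^2 = 1` exactly;
#'   strongly dependent with zero correlation.
#' * `"t4.1"` — `X = W + Z`, `Y = W - Z` with `W`, `Z` iid t(4.1); dependent
#'   with covariance zero and barely-finite fourth moments.
#' * `"mvt"` — bivariate t with 5 degrees of freedom, zero mean and
#'   identity scale matrix (covariance `(5/3) I`).
#' * `"uniform"` — independent `Uniform(0, 1)` marginals.
#'
#' @param scenario Scenario name.
#' @param n Number of pairs.
#' @param seed Optional integer seed (caller's RNG stream restored).
#' @return A `data.frame` with columns `x` and `y`.
#' @examples
#' d <- sample_scenario("circular", 5, seed = 1)
#' d$x^2 + d$y^2  # all 1
#' @export
sample_scenario <- function(scenario, n, seed = NULL) {
  scenario <- match.arg(scenario, wp_scenarios())
  if (n < 3) {
    stop("invalid size: `n` must be at least 3", call. = FALSE)
  }
  .with_seed(seed, {
    d <- switch(scenario,
      mvn = list(x = rnorm(n), y = rnorm(n)),
      exponential = {
        r <- rexp(n)
        th <- runif(n, 0, 2 * pi)
        list(x = 2 * r * cos(th), y = r * sin(th))
      },
      circular = {
        th <- runif(n, 0, 2 * pi)
        list(x = cos(th), y = sin(th))
      },
      "t4.1" = {
        wv <- rt(n, df = 4.1)
        zv <- rt(n, df = 4.1)
        list(x = wv + zv, y = wv - zv)
      },
      mvt = {
        s <- sqrt(rchisq(n, df = 5) / 5)
        list(x = rnorm(n) / s, y = rnorm(n) / s)
      },
      uniform = list(x = runif(n), y = runif(n))
    )
    data.frame(x = d$x, y = d$y)
  })
}

#' @rdname sample_scenario
#' @return `wp_scenarios()` returns the vector of valid scenario names.
#' @export
wp_scenarios <- function() {
  c("mvn", "exponential", "circular", "t4.1", "mvt", "uniform")
}

# Population means and SDs of each scenario's marginals, used to
# standardize before the correlation-inducing transform.  All analytic:
# exponential: X = 2 r cos(th), E r^2 = 2, E cos^2 = 1/2 => Var X = 4,
# Var Y = 1; circular: E X^2 = 1/2; t(4.1) sums: 2 * 4.1/2.1; mvt with
# identity scale: 5/3; uniform: 1/12.
.scenario_moments <- function(scenario) {
  scenario <- match.arg(scenario, wp_scenarios())
  switch(scenario,
         mvn = list(mean = c(0, 0), sd = c(1, 1)),
         exponential = list(mean = c(0, 0), sd = c(2, 1)),
         circular = list(mean = c(0, 0), sd = rep(sqrt(1 / 2), 2)),
         "t4.1" = list(mean = c(0, 0), sd = rep(sqrt(2 * 4.1 / 2.1), 2)),
         mvt = list(mean = c(0, 0), sd = rep(sqrt(5 / 3), 2)),
         uniform = list(mean = c(0.5, 0.5), sd = rep(sqrt(1 / 12), 2)))
}

#' Induce a target correlation by a linear transform
#'
#' Standardizes `x` and `y` by the scenario's population means and
#' standard deviations and applies the lower-triangular map
#' \deqn{B(\rho) = \begin{pmatrix} 1 & 0 \\ \rho & \sqrt{1-\rho^2}
#' \end{pmatrix},}
#' i.e. \eqn{\tilde x = x_s}, \eqn{\tilde y = \rho x_s +
#' \sqrt{1-\rho^2}\, y_s}.  When the inputs are uncorrelated with unit
#' variance the output has population correlation exactly `rho`
#' (`B(rho) B(rho)'` has unit diagonal and off-diagonal `rho`).
#'
#' @param data A `data.frame` with columns `x`, `y` drawn from `scenario`.
#' @param rho Target correlation in `[0, 1)`.
#' @param scenario Scenario name, used to look up the population moments.
#' @return A `data.frame` with transformed columns `x` and `y`.
#' @export
induce_correlation <- function(data, rho, scenario) {
  if (rho < 0 || rho >= 1) {
    stop("invalid target: `rho` must lie in [0, 1)", call. = FALSE)
  }
  mom <- .scenario_moments(scenario)
  xs <- (data$x - mom$mean[1]) / mom$sd[1]
  ys <- (data$y - mom$mean[2]) / mom$sd[2]
  data.frame(x = xs, y = rho * xs + sqrt(1 - rho^2) * ys)
}
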