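#' Weighted mean
#'
#' @param v Numeric vector.
#' @param w Probability weights of the same length (assumed to sum to 1).
#' @return `sum(w * v)`.
#' @examples
#' weighted_mean(c(1, 2, 4), c(0.2, 0.3, 0.5))  # 2.8
#' @export
weighted_mean <- function(v, w) {
  if (length(v) != length(w)) {
    stop("invalid data: `v` (length ", length(v), ") and `w` (length ",
         length(w), ") must have equal length", call. = FALSE)
  }
  sum(w * v)
}

#' Weighted Pearson correlation coefficient
#'
#' Computes the weighted sample Pearson correlation
#' \deqn{\hat\rho_w = \frac{\sum_i w_i (x_i - \bar x_w)(y_i - \bar y_w)}
#'   {\sqrt{\sum_i w_i (x_i-\bar x_w)^2 \sum_i w_i (y_i-\bar y_w)^2}},}
#' where \eqn{\bar x_w = \sum_i w_i x_i} and the weights satisfy
#' \eqn{\sum_i w_i = 1}, \eqn{w_i > 0}.  With equal weights this is exactly
#' the classic sample Pearson correlation.  The estimate is invariant to
#' positive affine rescaling of either variable.
#'
#' @param x A [paired_sample], or a numeric vector (with `y` and optional
#'   `w` supplied).
#' @param y,w Numeric vectors, used when `x` is not a `paired_sample`.
#' @return The correlation estimate in `[-1, 1]`.
#' @examples
#' weighted_pearson(c(1, 2, 4), c(2, 1, 5), w = c(0.2, 0.3, 0.5))
#' @export
weighted_pearson <- function(x, y = NULL, w = NULL) {
  s <- as_paired_sample(x, y, w)
  mx <- sum(s$w * s$x)
  my <- sum(s$w * s$y)
  vx <- sum(s$w * s$x^2) - mx^2
  vy <- sum(s$w * s$y^2) - my^2
  if (vx <= 0 || vy <= 0) {
    stop("degenerate sample: zero weighted variance in `x` or `y`",
         call. = FALSE)
  }
  r <- (sum(s$w * s$x * s$y) - mx * my) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Weighted moment estimators and standardized residual vectors
#'
#' Computes the five weighted means (of \eqn{x, y, x^2, y^2, xy}), the five
#' weighted standard deviations with the `n/(n-1)` correction factor that
#' aligns them with the classic unbiased estimators in the equal-weight
#' case, and the standardized residual vectors `p, q, r, s, t` used to
#' assemble the moment covariance estimator (see [sigma_hat()]).
#'
#' Each weighted SD has the form
#' \eqn{s^2_{xw} = n \sum_i w_i (x_i - \bar x_w)^2 / (n - 1)} and each
#' standardized vector, e.g. \eqn{p_i = (x_i - \bar x_w)/s_{xw}}, has
#' weighted mean zero and weighted second moment \eqn{(n-1)/n}.
#'
#' @inheritParams weighted_pearson
#' @return An object of class `"moment_set"`: a list with `means` (named
#'   length-5 vector), `sds` (named length-5 vector), the standardized
#'   vectors `p`, `q`, `r`, `s`, `t`, and `n`.
#' @export
moment_set <- function(x, y = NULL, w = NULL) {
  smp <- as_paired_sample(x, y, w)
  n <- smp$n
  cf <- n / (n - 1)
  feats <- cbind(x = smp$x, y = smp$y, x2 = smp$x^2, y2 = smp$y^2,
                 xy = smp$x * smp$y)
  means <- colSums(smp$w * feats)
  # sum(w (f - mean)^2) = sum(w f^2) - mean^2 since sum(w) = 1
  vars <- cf * (colSums(smp$w * feats^2) - means^2)
  vars[vars < 0] <- 0  # guard against negative rounding at machine precision
  sds <- sqrt(vars)
  if (sds[["x"]] == 0 || sds[["y"]] == 0 || sds[["xy"]] == 0) {
    stop("degenerate sample: zero weighted SD among x, y or xy",
         call. = FALSE)
  }
  if (sds[["x2"]] == 0 || sds[["y2"]] == 0) {
    stop("degenerate sample: x^2 or y^2 is constant", call. = FALSE)
  }
  centred <- sweep(feats, 2L, means, "-")
  std <- sweep(centred, 2L, sds, "/")
  structure(list(means = means, sds = sds,
                 p = std[, "x"], q = std[, "y"], r = std[, "x2"],
                 s = std[, "y2"], t = std[, "xy"],
                 n = n, w = smp$w),
            class = "moment_set")
}

#' Delta-method gradient of the correlation functional
#'
#' The weighted correlation can be written as a smooth function
#' \eqn{g(\bar x_w, \bar y_w, \overline{x^2}_w, \overline{y^2}_w,
#' \overline{xy}_w)} of five weighted raw moments.  This returns the
#' gradient of \eqn{g} evaluated at population (or plug-in) moments:
#' \deqn{d_1 = \rho\mu_X/\sigma_X^2 - \mu_Y/(\sigma_X\sigma_Y),\quad
#'   d_2 = \rho\mu_Y/\sigma_Y^2 - \mu_X/(\sigma_X\sigma_Y),}
#' \deqn{d_3 = -\rho/(2\sigma_X^2),\quad d_4 = -\rho/(2\sigma_Y^2),\quad
#'   d_5 = 1/(\sigma_X\sigma_Y).}
#'
#' @param mu_x,mu_y Means of X and Y.
#' @param sigma_x,sigma_y Standard deviations of X and Y (positive).
#' @param rho Correlation in `(-1, 1)`.
#' @return Numeric vector `c(d1, d2, d3, d4, d5)`.
#' @export
gradient_d <- function(mu_x, mu_y, sigma_x, sigma_y, rho) {
  if (sigma_x <= 0 || sigma_y <= 0) {
    stop("invalid moments: `sigma_x` and `sigma_y` must be positive",
         call. = FALSE)
  }
  sxy <- sigma_x * sigma_y
  c(rho * mu_x / sigma_x^2 - mu_y / sxy,
    rho * mu_y / sigma_y^2 - mu_x / sxy,
    -rho / (2 * sigma_x^2),
    -rho / (2 * sigma_y^2),
    1 / sxy)
}

#' Moment covariance estimator for (X, Y, X^2, Y^2, XY)
#'
#' The plug-in estimator of the 5x5 covariance matrix of the summand vector
#' \eqn{(X, Y, X^2, Y^2, XY)}.  Every entry takes the form
#' \eqn{n \sum_i w_i (a_i - \bar a_w)(b_i - \bar b_w)/(n-1)} for `a`, `b`
#' ranging over the five derived columns; the diagonal equals the squared
#' weighted SDs of [moment_set()].  With equal weights this is exactly the
#' unbiased sample covariance matrix of the five columns.
#'
#' @inheritParams weighted_pearson
#' @return A symmetric 5x5 matrix with dimnames
#'   `c("x", "y", "x2", "y2", "xy")`.
#' @export
sigma_hat <- function(x, y = NULL, w = NULL) {
  smp <- as_paired_sample(x, y, w)
  ms <- moment_set(smp)  # validates non-degeneracy
  n <- smp$n
  cf <- n / (n - 1)
  feats <- cbind(x = smp$x, y = smp$y, x2 = smp$x^2, y2 = smp$y^2,
                 xy = smp$x * smp$y)
  raw <- crossprod(feats, smp$w * feats)   # sum_i w_i a_i b_i
  S <- cf * (raw - tcrossprod(ms$means))
  (S + t(S)) / 2
}

#' Delta-method variance of the weighted Pearson estimator
#'
#' Estimates \eqn{\widehat{Var}(\hat\rho_w) = \sum_i w_i^2 \, d \hat\Sigma
#' d'}, where \eqn{\hat\Sigma} is the moment covariance estimator of
#' [sigma_hat()] and the gradient `d` is evaluated at the weighted plug-in
#' moments together with `rho_plugin`.  Choosing `rho_plugin = `\eqn{\hat
#' \rho_w} gives the plug-in variance used by the asymptotic test and the
#' Perm-1/Perm-Z1 studentizations; `rho_plugin = 0` gives the null-variance
#' form used by Perm-2/Perm-Z2.  The same estimator applies to random
#' weights, whose observed values are moment estimates of their means.
#'
#' If the quadratic form \eqn{d\hat\Sigma d'} is non-positive (possible at
#' very small n through rounding) it is clamped to `1e-12` with a warning so
#' that studentized statistics remain defined.
#'
#' @inheritParams weighted_pearson
#' @param rho_plugin Correlation value in `(-1, 1)` plugged into the
#'   gradient; typically `weighted_pearson(x)` or `0`.
#' @return A strictly positive variance estimate.
#' @export
variance_rhohat <- function(x, y = NULL, w = NULL, rho_plugin) {
  smp <- as_paired_sample(x, y, w)
  if (abs(rho_plugin) >= 1) {
    stop("invalid plug-in: `rho_plugin` must lie in (-1, 1)", call. = FALSE)
  }
  ms <- moment_set(smp)
  S <- sigma_hat(smp)
  d <- gradient_d(ms$means[["x"]], ms$means[["y"]],
                  ms$sds[["x"]], ms$sds[["y"]], rho_plugin)
  q <- drop(crossprod(d, S %*% d))
  if (q <= 0) {
    warning("non-positive delta-method quadratic form; clamping to 1e-12",
            call. = FALSE)
    q <- 1e-12
  }
  sum(smp$w^2) * q
}

#' Fisher Z transformation
#'
#' The variance-stabilizing transform
#' \eqn{z(\rho) = \tfrac12 \log\{(1+\rho)/(1-\rho)\}} (i.e. `atanh`), a
#' monotone increasing odd function on `(-1, 1)` with `z(0) = 0`, so that
#' one-sided rejection directions agree with those based on the raw
#' correlation.
#'
#' @param rho Correlation value(s) with `|rho| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) {
    stop("domain error: `fisher_z` requires |rho| < 1", call. = FALSE)
  }
  atanh(rho)
}

#' Delta-method variance of the Fisher-Z transformed estimator
#'
#' Divides the variance from [variance_rhohat()] by \eqn{(1 -
#' \rho^2)^2} evaluated at the same plug-in, the delta-method variance of
#' \eqn{z(\hat\rho_w)}.  With `rho_plugin = 0` the two variances coincide.
#'
#' @inheritParams variance_rhohat
#' @return A strictly positive variance estimate.
#' @export
variance_fisher_z <- function(x, y = NULL, w = NULL, rho_plugin) {
  if (abs(rho_plugin) >= 1) {
    stop("invalid plug-in: `rho_plugin` must lie in (-1, 1)", call. = FALSE)
  }
  variance_rhohat(x, y, w, rho_plugin = rho_plugin) / (1 - rho_plugin^2)^2
}

#' Asymptotic relative efficiency of the weighted estimator
#'
#' For fixed probability weights the weighted correlation has asymptotic
#' variance proportional to \eqn{\sum_i w_i^2} while the unweighted one is
#' proportional to `1/n`, so the A.R.E. is
#' \eqn{(1/n) / \sum_i w_i^2}.  By Cauchy-Schwarz this is at most 1, with
#' equality iff all weights are equal.
#'
#' @param w Vector of positive weights summing to 1 (renormalized if not).
#' @return The efficiency in `(0, 1]`.
#' @examples
#' are_fixed(rep(c(1/15, 2/15), each = 5))  # 0.9
#' @export
are_fixed <- function(w) {
  w <- as.numeric(w)
  if (length(w) < 1 || !all(is.finite(w)) || any(w <= 0)) {
    stop("invalid weights: all weights must be positive and finite",
         call. = FALSE)
  }
  w <- w / sum(w)
  (1 / length(w)) / sum(w^2)
}
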