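# Independent oracles, written from textbook formulas and kept free of any
# package internals.

# Classic Pearson correlation from the definition.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Unweighted delta-method variance of the Pearson estimator: (1/n) d' C d
# with C the unbiased sample covariance of (x, y, x^2, y^2, xy) and the
# gradient evaluated at the sample plug-ins.
oracle_delta_var <- function(x, y, rho_plugin) {
  n <- length(x)
  F <- cbind(x, y, x^2, y^2, x * y)
  C <- stats::cov(F)
  mx <- mean(x); my <- mean(y); sx <- stats::sd(x); sy <- stats::sd(y)
  d <- c(rho_plugin * mx / sx^2 - my / (sx * sy),
         rho_plugin * my / sy^2 - mx / (sx * sy),
         -rho_plugin / (2 * sx^2),
         -rho_plugin / (2 * sy^2),
         1 / (sx * sy))
  drop(crossprod(d, C %*% d)) / n
}

# DiCiccio-Romano style studentized statistic for the zero null with equal
# weights: rho-hat divided by the root of the plug-in variance of the
# standardized cross product, rho-hat / sqrt(tau^2/n) with
# tau^2 = Var((X - mu_X)(Y - mu_Y)) / (Var X Var Y), all at sample
# plug-ins.  var((x - xbar)(y - ybar)) is the exact quadratic form of the
# linear combination xy - ybar*x - xbar*y in the unbiased covariance of
# the five derived columns.
oracle_dr_stat <- function(x, y) {
  n <- length(x)
  rho <- oracle_pearson(x, y)
  tau2 <- stats::var((x - mean(x)) * (y - mean(y))) /
    (stats::var(x) * stats::var(y))
  rho / sqrt(tau2 / n)
}

# Delete-one jackknife of the classic Pearson estimator.
oracle_jackknife <- function(x, y) {
  n <- length(x)
  loo <- vapply(seq_len(n), function(i) cor(x[-i], y[-i]), numeric(1))
  v <- (n - 1) / n * sum((loo - mean(loo))^2)
  list(variance = v, statistic = cor(x, y) / sqrt(v))
}

# Analytic covariance matrix of (X, Y, X^2, Y^2, XY) for a standard
# bivariate normal with correlation rho (Isserlis moments).
oracle_bvn_sigma <- function(rho) {
  matrix(c(1,    rho,  0,         0,         0,
           rho,  1,    0,         0,         0,
           0,    0,    2,         2 * rho^2, 2 * rho,
           0,    0,    2 * rho^2, 2,         2 * rho,
           0,    0,    2 * rho,   2 * rho,   1 + rho^2),
         5, 5, byrow = TRUE)
}

# Binomial Monte Carlo half-width: 3 standard errors at rate p0.
mc_halfwidth <- function(p0, n_reps) 3 * sqrt(p0 * (1 - p0) / n_reps)
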