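# Vectorized evaluation of permutation-test statistics.
#
# Y holds one permuted copy of y per column; W is either the fixed weight
# vector (weights stay attached to x) or an n x B matrix of per-replicate
# averaged weights.  All weighted raw cross moments of the feature vector
# (x, y, x^2, y^2, xy) are accumulated by column, the centered covariance
# entries recovered via C_ab = n/(n-1) * (S_ab - m_a m_b) (valid because
# each weight column sums to 1), and the delta-method quadratic form
# d' Sigma d expanded termwise.  This is algebraically identical to the
# scalar route through moment_set()/sigma_hat()/variance_rhohat(), which a
# unit test asserts.
.wp_stat_cols <- function(x, Y, W,
                          stat_rule = c("raw", "student", "student-z"),
                          plugin = c("rho", "zero"), rho0 = 0) {
  stat_rule <- match.arg(stat_rule)
  plugin <- match.arg(plugin)
  n <- length(x)
  cf <- n / (n - 1)
  x2 <- x * x
  Y2 <- Y * Y
  wmat <- is.matrix(W)

  if (wmat) {
    sw2 <- colSums(W * W)
    m1  <- colSums(W * x)
    S11 <- colSums(W * x2)
    S13 <- colSums(W * x2 * x)
    S33 <- colSums(W * x2 * x2)
  } else {
    sw2 <- sum(W * W)
    m1  <- sum(W * x)
    S11 <- sum(W * x2)
    S13 <- sum(W * x2 * x)
    S33 <- sum(W * x2 * x2)
  }
  WY <- W * Y                      # length-n W recycles down columns
  m2  <- colSums(WY)               # sum w y
  S12 <- colSums(WY * x)           # sum w x y
  S22 <- colSums(WY * Y)           # sum w y^2
  S14 <- colSums(WY * Y * x)       # sum w x y^2
  S15 <- colSums(WY * x2)          # sum w x^2 y
  S24 <- colSums(WY * Y2)          # sum w y^3
  S34 <- colSums(WY * Y * x2)      # sum w x^2 y^2
  S35 <- colSums(WY * x2 * x)      # sum w x^3 y
  S44 <- colSums(WY * Y2 * Y)      # sum w y^4
  S45 <- colSums(WY * Y2 * x)      # sum w x y^3

  m3 <- S11                        # mean of x^2
  m4 <- S22                        # mean of y^2
  m5 <- S12                        # mean of xy

  C11 <- cf * (S11 - m1 * m1)
  C22 <- cf * (S22 - m2 * m2)
  C12 <- cf * (S12 - m1 * m2)
  rho <- C12 / sqrt(C11 * C22)
  rho <- pmin(1, pmax(-1, rho))
  if (stat_rule == "raw") {
    return(rho)
  }

  C13 <- cf * (S13 - m1 * m3)
  C14 <- cf * (S14 - m1 * m4)
  C15 <- cf * (S15 - m1 * m5)
  C23 <- cf * (S15 - m2 * m3)
  C24 <- cf * (S24 - m2 * m4)
  C25 <- cf * (S14 - m2 * m5)
  C33 <- cf * (S33 - m3 * m3)
  C34 <- cf * (S34 - m3 * m4)
  C35 <- cf * (S35 - m3 * m5)
  C44 <- cf * (S44 - m4 * m4)
  C45 <- cf * (S45 - m4 * m5)
  C55 <- cf * (S34 - m5 * m5)

  rs <- if (plugin == "zero") 0 else pmin(1 - 1e-8, pmax(-1 + 1e-8, rho))
  isd <- 1 / sqrt(C11 * C22)       # 1/(sigma_x sigma_y)
  d1 <- rs * m1 / C11 - m2 * isd
  d2 <- rs * m2 / C22 - m1 * isd
  d3 <- -rs / (2 * C11)
  d4 <- -rs / (2 * C22)
  d5 <- isd

  q <- d1 * d1 * C11 + d2 * d2 * C22 + d3 * d3 * C33 + d4 * d4 * C44 +
    d5 * d5 * C55 +
    2 * (d1 * d2 * C12 + d1 * d3 * C13 + d1 * d4 * C14 + d1 * d5 * C15 +
           d2 * d3 * C23 + d2 * d4 * C24 + d2 * d5 * C25 +
           d3 * d4 * C34 + d3 * d5 * C35 + d4 * d5 * C45)
  q <- pmax(q, 1e-12)
  v <- sw2 * q

  if (stat_rule == "student") {
    return((rho - rho0) / sqrt(v))
  }
  # Fisher-Z studentization; clamp rho away from +-1 so atanh stays finite
  vz <- v / (1 - rs^2)^2
  rz <- pmin(1 - 1e-8, pmax(-1 + 1e-8, rho))
  (atanh(rz) - atanh(rho0)) / sqrt(vz)
}
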