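test_that("asymptotic_test chains the estimator and variance and rejects
           degenerate inputs", {
  expect_error(asymptotic_test(1:5, 1:5), "degenerate statistic")
  s <- paired_sample(c(1, 2, 4), c(2, 1, 5), c(0.2, 0.3, 0.5))
  res <- asymptotic_test(s)
  rho <- weighted_pearson(s)
  expect_equal(res$estimate, rho)
  expect_equal(res$statistic,
               rho / sqrt(variance_rhohat(s, rho_plugin = rho)))
  expect_equal(res$p.value, pnorm(res$statistic, lower.tail = FALSE))
  res2 <- asymptotic_test(s, alternative = "two.sided")
  expect_equal(res2$p.value, 2 * pnorm(abs(res2$statistic),
                                       lower.tail = FALSE))
})

test_that("asymptotic_test holds its level under equal-weight normality", {
  set.seed(31)
  n <- 100
  reps <- 1500
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rnorm(n)
    rho <- weighted_pearson(x, y)
    stat <- rho / sqrt(variance_rhohat(x, y, rho_plugin = rho))
    if (pnorm(stat, lower.tail = FALSE) <= 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.05), mc_halfwidth(0.05, reps))
})

test_that("ttest_weighted reproduces the textbook Pearson t-test under
           equal weights", {
  set.seed(32)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  res <- ttest_weighted(x, y)
  ref <- cor.test(x, y, alternative = "greater")
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  # exactly zero correlation gives statistic 0 and one-sided p 1/2
  res0 <- ttest_weighted(c(-1, 0, 1), c(0, 1, 0))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 0.5)
})

test_that("studentized_statistic matches its oracles and plug-in algebra", {
  set.seed(33)
  x <- rnorm(30); y <- rnorm(30)
  # equal-weight Perm-2 statistic is the DiCiccio-Romano studentization
  expect_equal(studentized_statistic(x, y, variant = "perm-2"),
               oracle_dr_stat(x, y), tolerance = 1e-10)
  w <- beta_spacing_weights(30, 1, 1, seed = 8)
  # Perm-1 and Perm-2 differ only through the variance plug-in
  s1 <- studentized_statistic(x, y, w, variant = "perm-1")
  s2 <- studentized_statistic(x, y, w, variant = "perm-2")
  rho <- weighted_pearson(x, y, w)
  expect_equal(s1, rho / sqrt(variance_rhohat(x, y, w, rho_plugin = rho)),
               tolerance = 1e-12)
  expect_equal(s2, rho / sqrt(variance_rhohat(x, y, w, rho_plugin = 0)),
               tolerance = 1e-12)
  # naive scheme returns the raw weighted correlation
  expect_equal(studentized_statistic(x, y, w, variant = "naive-perm"),
               rho, tolerance = 1e-12)
  # Fisher-Z statistic at zero estimate is exactly zero
  xz <- c(-1, 0, 1); yz <- c(0, 1, 0)
  expect_equal(weighted_pearson(xz, yz), 0)
  expect_equal(studentized_statistic(xz, yz, variant = "perm-z2"), 0)
})

test_that("permutation_test agrees with full enumeration on a small
           fixture for every variant", {
  set.seed(34)
  x <- c(0.3, -1.2, 0.8, 1.9, -0.4)
  y <- c(1.1, 0.2, -0.7, 2.3, 0.5)
  w <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  for (v in c("naive-perm", "perm-1", "perm-2", "perm-ave", "perm-z1",
              "perm-z2")) {
    pe <- exact_permutation_test(x, y, w, variant = v)$p.value
    pm <- permutation_test(x, y, w, variant = v, B = 5000,
                           seed = 100)$p.value
    expect_lt(abs(pm - pe), 0.02)
  }
})

test_that("permutation_test validates inputs and is reproducible", {
  set.seed(35)
  x <- rnorm(12); y <- rnorm(12)
  expect_error(permutation_test(rep(1, 12), y), "constant")
  expect_error(permutation_test(x, y, B = 50), "at least 99")
  p1 <- permutation_test(x, y, variant = "perm-z2", B = 200, seed = 42)
  p2 <- permutation_test(x, y, variant = "perm-z2", B = 200, seed = 42)
  expect_identical(p1$p.value, p2$p.value)
  expect_identical(p1$statistic, p2$statistic)
  expect_gte(p1$p.value, 1 / 201)
  # the caller's RNG stream is not consumed when a seed is supplied
  set.seed(77); before <- rnorm(1)
  set.seed(77)
  invisible(permutation_test(x, y, B = 100, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("exact_permutation_test enumerates the full group", {
  res <- exact_permutation_test(c(1, 2, 3), c(2, 3, 1),
                                variant = "naive-perm")
  expect_equal(res$n_perm, 6L)
  expect_true(res$p.value %in% ((1:6) / 6))
  expect_gte(res$p.value, 1 / 6)
  expect_error(exact_permutation_test(rnorm(9), rnorm(9)), "n <= 8")
  # Monte-Carlo convergence on an n = 6 fixture
  x <- c(0.5, -0.1, 1.4, -2.0, 0.3, 0.9)
  y <- c(1.0, 0.4, -0.3, 0.8, -1.1, 0.2)
  w <- c(2, 1, 3, 1, 2, 1) / 10
  pe <- exact_permutation_test(x, y, w, variant = "perm-z2")$p.value
  pm <- permutation_test(x, y, w, variant = "perm-z2", B = 20000,
                         seed = 9)$p.value
  expect_lt(abs(pm - pe), 0.02)
})

test_that("naive permutation is exact under an exchangeable null", {
  set.seed(36)
  n <- 20
  reps <- 1500
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rnorm(n)
    p <- permutation_test(x, y, variant = "naive-perm", B = 300,
                          seed = 5000 + i)$p.value
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.05), mc_halfwidth(0.05, reps))
})

test_that("permutation p-values are super-uniform under exchangeability
           for every variant", {
  set.seed(37)
  n <- 20
  reps <- 1200
  variants <- c("naive-perm", "perm-1", "perm-2", "perm-ave", "perm-z1",
                "perm-z2")
  pv <- matrix(NA_real_, reps, length(variants),
               dimnames = list(NULL, variants))
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rnorm(n)
    w <- rep(1 / n, n)
    smp <- paired_sample(x, y, w)
    for (v in variants) {
      pv[i, v] <- permutation_test(smp, variant = v, B = 200,
                                   seed = 20000 + i)$p.value
    }
  }
  for (v in variants) {
    for (cut in c(0.05, 0.10)) {
      expect_lt(abs(mean(pv[, v] <= cut) - cut),
                mc_halfwidth(cut, reps) + 1 / 201)
    }
  }
})

test_that("one-sided p-values decrease as the induced correlation grows", {
  base <- sample_scenario("mvn", 40, seed = 38)
  w <- beta_spacing_weights(40, 1, 1, seed = 39)
  p_seq <- vapply(c(0, 0.2, 0.4, 0.6), function(r) {
    d <- induce_correlation(base, r, "mvn")
    permutation_test(d$x, d$y, w, variant = "perm-z2", B = 400,
                     seed = 40)$p.value
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 0))
})

test_that("decorrelate implements the A(rho0) construction", {
  set.seed(41)
  x <- rnorm(25); y <- 0.6 * x + 0.8 * rnorm(25)
  w <- beta_spacing_weights(25, 1, 1, seed = 42)
  s <- paired_sample(x, y, w)
  # A(0) is the identity up to standardization: correlation unchanged
  expect_equal(weighted_pearson(decorrelate(s, rho0 = 0)),
               weighted_pearson(s), tolerance = 1e-12)
  # weighted standardization zeroes the weighted correlation at its own
  # estimate; unweighted standardization does the same for the classic one
  expect_equal(weighted_pearson(decorrelate(s, rho0 = weighted_pearson(s),
                                            standardize = "weighted")),
               0, tolerance = 1e-10)
  d0 <- decorrelate(paired_sample(x, y), rho0 = cor(x, y))
  expect_equal(cor(d0$x, d0$y), 0, tolerance = 1e-10)
  # A(0.6) %*% [[1, .6], [.6, 1]] %*% t(A(0.6)) = I
  A <- matrix(c(1, 0, -0.6 / sqrt(1 - 0.36), 1 / sqrt(1 - 0.36)),
              2, 2, byrow = TRUE)
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(A %*% R %*% t(A), diag(2), tolerance = 1e-12)
  # numeric guard near the boundary
  d <- decorrelate(s, rho0 = 0.999999)
  expect_true(all(is.finite(d$y)))
})

test_that("test_nonzero reduces to the zero-null test at rho0 = 0 and
           records the original null", {
  set.seed(43)
  x <- rnorm(20); y <- rnorm(20)
  w <- beta_spacing_weights(20, 1, 1, seed = 44)
  s <- paired_sample(x, y, w)
  p_direct <- permutation_test(decorrelate(s, rho0 = 0), variant = "perm-z2",
                               B = 300, seed = 7)$p.value
  res <- test_nonzero(s, rho0 = 0, method = "perm-z2", B = 300, seed = 7)
  expect_equal(res$p.value, p_direct, tolerance = 1e-12)
  res3 <- test_nonzero(s, rho0 = 0.3, method = "perm-z2", B = 300,
                       seed = 7)
  expect_equal(res3$rho0, 0.3)
  expect_equal(res3$estimate, weighted_pearson(s))
})

test_that("jackknife_test matches the textbook jackknife under equal
           weights and flags zero variance", {
  set.seed(45)
  x <- rnorm(15); y <- 0.4 * x + rnorm(15)
  res <- jackknife_test(x, y)
  ref <- oracle_jackknife(x, y)
  expect_equal(res$variance, ref$variance, tolerance = 1e-10)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
  expect_true(res$p.value > 0 && res$p.value <= 1)
  expect_error(jackknife_test(1:10, (1:10) * 2), "variance is zero")
})
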