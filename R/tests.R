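#' @title Test-result objects
#' @description Every test in the package returns a `"wp_test"` object: a
#'   list with the weighted correlation `estimate`, the test `statistic`,
#'   the `variance` used for studentization (when applicable), the
#'   `p.value`, the `method` label, the `alternative`, the null value
#'   `rho0`, the sample size `n`, and, for Monte Carlo permutation methods,
#'   `n_perm` and `seed`.
#' @param estimate,statistic,variance,p.value,method,alternative,rho0,n,n_perm,seed
#'   Fields as described above.
#' @return A `"wp_test"` object.
#' @keywords internal
new_wp_test <- function(estimate, statistic, variance, p.value, method,
                        alternative, rho0, n, n_perm = NULL, seed = NULL) {
  structure(list(estimate = estimate, statistic = statistic,
                 variance = variance, p.value = p.value, method = method,
                 alternative = alternative, rho0 = rho0, n = n,
                 n_perm = n_perm, seed = seed),
            class = "wp_test")
}

#' @export
print.wp_test <- function(x, ...) {
  lab <- c("t-test" = "Conventional t-test (invalid under unequal weights)",
           "asymptotic" = "Asymptotic test (delta-method variance)",
           "naive-perm" = "Naive permutation test (unstudentized)",
           "perm-1" = "Studentized permutation test (plug-in rho-hat)",
           "perm-2" = "Studentized permutation test (plug-in 0)",
           "perm-ave" = "Studentized permutation test (averaged weights)",
           "perm-z1" = "Fisher-Z studentized permutation test (plug-in rho-hat)",
           "perm-z2" = "Fisher-Z studentized permutation test (plug-in 0)",
           "jackknife" = "Jackknife-variance test (comparator, non-canonical)")
  cat("\n\t", if (x$method %in% names(lab)) lab[[x$method]] else x$method,
      "\n\n", sep = "")
  cat(sprintf("weighted Pearson correlation = %.6f, n = %d\n",
              x$estimate, x$n))
  cat(sprintf("statistic = %.6f%s, p-value = %.6g\n", x$statistic,
              if (!is.null(x$variance) && is.finite(x$variance))
                sprintf(" (variance %.6g)", x$variance) else "",
              x$p.value))
  cat(sprintf("alternative: rho %s %g\n",
              switch(x$alternative, greater = ">", less = "<", "!="),
              x$rho0))
  if (!is.null(x$n_perm)) {
    cat(sprintf("permutations: %d%s\n", x$n_perm,
                if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.wp_test <- function(x, ...) {
  data.frame(method = x$method, n = x$n, estimate = x$estimate,
             statistic = x$statistic,
             variance = if (is.null(x$variance)) NA_real_ else x$variance,
             p.value = x$p.value, alternative = x$alternative,
             rho0 = x$rho0,
             n_perm = if (is.null(x$n_perm)) NA_integer_ else x$n_perm,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             stringsAsFactors = FALSE)
}

.wp_alternatives <- c("greater", "less", "two.sided")

.norm_pvalue <- function(stat, alternative) {
  switch(alternative,
         greater = pnorm(stat, lower.tail = FALSE),
         less = pnorm(stat),
         two.sided = 2 * pnorm(abs(stat), lower.tail = FALSE))
}

#' Asymptotic test for the weighted Pearson correlation
#'
#' Tests `H0: rho = rho0` using the large-sample normal approximation for
#' the weighted estimator: the statistic is
#' \eqn{(\hat\rho_w - \rho_0)/\sqrt{\widehat{Var}(\hat\rho_w)}} with the
#' delta-method variance of [variance_rhohat()] evaluated at the plug-in
#' \eqn{\hat\rho_w}, referred to the standard normal distribution.  The
#' approximation is reliable for `n` of about 50 and larger; for smaller
#' samples prefer [permutation_test()].
#'
#' @inheritParams weighted_pearson
#' @param rho0 Null correlation value in `(-1, 1)`.
#' @param alternative One of `"greater"` (default, the one-sided test
#'   `H1: rho > rho0`), `"less"`, `"two.sided"`.
#' @return A [`wp_test`][new_wp_test] object.
#' @export
asymptotic_test <- function(x, y = NULL, w = NULL, rho0 = 0,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  if (abs(rho0) >= 1) {
    stop("invalid null: `rho0` must lie in (-1, 1)", call. = FALSE)
  }
  rho <- weighted_pearson(smp)
  if (abs(rho) >= 1 - 1e-12) {
    stop("degenerate statistic: |weighted correlation| = 1, variance is 0",
         call. = FALSE)
  }
  v <- variance_rhohat(smp, rho_plugin = rho)
  stat <- (rho - rho0) / sqrt(v)
  new_wp_test(rho, stat, v, .norm_pvalue(stat, alternative), "asymptotic",
              alternative, rho0, smp$n)
}

#' Conventional t-test for a weighted correlation (comparator)
#'
#' The t-test routinely applied by statistical software to a weighted
#' correlation: \eqn{t = \hat\rho_w \sqrt{(n-2)/(1-\hat\rho_w^2)}} on
#' `n - 2` degrees of freedom, i.e. the unweighted Pearson test with
#' \eqn{\hat\rho_w} substituted for \eqn{\hat\rho}.  With unequal weights
#' the statistic does not follow this reference distribution and the
#' type-I error can be severely inflated; the function is provided only as
#' a comparator for validity studies.
#'
#' @inheritParams asymptotic_test
#' @return A [`wp_test`][new_wp_test] object with `method = "t-test"`.
#' @export
ttest_weighted <- function(x, y = NULL, w = NULL,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  rho <- weighted_pearson(smp)
  if (abs(rho) >= 1 - 1e-12) {
    stop("degenerate statistic: |weighted correlation| = 1", call. = FALSE)
  }
  df <- smp$n - 2
  stat <- rho * sqrt(df / (1 - rho^2))
  p <- switch(alternative,
              greater = pt(stat, df, lower.tail = FALSE),
              less = pt(stat, df),
              two.sided = 2 * pt(abs(stat), df, lower.tail = FALSE))
  new_wp_test(rho, stat, NULL, p, "t-test", alternative, 0, smp$n)
}

# Registry mapping each permutation variant to its weight rule, statistic
# rule and variance plug-in.
.wp_schemes <- list(
  "naive-perm" = list(weights = "fixed",    stat = "raw",       plugin = "zero"),
  "perm-1"     = list(weights = "fixed",    stat = "student",   plugin = "rho"),
  "perm-2"     = list(weights = "fixed",    stat = "student",   plugin = "zero"),
  "perm-ave"   = list(weights = "averaged", stat = "student",   plugin = "rho"),
  "perm-z1"    = list(weights = "fixed",    stat = "student-z", plugin = "rho"),
  "perm-z2"    = list(weights = "fixed",    stat = "student-z", plugin = "zero")
)

#' Permutation-scheme registry
#'
#' Resolves a variant label to its weight rule (weights held fixed to `x`,
#' or averaged with the permuted weights), statistic rule (raw correlation,
#' studentized correlation, or studentized Fisher-Z), and variance plug-in
#' (`rho` for the observed/replicate estimate, `zero` for the null value).
#'
#' @param variant One of `"naive-perm"`, `"perm-1"`, `"perm-2"`,
#'   `"perm-ave"`, `"perm-z1"`, `"perm-z2"`.
#' @return A list with fields `variant`, `weights`, `stat`, `plugin`.
#' @export
permutation_scheme <- function(variant) {
  variant <- match.arg(variant, names(.wp_schemes))
  c(list(variant = variant), .wp_schemes[[variant]])
}

#' Studentized test statistic for a given permutation scheme
#'
#' Computes the observed statistic a permutation variant compares against
#' its permutation distribution: the raw weighted correlation for the naive
#' scheme; \eqn{(\hat\rho_w - \rho_0)/\sqrt{\widehat{Var}}} for Perm-1 /
#' Perm-2 / Perm-ave (variance from [variance_rhohat()] at the scheme's
#' plug-in); \eqn{(z(\hat\rho_w) - z(\rho_0))/\sqrt{\widehat{Var}_z}} for
#' the Fisher-Z variants ([variance_fisher_z()]).
#'
#' @inheritParams weighted_pearson
#' @param variant Scheme label or a [permutation_scheme()] object.
#' @param rho0 Null correlation value.
#' @return The statistic (a single number).
#' @export
studentized_statistic <- function(x, y = NULL, w = NULL, variant,
                                  rho0 = 0) {
  smp <- as_paired_sample(x, y, w)
  sch <- if (is.list(variant)) variant else permutation_scheme(variant)
  .wp_stat_cols(smp$x, matrix(smp$y, ncol = 1), smp$w,
                stat_rule = sch$stat, plugin = sch$plugin, rho0 = rho0)[1]
}

# Restore the caller's RNG stream after using a local seed.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Lean permutation p-value core shared by permutation_test() and the
# simulation harness.  Returns the observed statistic and the tail counts.
.perm_core <- function(xv, yv, wv, sch, rho0, B) {
  n <- length(xv)
  obs <- .wp_stat_cols(xv, matrix(yv, ncol = 1), wv,
                       stat_rule = sch$stat, plugin = sch$plugin,
                       rho0 = rho0)[1]
  idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  Y <- matrix(yv[idx], n, B)
  W <- if (sch$weights == "averaged") {
    (wv + matrix(wv[idx], n, B)) / 2
  } else {
    wv
  }
  stats <- .wp_stat_cols(xv, Y, W, stat_rule = sch$stat,
                         plugin = sch$plugin, rho0 = rho0)
  upper <- (1 + sum(stats >= obs)) / (B + 1)
  lower <- (1 + sum(stats <= obs)) / (B + 1)
  list(obs = obs, upper = upper, lower = lower)
}

.perm_pvalue <- function(upper, lower, alternative) {
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(upper, lower)))
}

#' Monte Carlo permutation tests for the weighted correlation
#'
#' Tests `H0: rho = rho0` by comparing a (possibly studentized) statistic
#' with its distribution over `B` random permutations of `y`.  The weights
#' stay attached to `x` for every variant except `"perm-ave"`, where each
#' replicate uses the averaged weights \eqn{w^*_i = (w_i + w_{\pi(i)})/2}.
#' The replicate statistic is recomputed with the same scheme (including
#' re-estimating the plug-in variance on the permuted sample).
#'
#' Variants: `"naive-perm"` permutes the raw correlation and is exact only
#' under exchangeability (e.g. equal weights with independent marginals);
#' `"perm-1"`/`"perm-2"` studentize by the delta-method variance with
#' plug-in \eqn{\hat\rho_w} or 0; `"perm-z1"`/`"perm-z2"` studentize the
#' Fisher-Z transform likewise; `"perm-ave"` studentizes with plug-in
#' \eqn{\hat\rho_w} under averaged weights.  `"perm-z2"` has the most
#' robust small-sample type-I error control across heavy-tailed and
#' dependent-but-uncorrelated alternatives.
#'
#' The one-sided p-value uses add-one smoothing,
#' `(1 + #\{permuted >= observed\})/(B + 1)`, so it is always in
#' `[1/(B+1), 1]`; ties count toward the null.  The two-sided p-value is
#' twice the smaller tail, capped at 1.
#'
#' @inheritParams asymptotic_test
#' @param variant Scheme label; see [permutation_scheme()].
#' @param B Number of random permutations (at least 99; default 1000).
#' @param seed Optional integer seed for the permutation draws.  The
#'   caller's RNG stream is left untouched when a seed is given.
#' @return A [`wp_test`][new_wp_test] object.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- rnorm(30)
#' w <- beta_spacing_weights(30, 1, 1)
#' permutation_test(x, y, w, variant = "perm-z2", B = 500, seed = 7)
#' @export
permutation_test <- function(x, y = NULL, w = NULL, variant = "perm-z2",
                             rho0 = 0, B = 1000,
                             alternative = c("greater", "less", "two.sided"),
                             seed = NULL) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  if (abs(rho0) >= 1) {
    stop("invalid null: `rho0` must lie in (-1, 1)", call. = FALSE)
  }
  if (B < 99) {
    stop("configuration error: `B` must be at least 99", call. = FALSE)
  }
  sch <- permutation_scheme(variant)
  res <- .with_seed(seed, .perm_core(smp$x, smp$y, smp$w, sch, rho0, B))
  new_wp_test(weighted_pearson(smp), res$obs, NULL,
              .perm_pvalue(res$upper, res$lower, alternative),
              sch$variant, alternative, rho0, smp$n, n_perm = B,
              seed = seed)
}

# All permutations of 1..n as an n! x n matrix (n <= 8).
.permn <- function(v) {
  n <- length(v)
  if (n == 1L) {
    return(matrix(v, 1L, 1L))
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], .permn(v[-i]), deparse.level = 0)
  }))
}

#' Exact (full-enumeration) permutation test
#'
#' Evaluates the permutation distribution over all `n!` permutations of
#' `y` (feasible for `n <= 8`).  The identity permutation is part of the
#' group, so the one-sided p-value `#\{permuted >= observed\}/n!` is at
#' least `1/n!`.
#'
#' @inheritParams permutation_test
#' @return A [`wp_test`][new_wp_test] object with `n_perm = factorial(n)`.
#' @export
exact_permutation_test <- function(x, y = NULL, w = NULL,
                                   variant = "perm-z2", rho0 = 0,
                                   alternative = c("greater", "less",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  if (smp$n > 8L) {
    stop("size error: exact enumeration requires n <= 8, got n = ", smp$n,
         call. = FALSE)
  }
  if (abs(rho0) >= 1) {
    stop("invalid null: `rho0` must lie in (-1, 1)", call. = FALSE)
  }
  sch <- permutation_scheme(variant)
  perms <- .permn(seq_len(smp$n))
  Y <- matrix(smp$y[t(perms)], smp$n, nrow(perms))
  W <- if (sch$weights == "averaged") {
    (smp$w + matrix(smp$w[t(perms)], smp$n, nrow(perms))) / 2
  } else {
    smp$w
  }
  stats <- .wp_stat_cols(smp$x, Y, W, stat_rule = sch$stat,
                         plugin = sch$plugin, rho0 = rho0)
  obs <- .wp_stat_cols(smp$x, matrix(smp$y, ncol = 1), smp$w,
                       stat_rule = sch$stat, plugin = sch$plugin,
                       rho0 = rho0)[1]
  upper <- mean(stats >= obs)
  lower <- mean(stats <= obs)
  new_wp_test(weighted_pearson(smp), obs, NULL,
              .perm_pvalue(upper, lower, alternative),
              sch$variant, alternative, rho0, smp$n,
              n_perm = nrow(perms))
}

#' De-correlation transform for non-zero null correlations
#'
#' Standardizes `x` and `y` to mean zero and unit SD and applies the
#' linear map \eqn{A(\rho_0)} with
#' \eqn{A(\rho) (1\ \rho; \rho\ 1) A(\rho)' = I_2}, i.e.
#' \eqn{U = U'}, \eqn{V = (V' - \rho_0 U')/\sqrt{1 - \rho_0^2}}.  If the
#' sample correlation equals `rho0` the transformed pair is exactly
#' uncorrelated, so a test of `H0: rho = rho0` becomes a zero-null test on
#' `(U, V)`.  Weights are unchanged and stay attached to `U`.
#'
#' By default standardization uses the plain (unweighted) sample mean and
#' SD, under which the downstream de-correlated permutation test holds
#' its nominal level.  `standardize = "weighted"` uses the weighted
#' moments instead, which makes `weighted_pearson(decorrelate(s, rho0 =
#' weighted_pearson(s), standardize = "weighted"))` exactly zero but
#' leaves the downstream test somewhat conservative.
#'
#' @inheritParams asymptotic_test
#' @param standardize `"unweighted"` (default) or `"weighted"` moments
#'   for the standardization step.
#' @return A new [paired_sample] holding the transformed pair.
#' @export
decorrelate <- function(x, y = NULL, w = NULL, rho0,
                        standardize = c("unweighted", "weighted")) {
  standardize <- match.arg(standardize)
  smp <- as_paired_sample(x, y, w)
  if (abs(rho0) >= 1) {
    stop("invalid null: `rho0` must lie in (-1, 1)", call. = FALSE)
  }
  if (standardize == "weighted") {
    ms <- moment_set(smp)
    u <- (smp$x - ms$means[["x"]]) / ms$sds[["x"]]
    v <- (smp$y - ms$means[["y"]]) / ms$sds[["y"]]
  } else {
    u <- (smp$x - mean(smp$x)) / sd(smp$x)
    v <- (smp$y - mean(smp$y)) / sd(smp$y)
  }
  paired_sample(u, (v - rho0 * u) / sqrt(1 - rho0^2), smp$w)
}

#' Test a non-zero null correlation via de-correlation
#'
#' Applies [decorrelate()] at `rho0` and runs the chosen zero-null test on
#' the transformed pair: under `H0: rho = rho0` the transformed correlation
#' tends to zero, so the original hypotheses become
#' `H0: rho(U, V) = 0` versus `H1: rho(U, V) > 0`.
#'
#' @inheritParams permutation_test
#' @param method `"asymptotic"` or a permutation variant label.
#' @return A [`wp_test`][new_wp_test] object; `estimate` is the weighted
#'   correlation of the original sample and `rho0` records the original
#'   null value.
#' @export
test_nonzero <- function(x, y = NULL, w = NULL, rho0,
                         method = "perm-z2", B = 1000,
                         alternative = c("greater", "less", "two.sided"),
                         seed = NULL) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  dec <- decorrelate(smp, rho0 = rho0)
  res <- if (identical(method, "asymptotic")) {
    asymptotic_test(dec, rho0 = 0, alternative = alternative)
  } else {
    permutation_test(dec, variant = method, rho0 = 0, B = B,
                     alternative = alternative, seed = seed)
  }
  res$estimate <- weighted_pearson(smp)
  res$rho0 <- rho0
  res
}

#' Jackknife-variance test (comparator, non-canonical)
#'
#' Delete-one jackknife test for `H0: rho = 0`: for each `i` the
#' observation is dropped, the remaining weights renormalized, and the
#' weighted correlation recomputed; the jackknife variance
#' \eqn{(n-1)/n \sum_i (\hat\rho_{w,(i)} - \bar\rho_{(\cdot)})^2}
#' studentizes \eqn{\hat\rho_w} against a normal reference.  Provided as a
#' comparator; the details (delete-one, weight renormalization, normal
#' reference) are this package's own convention.
#'
#' @inheritParams ttest_weighted
#' @return A [`wp_test`][new_wp_test] object with `method = "jackknife"`.
#' @export
jackknife_test <- function(x, y = NULL, w = NULL,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  smp <- as_paired_sample(x, y, w)
  if (smp$n < 4L) {
    stop("invalid data: jackknife requires n >= 4", call. = FALSE)
  }
  loo <- vapply(seq_len(smp$n), function(i) {
    wi <- smp$w[-i]
    weighted_pearson(smp$x[-i], smp$y[-i], wi / sum(wi))
  }, numeric(1))
  v <- (smp$n - 1) / smp$n * sum((loo - mean(loo))^2)
  # leave-one-out estimates of perfectly correlated data agree to machine
  # precision; treat such variances as exactly zero
  if (v <= 1e-20) {
    stop("degenerate statistic: jackknife variance is zero", call. = FALSE)
  }
  rho <- weighted_pearson(smp)
  stat <- rho / sqrt(v)
  new_wp_test(rho, stat, v, .norm_pvalue(stat, alternative), "jackknife",
              alternative, 0, smp$n)
}
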