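# Deterministic 32-bit hash of a cell label, so per-cell seeds depend only
# on the cell's identity (never on execution order).
.hash32 <- function(s) {
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483647
  as.integer(h)
}

.wp_methods <- c("t-test", "asymptotic", "naive-perm", "perm-1", "perm-2",
                 "perm-ave", "perm-z1", "perm-z2", "jackknife")

# One Monte Carlo cell: fixed (scenario, n); all methods share each
# replicate's data and weights so method comparisons are paired.
# Permutation draws use per-replicate derived seeds (RNG state restored),
# so cell results do not depend on which other methods run.
.wp_cell <- function(scenario, n, methods, weight_scheme, alpha_shape,
                     beta_shape, rho_data, rho_null, alpha, n_reps, n_perm,
                     weight_refresh, alternative, cell_seed) {
  rej <- integer(length(methods))
  names(rej) <- methods
  perm_idx <- which(!(methods %in% c("t-test", "asymptotic", "jackknife")))
  .with_seed(cell_seed, {
    w <- rep.int(1 / n, n)
    for (rep_i in seq_len(n_reps)) {
      if (weight_scheme == "beta" &&
          (rep_i - 1L) %% weight_refresh == 0L) {
        w <- beta_spacing_weights(n, alpha_shape, beta_shape)
      }
      d <- sample_scenario(scenario, n)
      if (rho_data > 0) {
        d <- induce_correlation(d, rho_data, scenario)
      }
      if (weight_scheme == "leverage") {
        w <- leverage_weights(d$x)
      }
      smp <- structure(list(x = d$x, y = d$y, w = w, n = n),
                       class = "paired_sample")
      if (rho_null > 0) {
        smp <- decorrelate(smp, rho0 = rho_null)
      }
      for (m in seq_along(methods)) {
        meth <- methods[m]
        p <- if (meth == "t-test") {
          rho <- weighted_pearson(smp)
          stat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
          switch(alternative,
                 greater = pt(stat, n - 2, lower.tail = FALSE),
                 less = pt(stat, n - 2),
                 two.sided = 2 * pt(abs(stat), n - 2, lower.tail = FALSE))
        } else if (meth == "asymptotic") {
          rho <- weighted_pearson(smp)
          stat <- rho / sqrt(variance_rhohat(smp, rho_plugin = rho))
          .norm_pvalue(stat, alternative)
        } else if (meth == "jackknife") {
          jackknife_test(smp, alternative = alternative)$p.value
        } else {
          sch <- permutation_scheme(meth)
          sd_r <- (cell_seed + rep_i * 1009L + m * 97L) %% 2147483647L
          res <- .with_seed(sd_r,
                            .perm_core(smp$x, smp$y, smp$w, sch, 0, n_perm))
          .perm_pvalue(res$upper, res$lower, alternative)
        }
        if (p <= alpha) rej[m] <- rej[m] + 1L
      }
    }
  })
  rej / n_reps
}

.wp_study <- function(scenarios, n_grid, methods, weight_scheme,
                      alpha_shape, beta_shape, rho_data, rho_null, alpha,
                      n_reps, n_perm, weight_refresh, alternative, seed,
                      verbose) {
  scenarios <- vapply(scenarios, function(s) match.arg(s, wp_scenarios()),
                      character(1), USE.NAMES = FALSE)
  bad <- setdiff(methods, .wp_methods)
  if (length(bad)) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid methods are: ", paste(.wp_methods, collapse = ", "),
         call. = FALSE)
  }
  weight_scheme <- match.arg(weight_scheme, c("beta", "equal", "leverage"))
  rows <- list()
  for (sc in scenarios) {
    for (n in n_grid) {
      cell_seed <- .hash32(paste(seed, sc, n, weight_scheme, alpha_shape,
                                 beta_shape, rho_data, rho_null,
                                 sep = "|"))
      if (verbose) {
        message(sprintf("cell %s n=%d (seed %d): %d reps x %d methods",
                        sc, n, cell_seed, n_reps, length(methods)))
      }
      rate <- .wp_cell(sc, n, methods, weight_scheme, alpha_shape,
                       beta_shape, rho_data, rho_null, alpha, n_reps,
                       n_perm, weight_refresh, alternative, cell_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, n = n, method = methods,
        weight_scheme = weight_scheme, rho_data = rho_data,
        rho0 = rho_null, alternative = alternative, alpha = alpha,
        n_reps = n_reps, n_perm = n_perm,
        rejection_rate = unname(rate),
        mc_se = sqrt(unname(rate) * (1 - unname(rate)) / n_reps),
        cell_seed = cell_seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wp_study", "data.frame")
  out
}

#' Type-I error study for weighted-correlation tests
#'
#' Monte Carlo rejection-rate grid over scenarios, sample sizes and test
#' methods under a true null.  For each cell, `n_reps` datasets are drawn
#' from the scenario; when `rho0 > 0` the data are transformed to
#' correlation `rho0` ([induce_correlation()]) and tested through the
#' de-correlation route ([decorrelate()]), so the null always holds.  With
#' the `"beta"` weight scheme a fresh spacing-weight vector is generated
#' every `weight_refresh` replications; `"leverage"` weights are recomputed
#' from each replicate's `x`; `"equal"` uses `1/n`.  All methods in a cell
#' are evaluated on the same replicates (paired comparison), and every cell
#' is seeded from its own identity, so results are reproducible and
#' independent of cell execution order.
#'
#' @param scenarios Character vector of scenario names ([wp_scenarios()]).
#' @param n_grid Integer vector of sample sizes.
#' @param methods Character vector of method labels among `"t-test"`,
#'   `"asymptotic"`, `"naive-perm"`, `"perm-1"`, `"perm-2"`, `"perm-ave"`,
#'   `"perm-z1"`, `"perm-z2"`, `"jackknife"`.
#' @param weight_scheme `"beta"` (spacing weights), `"equal"`, or
#'   `"leverage"`.
#' @param alpha_shape,beta_shape Beta shape parameters for the spacing
#'   weights (defaults give uniform spacings).
#' @param rho0 Null (and true) correlation; `0` tests the zero null
#'   directly, positive values exercise the de-correlation route.
#' @param alpha Nominal one-sided level (default 0.05).
#' @param n_reps Monte Carlo replications per cell.
#' @param n_perm Permutations per replicate for permutation methods.
#' @param weight_refresh Replications between regenerations of the spacing
#'   weights (default 1000).
#' @param alternative Test direction (default `"greater"`).
#' @param seed Integer master seed; per-cell seeds are derived from it and
#'   the cell identity.
#' @param verbose Print per-cell progress messages.
#' @return A data.frame (class `"wp_study"`) with one row per
#'   (scenario, n, method) cell: rejection rate, its binomial Monte Carlo
#'   standard error `sqrt(r(1-r)/n_reps)`, and the cell configuration.
#' @examples
#' \donttest{
#' type1_error_study("mvn", 20, c("naive-perm", "perm-z2"),
#'                   weight_scheme = "equal", n_reps = 200, n_perm = 199)
#' }
#' @export
type1_error_study <- function(scenarios = wp_scenarios(),
                              n_grid = c(10L, 20L, 50L),
                              methods = "perm-z2",
                              weight_scheme = "beta",
                              alpha_shape = 1, beta_shape = 1,
                              rho0 = 0, alpha = 0.05,
                              n_reps = 2000L, n_perm = 500L,
                              weight_refresh = 1000L,
                              alternative = "greater",
                              seed = 1L, verbose = FALSE) {
  .wp_study(scenarios, n_grid, methods, weight_scheme, alpha_shape,
            beta_shape, rho_data = rho0, rho_null = rho0, alpha, n_reps,
            n_perm, weight_refresh, alternative, seed, verbose)
}

#' Power study for weighted-correlation tests
#'
#' Same machinery as [type1_error_study()] with the data transformed to
#' correlation `rho_true` while the tests are run at null `rho0`; the
#' recorded rejection rates are powers.  With `rho_true == rho0` this
#' reduces to a level study.
#'
#' @inheritParams type1_error_study
#' @param rho_true True correlation induced in the data.
#' @param rho0 Null value tested (default 0).
#' @return A `"wp_study"` data.frame of rejection rates (powers).
#' @export
power_study <- function(scenarios = "mvn", n_grid = c(50L, 100L, 200L),
                        methods = c("asymptotic", "perm-z2"),
                        rho_true, rho0 = 0,
                        weight_scheme = "beta",
                        alpha_shape = 1, beta_shape = 1, alpha = 0.05,
                        n_reps = 2000L, n_perm = 500L,
                        weight_refresh = 1000L, alternative = "greater",
                        seed = 1L, verbose = FALSE) {
  if (rho_true <= rho0) {
    warning("`rho_true` <= `rho0`: expected power at or below the level",
            call. = FALSE)
  }
  .wp_study(scenarios, n_grid, methods, weight_scheme, alpha_shape,
            beta_shape, rho_data = rho_true, rho_null = rho0, alpha,
            n_reps, n_perm, weight_refresh, alternative, seed, verbose)
}

#' @export
plot.wp_study <- function(x, ...) {
  scs <- unique(x$scenario)
  op <- graphics::par(mfrow = c(1, length(scs)))
  on.exit(graphics::par(op))
  for (sc in scs) {
    d <- x[x$scenario == sc, ]
    meths <- unique(d$method)
    graphics::matplot(
      sort(unique(d$n)),
      sapply(meths, function(m) d$rejection_rate[d$method == m][
        order(d$n[d$method == m])]),
      type = "b", pch = seq_along(meths), lty = 1,
      xlab = "n", ylab = "rejection rate", main = sc, ...)
    graphics::abline(h = unique(d$alpha), lty = 2, col = "grey50")
    graphics::legend("topright", legend = meths, pch = seq_along(meths),
                     col = seq_along(meths), bty = "n", cex = 0.8)
  }
  invisible(x)
}
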