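#' Read a weighted paired sample from a delimited text file
#'
#' Reads a CSV (comma-separated, header row, `.` decimal) and builds a
#' validated [paired_sample].  The weight column is optional; when absent,
#' equal weights are used.
#'
#' @param path Path to the CSV file.
#' @param x_col,y_col,w_col Column names for the observations and weights
#'   (defaults `"x"`, `"y"`, `"w"`).
#' @return A [paired_sample].
#' @export
read_paired_csv <- function(path, x_col = "x", y_col = "y", w_col = "w") {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop("input error: cannot parse ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (nrow(df) == 0) {
    stop("input error: ", path, " contains no data rows", call. = FALSE)
  }
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop("input error: missing required column `", col, "` in ", path,
           call. = FALSE)
    }
  }
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop("invalid data: non-numeric or missing value in column `", col,
           "` at row ", bad[1], call. = FALSE)
    }
    v
  }
  w <- if (w_col %in% names(df)) num_col(w_col) else NULL
  paired_sample(num_col(x_col), num_col(y_col), w)
}

#' Run a configured test and emit a flat report
#'
#' Executes one test described by a configuration list and writes a
#' single-row CSV record (method, n, estimate, statistic, variance,
#' p-value, alternative, rho0, n_perm, seed) to standard output and,
#' optionally, to a file.  The effective (post-normalization) weights and
#' seed are reported via `message()` for auditability.
#'
#' @param config A list with elements `input` (CSV path), optional
#'   `x_col`/`y_col`/`w_col`, `method` (see [type1_error_study()] for
#'   labels), and optional `rho0`, `alternative`, `n_perm`, `seed`,
#'   `output`.
#' @return The [`wp_test`][new_wp_test] result, invisibly.
#' @export
run_test_command <- function(config) {
  smp <- read_paired_csv(config$input,
                         x_col = config$x_col %||% "x",
                         y_col = config$y_col %||% "y",
                         w_col = config$w_col %||% "w")
  method <- match.arg(config$method, .wp_methods)
  rho0 <- config$rho0 %||% 0
  alternative <- config$alternative %||% "greater"
  n_perm <- config$n_perm %||% 1000L
  seed <- config$seed
  message(sprintf("n = %d; effective weights: [%s]", smp$n,
                  paste(signif(smp$w, 6), collapse = ", ")))
  if (!is.null(seed)) message("seed: ", seed)
  res <- if (method == "t-test") {
    ttest_weighted(smp, alternative = alternative)
  } else if (method == "jackknife") {
    jackknife_test(smp, alternative = alternative)
  } else if (method == "asymptotic") {
    if (rho0 != 0) {
      test_nonzero(smp, rho0 = rho0, method = "asymptotic",
                   alternative = alternative)
    } else {
      asymptotic_test(smp, rho0 = 0, alternative = alternative)
    }
  } else if (rho0 != 0) {
    test_nonzero(smp, rho0 = rho0, method = method, B = n_perm,
                 alternative = alternative, seed = seed)
  } else {
    permutation_test(smp, variant = method, rho0 = 0, B = n_perm,
                     alternative = alternative, seed = seed)
  }
  rec <- as.data.frame(res)
  out <- textConnection("rec_csv", "w", local = TRUE)
  write.csv(rec, out, row.names = FALSE)
  close(out)
  cat(rec_csv, sep = "\n")
  if (!is.null(config$output)) {
    write.csv(rec, config$output, row.names = FALSE)
  }
  invisible(res)
}

#' Run a simulation study from a YAML configuration
#'
#' Reads a YAML file (or takes an equivalent list) naming scenarios, the
#' sample-size grid, methods and replication settings, runs
#' [type1_error_study()] (or [power_study()] when `rho_true` is given),
#' and writes the tidy rejection-rate grid as CSV.
#'
#' Recognized fields: `scenarios`, `n_grid`, `methods`, `weight_scheme`,
#' `alpha_shape`, `beta_shape`, `rho0`, `rho_true`, `alpha`, `n_reps`,
#' `n_perm`, `weight_refresh`, `alternative`, `seed`.
#'
#' @param config Path to a YAML file, or a configuration list.
#' @param output Optional CSV output path.
#' @param seed Optional integer overriding the configured seed.
#' @return The `"wp_study"` data.frame, invisibly.
#' @export
run_simulate_command <- function(config, output = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  bad_sc <- setdiff(cfg$scenarios %||% "mvn", wp_scenarios())
  if (length(bad_sc)) {
    stop("unknown scenario(s) ", paste(bad_sc, collapse = ", "),
         "; valid scenarios are: ", paste(wp_scenarios(), collapse = ", "),
         call. = FALSE)
  }
  args <- list(
    scenarios = cfg$scenarios %||% "mvn",
    n_grid = cfg$n_grid %||% c(10L, 20L, 50L),
    methods = cfg$methods %||% "perm-z2",
    weight_scheme = cfg$weight_scheme %||% "beta",
    alpha_shape = cfg$alpha_shape %||% 1,
    beta_shape = cfg$beta_shape %||% 1,
    rho0 = cfg$rho0 %||% 0,
    alpha = cfg$alpha %||% 0.05,
    n_reps = cfg$n_reps %||% 2000L,
    n_perm = cfg$n_perm %||% 500L,
    weight_refresh = cfg$weight_refresh %||% 1000L,
    alternative = cfg$alternative %||% "greater",
    seed = seed %||% cfg$seed %||% 1L,
    verbose = TRUE)
  res <- if (!is.null(cfg$rho_true)) {
    do.call(power_study, c(args, list(rho_true = cfg$rho_true)))
  } else {
    do.call(type1_error_study, args)
  }
  if (!is.null(output)) {
    write.csv(res, output, row.names = FALSE)
    message("wrote ", nrow(res), " rows to ", output)
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
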