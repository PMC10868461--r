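#' Construct and validate a weighted paired sample
#'
#' Bundles paired observations with per-observation probability weights and
#' enforces the constraints every estimator and test in this package relies
#' on: equal lengths, finite values, strictly positive weights summing to
#' one, and non-degenerate (non-constant) `x` and `y`.
#'
#' Weights are always renormalized so that `sum(w) == 1` exactly (to within
#' floating point).  When the raw sum deviates from 1 by more than `1e-6`
#' the renormalization is reported with a warning, so frequency-style
#' weights passed by mistake remain visible.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with at least
#'   two distinct values.
#' @param w Optional numeric vector of strictly positive weights.  When
#'   omitted, equal weights `1/n` are used and all estimators reduce to
#'   their classic unweighted forms.
#' @return An object of class `"paired_sample"`: a list with elements `x`,
#'   `y`, `w` (normalized) and `n`.
#' @examples
#' s <- paired_sample(c(1, 2, 4), c(2, 1, 5), w = c(0.2, 0.3, 0.5))
#' weighted_pearson(s)
#' @export
paired_sample <- function(x, y, w = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) {
    stop("invalid data: `x` (length ", n, ") and `y` (length ", length(y),
         ") must have equal length", call. = FALSE)
  }
  if (n < 3L) {
    stop("invalid data: at least 3 paired observations are required, got ",
         n, call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("invalid data: `x` and `y` must be finite (no NA/NaN/Inf)",
         call. = FALSE)
  }
  if (is.null(w)) {
    w <- rep.int(1 / n, n)
  } else {
    w <- as.numeric(w)
    if (length(w) != n) {
      stop("invalid weights: `w` (length ", length(w),
           ") must match `x` (length ", n, ")", call. = FALSE)
    }
    if (!all(is.finite(w))) {
      stop("invalid data: weights must be finite (no NA/NaN/Inf)",
           call. = FALSE)
    }
    if (any(w <= 0)) {
      stop("invalid weights: all weights must be strictly positive",
           call. = FALSE)
    }
    sw <- sum(w)
    if (abs(sw - 1) > 1e-6) {
      warning("weights sum to ", format(sw), "; renormalizing to sum 1",
              call. = FALSE)
    }
    w <- w / sw
  }
  if (min(x) == max(x)) {
    stop("degenerate sample: `x` is constant", call. = FALSE)
  }
  if (min(y) == max(y)) {
    stop("degenerate sample: `y` is constant", call. = FALSE)
  }
  structure(list(x = x, y = y, w = w, n = n), class = "paired_sample")
}

# Accept either a ready-made paired_sample or raw (x, y, w) vectors.
as_paired_sample <- function(x, y = NULL, w = NULL) {
  if (inherits(x, "paired_sample")) {
    return(x)
  }
  if (is.data.frame(x) && is.null(y)) {
    return(paired_sample(x$x, x$y, if ("w" %in% names(x)) x$w else w))
  }
  paired_sample(x, y, w)
}

#' @export
print.paired_sample <- function(x, ...) {
  cat("Weighted paired sample: n =", x$n, "\n")
  eq <- max(abs(x$w - 1 / x$n)) < 1e-12
  cat(if (eq) "  equal weights (1/n)\n" else
    sprintf("  weights in [%.4g, %.4g], sum(w^2) = %.4g\n",
            min(x$w), max(x$w), sum(x$w^2)))
  cat(sprintf("  weighted Pearson correlation: %.4f\n",
              weighted_pearson(x)))
  invisible(x)
}
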