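# Nonparametric statistics shared by every pipeline stage.  These are thin,
# contract-enforcing fronts over the corresponding base-R routines; the
# contracts (exact-mode switch, two-sided tests, average ranks) are the
# package-wide conventions documented here.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples, reporting the
#' U statistic for `x` (number of pairs where `x` precedes `y`).  The exact
#' null distribution is used when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.  The switch can be forced with `mode`.
#'
#' @param x,y Numeric vectors, each of length at least 1.
#' @param mode `"auto"` (default switch described above), `"exact"`, or
#'   `"approx"`.
#' @return A list of class `mw_test` with elements `statistic` (U),
#'   `p_value`, `method` (`"exact"` or `"normal_approximation"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must be non-empty and free of missing values", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
    auto = (n1 + n2 <= 12L) && !ties,
    exact = TRUE,
    approx = FALSE
  )
  if (use_exact && ties) {
    stop("exact mode is not defined in the presence of ties", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate all-tied tiny samples
  structure(
    list(statistic = unname(wt$statistic), p_value = min(p, 1),
         method = if (use_exact) "exact" else "normal_approximation",
         n1 = n1, n2 = n2),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values.  Input values must lie in
#' (0, 1]; the adjusted values are order-preserving and never smaller than
#' the raw ones.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive the mean of the ranks
#' they span).
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' spearman_rho(1:5, c(2, 4, 5, 8, 9))
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation is undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Trapezoidal area under a curve
#'
#' Area of the piecewise-linear curve through `(days, values)`.
#'
#' @param values Numeric vector of curve values.
#' @param days Strictly increasing numeric vector of the same length.
#' @return The trapezoidal area (signed if `values` changes sign).
#' @examples
#' trapezoid_auc(c(0, 1, 0), c(0, 1, 2))
#' @export
trapezoid_auc <- function(values, days) {
  values <- as.numeric(values); days <- as.numeric(days)
  if (length(values) != length(days) || length(days) < 2L) {
    stop("`values` and `days` must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(values) || anyNA(days)) stop("missing values are not allowed", call. = FALSE)
  if (any(diff(days) <= 0)) stop("`days` must be strictly increasing", call. = FALSE)
  n <- length(days)
  sum(0.5 * (values[-1] + values[-n]) * diff(days))
}
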