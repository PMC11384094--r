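#' Normalize condition samples by a reference median
#'
#' Divides every value by the median of the reference condition (the first
#' depicted condition, by convention), so that the reference median maps to
#' 1.0. Applying the function twice is a no-op.
#'
#' @param samples data.frame with columns `condition` and `value`.
#' @param reference Reference condition label; defaults to the first
#'   condition in order of appearance.
#' @return The data.frame with `value` rescaled; attributes `reference` and
#'   `reference_median` record the normalization.
#' @export
normalize_by_reference <- function(samples, reference = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("condition", "value") %in% names(samples)))
  if (is.null(reference)) reference <- as.character(samples$condition[1])
  ref_vals <- samples$value[samples$condition == reference]
  if (!length(ref_vals)) {
    stop("reference condition '", reference, "' not present", call. = FALSE)
  }
  ref_med <- stats::median(ref_vals)
  if (!is.finite(ref_med) || ref_med <= 0) {
    stop("reference median must be positive, got ", ref_med, call. = FALSE)
  }
  samples$value <- samples$value / ref_med
  attr(samples, "reference") <- reference
  attr(samples, "reference_median") <- ref_med
  samples
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For small samples (combined n of at most `exact_max`) the p-value is exact
#' by full enumeration of all group assignments of the ranks (ties handled by
#' average ranks, so the exact path works with tied data). Larger samples use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Combined sample size at or below which the exact
#'   enumeration is used (default 12).
#' @param method `"auto"` (size-based switch), `"exact"` or `"approx"`.
#' @return A `rank_sum_test` list: `statistic` (rank sum of `x`), `p_value`,
#'   `method` ("exact" or "normal-approximation"), `n_x`, `n_y`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L,
                              method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_x <- length(x); n_y <- length(y)
  combined <- c(x, y)
  r <- rank(combined)
  w_obs <- sum(r[seq_len(n_x)])
  if (length(unique(combined)) == 1L) {
    warning("all values identical across both samples; p = 1", call. = FALSE)
    return(structure(list(statistic = w_obs, p_value = 1,
                          method = "degenerate", n_x = n_x, n_y = n_y),
                     class = "rank_sum_test"))
  }
  use_exact <- switch(method,
                      auto = (n_x + n_y) <= exact_max,
                      exact = TRUE, approx = FALSE)
  if (use_exact) {
    sets <- utils::combn(n_x + n_y, n_x)
    w_all <- colSums(matrix(r[sets], nrow = n_x))
    eps <- 1e-9
    p_lo <- mean(w_all <= w_obs + eps)
    p_hi <- mean(w_all >= w_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    meth <- "exact"
  } else {
    # normal approximation with tie correction and continuity correction
    n <- n_x + n_y
    mu <- n_x * (n + 1) / 2
    ties <- table(combined)
    sigma2 <- n_x * n_y / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- w_obs - mu
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    meth <- "normal-approximation"
  }
  structure(list(statistic = w_obs, p_value = p, method = meth,
                 n_x = n_x, n_y = n_y),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s, n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' Pairwise rank-sum tests over conditions with Bonferroni correction
#'
#' All pairwise two-sided Wilcoxon rank-sum comparisons between conditions,
#' adjusted by the number of comparisons actually performed.
#'
#' @param samples data.frame with `condition` and `value` columns.
#' @param ... Passed to [wilcoxon_rank_sum()].
#' @return data.frame `cond_a`, `cond_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `stars`, `method`; attribute `m` records the number of
#'   comparisons.
#' @export
pairwise_rank_sum <- function(samples, ...) {
  conds <- unique(as.character(samples$condition))
  if (length(conds) < 2L) stop("need at least two conditions", call. = FALSE)
  cmb <- utils::combn(conds, 2L, simplify = FALSE)
  rows <- lapply(cmb, function(pr) {
    t <- wilcoxon_rank_sum(samples$value[samples$condition == pr[1]],
                           samples$value[samples$condition == pr[2]], ...)
    data.frame(cond_a = pr[1], cond_b = pr[2], statistic = t$statistic,
               p_raw = t$p_value, method = t$method)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw)
  out$stars <- significance_stars(out$p_adjusted)
  out <- out[, c("cond_a", "cond_b", "statistic", "p_raw", "p_adjusted",
                 "stars", "method")]
  attr(out, "m") <- nrow(out)
  out
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons and caps at 1.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  if (m == length(p_values)) {
    stats::p.adjust(p_values, method = "bonferroni")
  } else {
    pmin(1, p_values * m)
  }
}

#' Significance stars from an adjusted p-value
#'
#' The plotting convention: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, `"ns"` otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Boxplot summary with percentile whiskers
#'
#' The plotting convention used throughout: box at the 25th/75th percentiles,
#' whiskers at the 5th/95th percentiles, median line, and every value outside
#' the whiskers listed as an outlier. Percentiles use linear interpolation
#' between order statistics (R's default quantile type 7). With fewer than 5
#' values the whiskers fall back to the minimum/maximum with a warning.
#'
#' @param values Numeric vector.
#' @return A `boxplot_summary` list: `median`, `q25`, `q75`, `whisker_lo`,
#'   `whisker_hi`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (!n) stop("no values", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  if (n < 5L) {
    warning("fewer than 5 values: whiskers set to min/max", call. = FALSE)
    lo <- min(values); hi <- max(values)
  } else {
    lo <- q[1]; hi <- q[5]
  }
  structure(list(median = q[3], q25 = q[2], q75 = q[4],
                 whisker_lo = lo, whisker_hi = hi,
                 outliers = values[values < lo | values > hi], n = n),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot: median %.4g [%.4g, %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
    x$median, x$q25, x$q75, x$whisker_lo, x$whisker_hi, length(x$outliers)))
  invisible(x)
}
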