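#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums, over all tables with those
#' margins, the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (the
#' probability-mass two-sided rule; alternatives such as doubling the
#' smaller tail give different values). Exact and deterministic for any
#' non-negative integer table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List of class `milksub_test`: `statistic` (sample odds ratio),
#'   `p_value`, `method`, `n` (grand total), `adjustment`.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))$p_value  # 2/252
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    stop("table must be 2x2", call. = FALSE)
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers", call. = FALSE)
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (sum(tab) < 1) stop("grand total must be at least 1", call. = FALSE)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards ties in floating point, as in stats::fisher.test
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_test_result(statistic = or, p_value = min(1, p),
                  method = "Fisher's exact test (two-sided)", n = sum(tab))
}

#' Pearson chi-square test of independence for an r x c table
#'
#' No continuity correction (a uniform rule across table sizes).
#'
#' @param tab r x c matrix of non-negative counts, r, c >= 2, with no
#'   zero row or column margin.
#' @return `milksub_test` list: `statistic`, `df`, `p_value`, `method`, `n`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2x2", call. = FALSE)
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("cells must be non-negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- new_test_result(statistic = unname(res$statistic),
                         p_value = unname(res$p.value),
                         method = "Pearson chi-square test", n = sum(tab))
  out$df <- unname(res$parameter)
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Compares paired baseline/scenario intakes. Zero differences are
#' dropped (Wilcoxon's convention); absolute differences are ranked with
#' midranks for ties. With `m` non-zero differences at most
#' `exact_limit`, the two-sided p-value is exact: the null distribution
#' of the positive-rank sum over all 2^m equiprobable sign assignments is
#' built by convolution, and the probability of a rank sum at least as
#' far from its mean as observed is summed (the distribution is symmetric
#' under sign flips, ties included). Beyond `exact_limit` a normal
#' approximation with the general tie-corrected variance
#' sum(r_i^2)/4 is used, without continuity correction.
#'
#' @param baseline,scenario Equal-length numeric vectors, paired by
#'   position (same child order).
#' @param exact_limit Largest m for which the exact distribution is used
#'   (default 25).
#' @return `milksub_test` list: `statistic` (positive-rank sum V),
#'   `p_value`, `method`, `n` (pairs used after dropping zeros),
#'   `degenerate` flag (TRUE when all differences are zero, p = 1).
#' @examples
#' wilcoxon_signed_rank(1:6, (1:6) + 1)$p_value  # 2/64
#' @export
wilcoxon_signed_rank <- function(baseline, scenario, exact_limit = 25) {
  if (length(baseline) != length(scenario))
    stop("baseline and scenario must have equal length", call. = FALSE)
  if (length(baseline) < 1) stop("need at least one pair", call. = FALSE)
  d <- scenario - baseline
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    out <- new_test_result(statistic = 0, p_value = 1,
                           method = "Wilcoxon signed-rank test", n = 0)
    out$degenerate <- TRUE
    return(out)
  }
  r <- rank(abs(d))                      # midranks for ties
  v <- sum(r[d > 0])
  if (m <= exact_limit) {
    # exact null distribution of 2*V over sign assignments: convolution of
    # (1 + x^(2 r_i))/2; doubling makes midrank halves integral
    w <- as.integer(round(2 * r))
    dist <- numeric(sum(w) + 1)          # index i -> P(2V = i - 1)
    dist[1] <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), dist[seq_len(length(dist) - wi)])
      dist <- (dist + shifted) / 2
    }
    s <- sum(w)                          # 2V ranges over 0..s, symmetric at s/2
    dev <- abs(2 * v - s / 2)
    support_dev <- abs(seq_along(dist) - 1 - s / 2)
    p <- sum(dist[support_dev >= dev - 1e-9])
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  out <- new_test_result(statistic = v, p_value = min(1, p),
                         method = method, n = m)
  out$degenerate <- FALSE
  out
}

#' Bonferroni adjustment with an explicit family size
#'
#' Each p-value is multiplied by the family size `m` and capped at 1.
#' `m` may exceed the number of p-values supplied (a family can include
#' comparisons reported elsewhere).
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param m Family size, `m >= length(p)` and `m >= 1`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p) || m < 1)
    stop("family size m must be >= number of p-values", call. = FALSE)
  pmin(1, m * p)
}

new_test_result <- function(statistic, p_value, method, n,
                            adjustment = "none") {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, adjustment = adjustment), class = "milksub_test")
}

#' @export
print.milksub_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      " p =", format.pval(x$p_value, digits = 4), " n =", x$n, "\n")
  if (!is.null(x$df)) cat("  df =", x$df, "\n")
  if (isTRUE(x$degenerate)) cat("  (all differences zero)\n")
  invisible(x)
}
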