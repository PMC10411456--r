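test_that("Fisher exact p matches the hand-enumerable worked case", {
  res <- fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # identical rows carry no association
  expect_equal(fisher_exact_2x2(matrix(c(3, 7, 3, 7), 2,
                                       byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "integer")
})

test_that("Fisher exact agrees with enumeration and stats::fisher.test", {
  set.seed(11)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square test reproduces hand computations", {
  expect_error(chi_square_test(matrix(c(50, 50, 0, 0), 2)), "margin")

  even <- chi_square_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  diag20 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag20$statistic, 20)
  expect_equal(diag20$df, 1)
  expect_equal(diag20$p_value, pchisq(20, 1, lower.tail = FALSE))

  set.seed(2)
  big <- matrix(rpois(28, 30) + 1, 4, 7)
  expect_equal(chi_square_test(big)$df, 18)
})

test_that("Wilcoxon signed-rank handles the stated conventions", {
  # all differences zero: degenerate, p = 1
  deg <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)

  # 6 all-positive differences, no ties: exact p = 2 / 2^6
  res <- wilcoxon_signed_rank(1:6, (1:6) + (1:6) / 10)
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)
  expect_equal(res$n, 6)

  # zeros are dropped before ranking
  withz <- wilcoxon_signed_rank(c(5, 1:6), c(5, (1:6) + (1:6) / 10))
  expect_equal(withz$p_value, 2 / 64, tolerance = 1e-12)
  expect_equal(withz$n, 6)

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact Wilcoxon agrees with sign-assignment enumeration", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    b <- round(stats::rlnorm(n, 2, 1), 1)
    s <- round(b + stats::rnorm(n, 0.5, 2), 1)  # ties and zeros likely
    p <- wilcoxon_signed_rank(b, s)$p_value
    expect_equal(p, wilcoxon_oracle(b, s), tolerance = 1e-12)
  }
})

test_that("tie-free exact Wilcoxon matches stats::wilcox.test", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(5:15, 1)
    d <- stats::rnorm(n)
    b <- stats::rlnorm(n)
    s <- b + d
    if (anyDuplicated(abs(d)) || any(d == 0)) next
    expect_equal(wilcoxon_signed_rank(b, s)$p_value,
                 stats::wilcox.test(s, b, paired = TRUE,
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon path uses the tie-corrected normal", {
  set.seed(17)
  n <- 200
  b <- stats::rlnorm(n)
  s <- b * stats::rlnorm(n, 0.05, 0.3)
  res <- wilcoxon_signed_rank(b, s)
  expect_match(res$method, "normal")
  # against wilcox.test without continuity correction
  ref <- stats::wilcox.test(s, b, paired = TRUE, exact = FALSE,
                            correct = FALSE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)
  # the switch point is configurable
  exact_res <- wilcoxon_signed_rank(b[1:20], s[1:20], exact_limit = 25)
  expect_match(exact_res$method, "exact")
})

test_that("Bonferroni adjustment is capped, ordered and validated", {
  expect_equal(bonferroni_adjust(0.01, m = 7), 0.07)
  expect_equal(bonferroni_adjust(0.5, m = 7), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.4)), c(0.4, 0.8))
  p <- c(0.001, 0.01, 0.04, 0.3)
  adj <- bonferroni_adjust(p, m = 6)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj) >= 0))
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "family size")
})

test_that("Fisher test keeps its size under a null simulation", {
  set.seed(29)
  n_rep <- 2000
  reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x1 <- rbinom(1, 40, 0.3)
    x2 <- rbinom(1, 40, 0.3)
    tab <- matrix(c(x1, 40 - x1, x2, 40 - x2), 2, byrow = TRUE)
    reject[i] <- fisher_exact_2x2(tab)$p_value < 0.05
  }
  expect_lte(mean(reject), 0.06)
})
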