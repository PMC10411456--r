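# shared in-code fixtures for the test suite

# minimal composition table: two plain foods, one milk of each type
tiny_composition <- function() {
  composition_table(data.frame(
    food_id = c("rice", "egg", "scm", "gum1", "gum3", "cowmilk"),
    name = c("rice", "egg", "condensed as consumed", "ycm 1+", "ycm 3+",
             "cow's milk"),
    basis = c("per_100_g", "per_100_g", rep("per_100_mL", 4)),
    density_g_per_mL = c(NA, NA, 1.07, 1.03, 1.03, 1.03),
    milk_type = c("none", "none", "condensed", "ycm", "ycm", "cow"),
    ycm_ageband = c("", "", "", "1plus", "3plus", ""),
    energy_kcal = c(130, 155, 70, 67, 75, 61),
    protein_g = c(2.7, 13, 1.7, 2.2, 2.5, 3.2),
    vita_ug = c(0, 149, 22, 84, 105, 28),
    vitc_mg = c(0, 0, 0.5, 10, 10, 0),
    vitd_ug = c(0, 2.2, 0.03, 2.2, 3.0, 0.03),
    folate_ug = c(2, 47, 3, 23, 30, 5),
    calcium_mg = c(10, 56, 80, 151, 164, 113),
    iron_mg = c(0.4, 1.8, 0.07, 1.03, 1.95, 0.03),
    zinc_mg = c(0.6, 1.3, 0.3, 0.9, 1.3, 0.4),
    stringsAsFactors = FALSE))
}

recall_df <- function(child_id, food_id, amount) {
  data.frame(child_id = child_id, food_id = food_id, amount = amount,
             stringsAsFactors = FALSE)
}

# random recall lines over the tiny composition table for n children
random_recall <- function(n_children, table = tiny_composition(),
                          max_lines = 5) {
  rows <- lapply(seq_len(n_children), function(i) {
    k <- sample.int(max_lines, 1)
    recall_df(sprintf("k%03d", i),
              sample(table$food_id, k, replace = TRUE),
              round(stats::runif(k, 0, 300), 2))
  })
  do.call(rbind, rows)
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins from binomial coefficients (independent of dhyper)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# brute-force exact Wilcoxon signed-rank p: enumerate all 2^m sign vectors
wilcoxon_oracle <- function(baseline, scenario) {
  d <- scenario - baseline
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  s <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - s / 2) >= abs(v_obs - s / 2) - 1e-9)
}
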