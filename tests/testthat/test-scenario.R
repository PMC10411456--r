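test_that("equal-volume substitution swaps the milk line at equal mL", {
  tab <- tiny_composition()
  spec <- scenario_spec("equal_volume", replacement_ids =
                          c("12_35" = "gum1", "36_60" = "gum3"))
  rec <- recall_df("a", c("rice", "scm"), c(120, 100))
  out <- substitute_recall(rec, tab, spec, age_months = c(a = 20))
  expect_equal(out$food_id, c("rice", "gum1"))
  expect_equal(out$amount, c(120, 100))
  # older child gets the 3+ product
  out3 <- substitute_recall(rec, tab, spec, age_months = c(a = 50))
  expect_equal(out3$food_id, c("rice", "gum3"))
})

test_that("isocaloric substitution preserves each line's energy", {
  tab <- tiny_composition()
  # make the target exactly twice the replacement energy density
  tab$energy_kcal[tab$food_id == "scm"] <- 134
  spec <- scenario_spec("isocaloric", replacement_ids =
                          c("12_35" = "gum1", "36_60" = "gum3"))
  rec <- recall_df("a", "scm", 100)
  out <- substitute_recall(rec, tab, spec, age_months = c(a = 20))
  expect_equal(out$amount, 200)

  tab0 <- tab
  tab0$energy_kcal[tab0$food_id == "gum1"] <- 0
  expect_error(substitute_recall(rec, tab0, spec, c(a = 20)),
               "positive")
})

test_that("children without target milk pass through unchanged", {
  tab <- tiny_composition()
  spec <- scenario_spec("equal_volume", replacement_ids =
                          c("12_35" = "gum1", "36_60" = "gum3"))
  rec <- recall_df(c("a", "a", "b"), c("rice", "cowmilk", "gum1"),
                   c(100, 150, 200))
  out <- substitute_recall(rec, tab, spec,
                           age_months = c(a = 20, b = 40))
  expect_identical(out, rec)
})

test_that("self-substitution is the identity under both modes", {
  tab <- tiny_composition()
  rec <- recall_df("a", c("rice", "scm"), c(120, 87.5))
  for (mode in c("equal_volume", "isocaloric")) {
    spec <- scenario_spec(mode, replacement_ids =
                            c("12_35" = "scm", "36_60" = "scm"))
    out <- substitute_recall(rec, tab, spec, c(a = 30))
    expect_equal(compute_intake(out, tab), compute_intake(rec, tab))
  }
})

test_that("conservation laws hold per child on random populations", {
  tab <- tiny_composition()
  set.seed(19)
  rec <- random_recall(60, tab)
  ids <- sprintf("k%03d", 1:60)
  ages <- setNames(sample(12:60, 60, replace = TRUE), ids)
  iso <- scenario_spec("isocaloric", replacement_ids =
                         c("12_35" = "gum1", "36_60" = "gum3"))
  vol <- scenario_spec("equal_volume", replacement_ids =
                         c("12_35" = "gum1", "36_60" = "gum3"))
  base <- compute_intakes(rec, tab, ids)
  out_iso <- compute_intakes(substitute_recall(rec, tab, iso, ages), tab, ids)
  expect_equal(out_iso$energy_kcal, base$energy_kcal, tolerance = 1e-9)

  # equal volume: total consumed milk volume unchanged
  milk_volume <- function(r) {
    idx <- match(r$food_id, tab$food_id)
    milk <- tab$milk_type[idx] != "none"
    amt <- r$amount
    g_basis <- tab$basis[idx] == "per_100_g"
    amt[g_basis] <- amt[g_basis] / tab$density_g_per_mL[idx][g_basis]
    tapply(amt[milk], r$child_id[milk], sum)
  }
  out_vol <- substitute_recall(rec, tab, vol, ages)
  v0 <- milk_volume(rec)
  v1 <- milk_volume(out_vol)
  expect_equal(v1[names(v0)], v0, tolerance = 1e-12)
})

test_that("a componentwise-denser replacement never lowers any intake", {
  tab <- tiny_composition()
  # force full componentwise domination of the target by the replacements
  tab$energy_kcal[tab$food_id == "scm"] <- 60
  for (id in c("gum1", "gum3"))
    expect_true(all(tab[tab$food_id == id, NUTRIENT_COLS] >=
                      tab[tab$food_id == "scm", NUTRIENT_COLS] - 1e-12))
  set.seed(23)
  rec <- random_recall(50, tab)
  ids <- unique(rec$child_id)
  ages <- setNames(sample(12:60, length(ids), replace = TRUE), ids)
  vol <- scenario_spec("equal_volume", replacement_ids =
                         c("12_35" = "gum1", "36_60" = "gum3"))
  base <- compute_intakes(rec, tab, ids)
  out <- compute_intakes(substitute_recall(rec, tab, vol, ages), tab, ids)
  for (col in NUTRIENT_COLS)
    expect_true(all(out[[col]] >= base[[col]] - 1e-9))
})

test_that("summary statistics follow the documented conventions", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$p50, 3)
  expect_equal(s$sd, sd(1:5))

  s1 <- summarize_distribution(7)
  expect_equal(s1$mean, 7)
  expect_equal(s1$sd, 0)

  s2 <- summarize_distribution(c(0, 0, 0, 10))
  expect_equal(s2$p25, 0)
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$p50, 0)
  expect_equal(s2$p75, 2.5)

  expect_error(summarize_distribution(numeric()), "empty")
})

test_that("relative reduction uses round-half-up integer percent", {
  rr <- relative_reduction(84, 58)
  expect_equal(rr$value, 100 * 26 / 84)
  expect_equal(rr$rounded, 31)
  expect_equal(relative_reduction(80, 60)$rounded, 25)
  expect_equal(relative_reduction(100, 77.5)$rounded, 23)  # half rounds up
  expect_error(relative_reduction(0, 0), "undefined")
})

test_that("run_scenario pairs children and fills a full comparison row", {
  tab <- tiny_composition()
  set.seed(41)
  n <- 80
  ids <- sprintf("k%03d", 1:n)
  ages <- sample(12:60, n, replace = TRUE)
  pop <- data.frame(child_id = ids, age_months = ages)
  rec <- rbind(recall_df(ids, "rice", runif(n, 50, 400)),
               recall_df(ids[1:50], "scm", runif(50, 50, 300)),
               recall_df(ids[51:60], "cowmilk", runif(10, 100, 200)))
  spec <- scenario_spec("equal_volume", replacement_ids =
                          c("12_35" = "gum1", "36_60" = "gum3"))
  refs <- default_reference_values()
  out <- run_scenario(rec, tab, pop, spec, refs)
  expect_s3_class(out, "scenario_comparison")
  # only condensed consumers enter; both modeling groups covered
  expect_equal(sum(out$n[!duplicated(out$age_group)]), 50)
  expect_true(all(out$baseline_prevalence >= 0 &
                    out$baseline_prevalence <= 100))
  expect_true(all(out$scenario_prevalence <= out$baseline_prevalence))
  expect_true(all(out$p_distribution >= 0 & out$p_distribution <= 1))
  expect_true(all(out$p_prevalence >= 0 & out$p_prevalence <= 1))

  # no condensed consumers -> empty comparison set
  rec2 <- recall_df(ids, "rice", 100)
  expect_equal(nrow(run_scenario(rec2, tab, pop, spec, refs)), 0)
})
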