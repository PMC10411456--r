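#' Specify a milk substitution scenario
#'
#' A scenario replaces every recall line of one milk type (the target,
#' condensed milk in the motivating analysis) by a replacement product
#' chosen by the child's modeling age group: a young-child milk "1+"
#' formulation for 12-35 months and "3+" for 36-60 months.
#'
#' Two modes are supported. `equal_volume` keeps the consumed volume:
#' the replacement amount in mL equals the original amount in mL.
#' `isocaloric` keeps the consumed energy: the replacement amount is the
#' original amount times the ratio of energy densities (target kcal per
#' 100 mL over replacement kcal per 100 mL), so each replaced line
#' supplies exactly the energy it did before.
#'
#' @param mode `"equal_volume"` or `"isocaloric"`.
#' @param target_milk Milk type being replaced (default `"condensed"`).
#' @param replacement_ids Named character vector mapping modeling groups
#'   to replacement `food_id`s, e.g. `c("12_35" = "YCM1", "36_60" = "YCM3")`.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("equal_volume", "isocaloric"),
                          target_milk = "condensed",
                          replacement_ids = c("12_35" = "YCM1",
                                              "36_60" = "YCM3")) {
  mode <- match.arg(mode)
  target_milk <- match.arg(target_milk, setdiff(MILK_TYPES, "none"))
  if (!all(c("12_35", "36_60") %in% names(replacement_ids)))
    stop("replacement_ids must name groups '12_35' and '36_60'",
         call. = FALSE)
  structure(list(mode = mode, target_milk = target_milk,
                 replacement_ids = replacement_ids),
            class = "scenario_spec")
}

# one-row per-100-mL entry for a food, converting basis if needed
entry_per_100_mL <- function(table, food_id) {
  row <- table[table$food_id == food_id, , drop = FALSE]
  if (nrow(row) != 1)
    stop("food_id '", food_id, "' not found in composition table",
         call. = FALSE)
  convert_basis(row, "per_100_mL")
}

#' Apply a substitution scenario to recall lines
#'
#' Every line whose food has the target milk type is replaced by a line
#' of the age-appropriate replacement product; all other lines pass
#' through unchanged, and children without target-milk lines are
#' returned unchanged. Amounts are handled on a millilitre basis
#' (lines for per-100-g target foods are converted through the food's
#' density). Substitution is applied per line, which is equivalent for
#' daily totals because intake computation is linear.
#'
#' @param lines Recall data frame `child_id, food_id, amount` (one or
#'   many children).
#' @param table Composition data frame.
#' @param spec A [scenario_spec()].
#' @param age_months Ages of the children in `lines`: either a single
#'   value or a named vector indexed by `child_id`.
#' @return Recall data frame of the same shape with target lines
#'   replaced.
#' @export
substitute_recall <- function(lines, table, spec, age_months) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (nrow(lines) == 0) return(lines)
  idx <- check_recall_lines(lines, table)
  is_target <- table$milk_type[idx] == spec$target_milk
  if (!any(is_target)) return(lines)

  if (length(age_months) == 1) {
    age <- rep(age_months, nrow(lines))
  } else {
    age <- age_months[as.character(lines$child_id)]
    if (anyNA(age))
      stop("age_months must cover every child_id in lines", call. = FALSE)
  }
  group <- modeling_group(age)

  out <- lines
  for (g in unique(group[is_target])) {
    sel <- is_target & group == g
    repl <- entry_per_100_mL(table, spec$replacement_ids[[g]])
    # original amounts on a mL basis
    amt <- lines$amount[sel]
    basis <- table$basis[idx[sel]]
    if (any(basis == "per_100_g")) {
      d <- table$density_g_per_mL[idx[sel]]
      if (any(basis == "per_100_g" & (!is.finite(d) | d <= 0)))
        stop("density required to express target-milk amounts in mL",
             call. = FALSE)
      amt <- ifelse(basis == "per_100_g", amt / d, amt)
    }
    if (spec$mode == "isocaloric") {
      if (repl$energy_kcal <= 0)
        stop("isocaloric substitution needs a replacement with positive ",
             "energy density", call. = FALSE)
      e_target <- sapply(unique(idx[sel]), function(i)
        convert_basis(table[i, , drop = FALSE], "per_100_mL")$energy_kcal)
      names(e_target) <- table$food_id[unique(idx[sel])]
      amt <- amt * e_target[as.character(lines$food_id[sel])] /
        repl$energy_kcal
    }
    out$food_id[sel] <- repl$food_id
    out$amount[sel] <- amt
  }
  out
}

#' Summary statistics of an intake distribution
#'
#' Mean, sample standard deviation (n - 1 denominator; 0 for a single
#' value), and the 25th, 50th and 75th percentiles by linear
#' interpolation between order statistics (R quantile type 7). The rule
#' is fixed so summaries are reproducible.
#'
#' @param values Non-empty numeric vector.
#' @return Named list `mean, sd, p25, p50, p75`.
#' @export
summarize_distribution <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mean(values),
       sd = if (length(values) == 1) 0 else stats::sd(values),
       p25 = q[1], p50 = q[2], p75 = q[3])
}

#' Relative reduction of a prevalence, in percent
#'
#' `100 * (baseline - scenario) / baseline`. The rounded form uses
#' round-half-up to an integer percent (so 30.95 reports as 31).
#'
#' @param baseline,scenario Prevalences in percent, baseline > 0.
#' @return List `value` (unrounded percent) and `rounded` (integer
#'   percent, half-up).
#' @export
relative_reduction <- function(baseline, scenario) {
  if (any(baseline <= 0))
    stop("relative reduction undefined for baseline prevalence 0",
         call. = FALSE)
  value <- 100 * (baseline - scenario) / baseline
  list(value = value, rounded = round_half_up(value))
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Run one substitution scenario over a population
#'
#' Restricts to the target-milk consumer group, applies the scenario,
#' recomputes intakes, and builds one comparison row per nutrient per
#' modeling age group: baseline and scenario summary statistics,
#' EAR cut-point prevalences, the paired Wilcoxon signed-rank p-value
#' for the intake-distribution shift (`p_distribution`), Fisher's exact
#' p-value comparing the two prevalences (`p_prevalence`), and the
#' relative prevalence reduction. Baseline and scenario intakes are
#' paired: same children, same order, as the signed-rank test requires.
#'
#' @param recall Recall data frame for the whole population.
#' @param table Composition data frame.
#' @param population Data frame `child_id, age_months` (extra columns
#'   kept but unused).
#' @param spec A [scenario_spec()].
#' @param refs Reference data frame (see [reference_values]).
#' @param nutrients Nutrient columns to evaluate; defaults to the
#'   micronutrients present in `refs`.
#' @return Data frame of class `scenario_comparison`, one row per
#'   (nutrient, modeling group); empty (zero rows) if no child consumes
#'   the target milk.
#' @export
run_scenario <- function(recall, table, population, spec, refs,
                         nutrients = intersect(MICRONUTRIENTS,
                                               unique(refs$nutrient))) {
  stopifnot(inherits(spec, "scenario_spec"),
            all(c("child_id", "age_months") %in% names(population)))
  population$child_id <- as.character(population$child_id)
  groups <- classify_population(recall, table, population$child_id)
  target_ids <- groups$child_id[groups$milk_group == spec$target_milk]
  empty <- scenario_comparison_frame()
  if (!length(target_ids)) return(empty)

  pop <- population[population$child_id %in% target_ids, , drop = FALSE]
  rec <- recall[as.character(recall$child_id) %in% target_ids, , drop = FALSE]
  ages <- stats::setNames(pop$age_months, pop$child_id)

  base_int <- compute_intakes(rec, table, pop$child_id)
  sub_rec <- substitute_recall(rec, table, spec, ages)
  scen_int <- compute_intakes(sub_rec, table, pop$child_id)

  base_int$age_months <- pop$age_months
  scen_int$age_months <- pop$age_months
  mg <- modeling_group(pop$age_months)

  rows <- list()
  for (g in c("12_35", "36_60")) {
    sel <- mg == g
    if (!any(sel)) next
    for (nut in nutrients) {
      b <- base_int[sel, , drop = FALSE]
      s <- scen_int[sel, , drop = FALSE]
      sb <- summarize_distribution(b[[nut]])
      ss <- summarize_distribution(s[[nut]])
      pb <- prevalence_below_reference(b, nut, refs)
      ps <- prevalence_below_reference(s, nut, refs)
      p1 <- wilcoxon_signed_rank(b[[nut]], s[[nut]])$p_value
      p2 <- fisher_exact_2x2(matrix(c(pb$count, pb$n - pb$count,
                                      ps$count, ps$n - ps$count),
                                    2, byrow = TRUE))$p_value
      rr <- if (pb$prevalence > 0)
        relative_reduction(pb$prevalence, ps$prevalence) else
          list(value = NA_real_, rounded = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        nutrient = nut, age_group = g, mode = spec$mode, n = sum(sel),
        baseline_mean = sb$mean, baseline_sd = sb$sd, baseline_p25 = sb$p25,
        baseline_p50 = sb$p50, baseline_p75 = sb$p75,
        scenario_mean = ss$mean, scenario_sd = ss$sd, scenario_p25 = ss$p25,
        scenario_p50 = ss$p50, scenario_p75 = ss$p75,
        baseline_prevalence = pb$prevalence,
        scenario_prevalence = ps$prevalence,
        p_distribution = p1, p_prevalence = p2,
        relative_reduction = rr$value,
        relative_reduction_rounded = rr$rounded,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

scenario_comparison_frame <- function() {
  out <- data.frame(
    nutrient = character(), age_group = character(), mode = character(),
    n = integer(),
    baseline_mean = numeric(), baseline_sd = numeric(),
    baseline_p25 = numeric(), baseline_p50 = numeric(),
    baseline_p75 = numeric(),
    scenario_mean = numeric(), scenario_sd = numeric(),
    scenario_p25 = numeric(), scenario_p50 = numeric(),
    scenario_p75 = numeric(),
    baseline_prevalence = numeric(), scenario_prevalence = numeric(),
    p_distribution = numeric(), p_prevalence = numeric(),
    relative_reduction = numeric(), relative_reduction_rounded = numeric(),
    stringsAsFactors = FALSE)
  class(out) <- c("scenario_comparison", "data.frame")
  out
}
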