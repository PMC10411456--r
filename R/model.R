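#' Fit a milk-substitution diet model
#'
#' The package's central interface. Given a population's recall lines, a
#' composition table and EAR reference values, this classifies children
#' into milk-consumer groups, restricts to consumers of the target milk,
#' and evaluates the substitution of that milk by a replacement product
#' under both the equal-volume and the isocaloric scenario, per nutrient
#' and modeling age group (12-35 and 36-60 months). Each comparison row
#' pairs baseline and scenario intakes child by child and carries summary
#' statistics, EAR cut-point inadequacy prevalences, the Wilcoxon
#' signed-rank p-value for the distribution shift, Fisher's exact
#' p-value for the prevalence change, and the relative prevalence
#' reduction.
#'
#' @param recall Recall data frame `child_id, food_id, amount`.
#' @param composition Composition data frame ([composition_table()]).
#' @param population Data frame `child_id, age_months` (+ optional
#'   covariates).
#' @param refs Reference values (default bundled EAR table).
#' @param target_milk Milk type to replace (default `"condensed"`).
#' @param replacement_ids Replacement product per modeling group
#'   (default young-child milk 1+/3+).
#' @param modes Scenario modes to run (default both).
#' @return Object of class `milk_substitution`: list with `comparisons`
#'   (a [run_scenario()] data frame stacked over modes), `n_target`
#'   (target-milk consumers per modeling group), and the call inputs.
#' @examples
#' cfg <- population_config(n_children = 300, seed = 42)
#' svy <- simulate_survey(cfg)
#' fit <- milk_substitution(svy$recall, default_composition(),
#'                          svy$population)
#' summary(fit)
#' @export
milk_substitution <- function(recall, composition, population,
                              refs = default_reference_values(),
                              target_milk = "condensed",
                              replacement_ids = c("12_35" = "YCM1",
                                                  "36_60" = "YCM3"),
                              modes = c("equal_volume", "isocaloric")) {
  composition <- composition_table(composition)
  comps <- list()
  for (mode in modes) {
    spec <- scenario_spec(mode, target_milk, replacement_ids)
    comps[[mode]] <- run_scenario(recall, composition, population, spec,
                                  refs)
  }
  comparisons <- do.call(rbind, comps)
  rownames(comparisons) <- NULL
  groups <- classify_population(recall, composition,
                                as.character(population$child_id))
  target <- population[groups$milk_group == target_milk, , drop = FALSE]
  n_target <- table(factor(modeling_group(target$age_months),
                           levels = c("12_35", "36_60")))
  structure(list(comparisons = comparisons,
                 n_target = n_target,
                 target_milk = target_milk,
                 replacement_ids = replacement_ids,
                 modes = modes,
                 refs = refs),
            class = "milk_substitution")
}

#' @export
print.milk_substitution <- function(x, ...) {
  cat("Milk substitution diet model\n")
  cat("  target milk:", x$target_milk, "-> replacement:",
      paste(names(x$replacement_ids), x$replacement_ids, sep = "=",
            collapse = ", "), "\n")
  cat("  consumers: ", paste(names(x$n_target), as.integer(x$n_target),
                             sep = " months n=", collapse = "; "), "\n")
  cat("  scenarios:", paste(x$modes, collapse = ", "), "\n")
  cat("  comparisons:", nrow(x$comparisons), "nutrient x age-group rows\n")
  invisible(x)
}

#' @export
summary.milk_substitution <- function(object, digits = 1, ...) {
  cc <- object$comparisons
  if (!nrow(cc)) {
    cat("No consumers of the target milk; nothing to compare.\n")
    return(invisible(object))
  }
  for (g in unique(cc$age_group)) {
    cat(sprintf("Modeling group %s months (n = %d %s consumers)\n",
                sub("_", "-", g), cc$n[cc$age_group == g][1],
                object$target_milk))
    sub <- cc[cc$age_group == g, ]
    tabl <- data.frame(
      nutrient = sub$nutrient, mode = sub$mode,
      baseline_prev = round(sub$baseline_prevalence, digits),
      scenario_prev = round(sub$scenario_prevalence, digits),
      rel_reduction = round(sub$relative_reduction, digits),
      p_distribution = signif(sub$p_distribution, 2),
      p_prevalence = signif(sub$p_prevalence, 2))
    print(tabl, row.names = FALSE)
    cat("\n")
  }
  invisible(object)
}

#' @export
as.data.frame.milk_substitution <- function(x, ...) {
  as.data.frame(x$comparisons)
}

#' @export
coef.milk_substitution <- function(object, ...) {
  cc <- object$comparisons
  stats::setNames(cc$relative_reduction,
                  paste(cc$nutrient, cc$age_group, cc$mode, sep = "."))
}

#' Plot inadequacy prevalences before and after substitution
#'
#' Grouped bar chart of baseline vs scenario prevalence per nutrient,
#' one panel per modeling age group, for one scenario mode.
#'
#' @param x A `milk_substitution` fit.
#' @param mode Which scenario mode to show (default first fitted).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.milk_substitution <- function(x, mode = x$modes[1], ...) {
  cc <- x$comparisons[x$comparisons$mode == mode, , drop = FALSE]
  if (!nrow(cc)) {
    warning("no comparisons to plot")
    return(invisible(x))
  }
  groups <- unique(cc$age_group)
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  for (g in groups) {
    sub <- cc[cc$age_group == g, ]
    h <- rbind(baseline = sub$baseline_prevalence,
               scenario = sub$scenario_prevalence)
    colnames(h) <- sub("_[a-z]+$", "", sub$nutrient)
    graphics::barplot(h, beside = TRUE, ylim = c(0, 100),
                      legend.text = rownames(h),
                      main = paste(sub("_", "-", g), "months,", mode),
                      ylab = "% below reference value", ...)
  }
  invisible(x)
}
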