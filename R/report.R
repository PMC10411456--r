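#' Build the survey report bundle
#'
#' Assembles the descriptive and analytic tables of a survey analysis:
#' population characteristics, characteristics by milk-consumer group
#' with chi-square p-values, inadequacy prevalence by group, nutrient
#' and age band with Fisher's exact comparisons against the
#' young-child-milk reference group (Bonferroni-adjusted within the
#' stated family), and the substitution-scenario comparisons. All
#' numbers are also collected into one machine-readable list that
#' serialises to JSON, so every reported figure is re-derivable.
#'
#' @param population Data frame with covariates, `age_months` and
#'   `milk_group`.
#' @param intakes Data frame from [compute_intakes()] (same children).
#' @param fit A [milk_substitution()] object (or NULL to skip).
#' @param refs Reference values.
#' @param bonferroni_m Family size for the group-comparison adjustment
#'   (default 2: the two comparator groups per nutrient per age band).
#' @return List of class `milksub_report` with elements
#'   `characteristics`, `characteristics_by_group`, `adequacy_by_group`,
#'   `comparisons`.
#' @export
build_report <- function(population, intakes, fit = NULL,
                         refs = default_reference_values(),
                         bonferroni_m = 2) {
  stopifnot(all(c("age_months", "milk_group") %in% names(population)))
  if (!identical(as.character(population$child_id),
                 as.character(intakes$child_id)))
    stop("population and intakes must list the same children in the same ",
         "order", call. = FALSE)

  characteristics <- do.call(rbind, lapply(
    c("region", "sex", "ses", "mother_education"), function(v) {
      if (!v %in% names(population)) return(NULL)
      tt <- table(population[[v]])
      data.frame(variable = v, level = names(tt), n = as.integer(tt),
                 percent = 100 * as.integer(tt) / nrow(population),
                 stringsAsFactors = FALSE)
    }))
  bands <- table(age_band(population$age_months))
  characteristics <- rbind(characteristics, data.frame(
    variable = "age_band", level = names(bands), n = as.integer(bands),
    percent = 100 * as.integer(bands) / nrow(population),
    stringsAsFactors = FALSE))

  grp <- factor(population$milk_group, levels = MILK_GROUPS)
  by_group <- do.call(rbind, lapply(
    c("sex", "region", "ses", "mother_education"), function(v) {
      if (!v %in% names(population)) return(NULL)
      tab <- table(population[[v]], grp)
      p <- tryCatch(chi_square_test(tab)$p_value, error = function(e) NA_real_)
      pct <- 100 * prop.table(tab, margin = 2)
      out <- as.data.frame.matrix(pct)
      cbind(data.frame(variable = v, level = rownames(out),
                       stringsAsFactors = FALSE),
            out, data.frame(chisq_p = p), row.names = NULL)
    }))

  adequacy <- adequacy_by_group(population, intakes, refs, bonferroni_m)

  out <- list(characteristics = characteristics,
              characteristics_by_group = by_group,
              adequacy_by_group = adequacy,
              comparisons = if (is.null(fit)) NULL else fit$comparisons)
  class(out) <- "milksub_report"
  out
}

# inadequacy % per (age band, nutrient, milk group) with Fisher exact
# comparisons of each non-reference group against the ycm reference group
adequacy_by_group <- function(population, intakes, refs, bonferroni_m) {
  nutrients <- intersect(MICRONUTRIENTS, unique(refs$nutrient))
  dat <- cbind(intakes,
               age_band = as.character(age_band(population$age_months)),
               milk_group = population$milk_group)
  dat$age_months <- population$age_months
  rows <- list()
  for (band in sort(unique(dat$age_band))) {
    for (nut in nutrients) {
      ref_grp <- dat[dat$age_band == band & dat$milk_group == "ycm", ]
      for (g in MILK_GROUPS) {
        sub <- dat[dat$age_band == band & dat$milk_group == g, ]
        if (!nrow(sub)) next
        pr <- prevalence_below_reference(sub, nut, refs)
        p_raw <- p_adj <- NA_real_
        if (g %in% c("condensed", "cow", "non_milk") && nrow(ref_grp)) {
          pr_ref <- prevalence_below_reference(ref_grp, nut, refs)
          p_raw <- fisher_exact_2x2(matrix(
            c(pr$count, pr$n - pr$count,
              pr_ref$count, pr_ref$n - pr_ref$count), 2,
            byrow = TRUE))$p_value
          p_adj <- bonferroni_adjust(p_raw, bonferroni_m)
        }
        rows[[length(rows) + 1]] <- data.frame(
          age_band = band, nutrient = nut, milk_group = g, n = pr$n,
          prevalence = pr$prevalence, fisher_p = p_raw,
          fisher_p_bonferroni = p_adj, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.milksub_report <- function(x, ...) {
  cat("Survey report bundle:\n")
  for (nm in names(x))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-26s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table plus `report.json` holding every number; the JSON
#' round-trips through [jsonlite::fromJSON()] to identical values.
#'
#' @param report A `milksub_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "milksub_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       jp, digits = NA, dataframe = "columns")
  invisible(c(paths, jp))
}

#' Read a population configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file holding the components of
#'   [population_config()].
#' @return Validated `population_config`.
#' @export
read_population_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path)
  as_matrix <- function(x) {
    m <- do.call(rbind, lapply(x, unlist))
    rownames(m) <- names(x)
    m
  }
  population_config(
    n_children = raw$n_children, seed = raw$seed,
    age_probs = unlist(raw$age_probs),
    covariate_probs = lapply(raw$covariate_probs, unlist),
    milk_group_probs = as_matrix(raw$milk_group_probs),
    intake_model = as.data.frame(raw$intake_model,
                                 stringsAsFactors = FALSE),
    milk_portion_model = as.data.frame(raw$milk_portion_model,
                                       stringsAsFactors = FALSE))
}

#' Write a population configuration to YAML or JSON
#'
#' @param config A [population_config()].
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_population_config <- function(config, path) {
  validate_population_config(config)
  x <- unclass(config)
  x$age_probs <- as.list(x$age_probs)
  x$covariate_probs <- lapply(x$covariate_probs, as.list)
  x$milk_group_probs <- apply(x$milk_group_probs, 1, as.list,
                              simplify = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15) else
    jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' simulate -> intakes -> classify -> adequacy -> substitute -> report,
#' writing the survey CSVs and the report bundle to `out_dir`. Fully
#' deterministic: a fixed (config, seed, n) yields byte-identical
#' outputs.
#'
#' @param config A [population_config()]; by default the bundled
#'   configuration calibrated to the baseline prevalence targets.
#' @param n Population size (default `config$n_children`).
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param calibrate Calibrate the intake model before simulating
#'   (default TRUE when `config` is not supplied).
#' @return Invisibly, a list with the fitted model, report, and paths.
#' @export
run_pipeline <- function(config = NULL, n = NULL, seed = 1,
                         out_dir = tempfile("milksub_run_"),
                         calibrate = is.null(config)) {
  if (is.null(config)) config <- population_config(seed = seed)
  table <- default_composition()
  refs <- default_reference_values()
  if (calibrate)
    config <- calibrate_to_baseline(baseline_targets(), config,
                                    refs = refs, table = table, seed = seed)
  if (is.null(n)) n <- config$n_children
  message("simulating survey: n = ", n, ", seed = ", seed)
  svy <- simulate_survey(config, n, seed)
  intakes <- compute_intakes(svy$recall, table, svy$population$child_id)
  intakes$age_months <- svy$population$age_months
  fit <- milk_substitution(svy$recall, table, svy$population, refs)
  report <- build_report(svy$population, intakes, fit, refs)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(svy$population, file.path(out_dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(svy$recall, file.path(out_dir, "recall.csv"),
                   row.names = FALSE)
  utils::write.csv(intakes, file.path(out_dir, "intakes.csv"),
                   row.names = FALSE)
  paths <- write_report(report, out_dir)
  invisible(list(fit = fit, report = report, config = config,
                 out_dir = out_dir,
                 paths = c(file.path(out_dir, c("population.csv",
                                                "recall.csv",
                                                "intakes.csv")), paths)))
}
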