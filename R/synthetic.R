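#' Configuration of the synthetic survey generator
#'
#' The generator emulates the structure of a large one-day national
#' dietary survey of children aged 12-60 months: demographic covariates,
#' mutually exclusive milk-consumer groups with age-specific shares, and
#' right-skewed single-day nutrient intakes. A configuration bundles:
#'
#' * `age_probs` — probabilities of the four descriptive age bands;
#'   months are uniform within a band.
#' * `covariate_probs` — categorical tables for sex, region (urban/rural),
#'   socioeconomic status and maternal education (7 ordinal levels).
#' * `milk_group_probs` — P(milk group | age band) over
#'   non_milk/ycm/condensed/cow, one row per age band.
#' * `intake_model` — per modeling group (12-35 / 36-60 months) and
#'   nutrient: a log-normal background-diet intake with log-scale
#'   location `mu`, log-scale SD `sigma`, and an optional point mass at
#'   zero `p_zero` (needed for nutrients such as vitamin D whose
#'   single-day intake is zero for a sizeable share of children).
#'   Background intakes are drawn independently across nutrients.
#' * `milk_portion_model` — per milk group, a log-normal daily consumed
#'   milk volume (mL) with `median_mL` and `sdlog`.
#'
#' @param n_children Default population size.
#' @param seed Default root seed.
#' @param age_probs,covariate_probs,milk_group_probs,intake_model,milk_portion_model
#'   Components as described above; defaults emulate the survey's
#'   published marginals.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_children = 11020, seed = 1,
                              age_probs = default_age_probs(),
                              covariate_probs = default_covariate_probs(),
                              milk_group_probs = default_milk_group_probs(),
                              intake_model = default_intake_model(),
                              milk_portion_model = default_portion_model()) {
  cfg <- structure(list(n_children = n_children, seed = seed,
                        age_probs = age_probs,
                        covariate_probs = covariate_probs,
                        milk_group_probs = milk_group_probs,
                        intake_model = intake_model,
                        milk_portion_model = milk_portion_model),
                   class = "population_config")
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("probability table '", what,
           "' must be non-negative and sum to 1", call. = FALSE)
  }
  if (cfg$n_children < 0 || cfg$n_children != round(cfg$n_children))
    stop("n_children must be a non-negative integer", call. = FALSE)
  check_probs(cfg$age_probs, "age_probs")
  for (nm in names(cfg$covariate_probs))
    check_probs(cfg$covariate_probs[[nm]], nm)
  for (b in rownames(cfg$milk_group_probs))
    check_probs(cfg$milk_group_probs[b, ], paste0("milk_group_probs[", b, "]"))
  im <- cfg$intake_model
  if (any(!is.finite(im$sigma) | im$sigma <= 0))
    stop("intake_model dispersion (sigma) must be positive", call. = FALSE)
  if (any(im$p_zero < 0 | im$p_zero >= 1))
    stop("intake_model p_zero must lie in [0, 1)", call. = FALSE)
  pm <- cfg$milk_portion_model
  if (any(pm$median_mL < 0) || any(pm$sdlog <= 0))
    stop("milk_portion_model volumes must be >= 0 with positive sdlog",
         call. = FALSE)
  invisible(cfg)
}

#' @rdname population_config
#' @export
default_age_probs <- function() {
  p <- c("12_23" = 0.229, "24_35" = 0.245, "36_47" = 0.258, "48_60" = 0.268)
  p / sum(p)
}

#' @rdname population_config
#' @export
default_covariate_probs <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = c(boy = 0.517, girl = 0.483),
    region = c(urban = 0.429, rural = 0.571),
    ses = norm(c(low = 0.592, middle = 0.343, high = 0.065)),
    mother_education = norm(c(none = 0.050, not_graduated_elementary = 0.107,
                              elementary = 0.316, junior_high = 0.208,
                              senior_high = 0.238, diploma = 0.038,
                              university = 0.044)))
}

#' @rdname population_config
#' @export
default_milk_group_probs <- function() {
  m <- rbind(
    "12_23" = c(non_milk = 0.548, ycm = 0.353, condensed = 0.065, cow = 0.034),
    "24_35" = c(non_milk = 0.458, ycm = 0.334, condensed = 0.135, cow = 0.073),
    "36_47" = c(non_milk = 0.185, ycm = 0.577, condensed = 0.155, cow = 0.083),
    "48_60" = c(non_milk = 0.568, ycm = 0.219, condensed = 0.133, cow = 0.080))
  m / rowSums(m)
}

#' @rdname population_config
#' @export
default_portion_model <- function() {
  data.frame(milk_group = c("ycm", "condensed", "cow"),
             median_mL = c(300, 250, 250),
             sdlog = c(0.5, 0.6, 0.5),
             stringsAsFactors = FALSE)
}

#' Bundled baseline calibration targets
#'
#' Baseline intake-distribution targets for condensed-milk consumers in
#' the emulated survey population: per modeling group and micronutrient,
#' the prevalence of intake below the EAR cut-point (percent) and the
#' quartiles of the single-day intake distribution. These drive the
#' default intake model and [calibrate_to_baseline()].
#'
#' @return Data frame `group, nutrient, prevalence, p25, p50, p75`.
#' @export
baseline_targets <- function() {
  utils::read.csv(system.file("extdata", "baseline_targets.csv",
                              package = "milksub", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reported prevalences of the emulated substitution analysis
#'
#' The published inadequacy prevalences (percent) for condensed-milk
#' consumers at baseline and under the two substitution scenarios
#' (equal-volume and isocaloric young-child milk), per modeling group
#' and micronutrient. Used as worked-example inputs for
#' [relative_reduction()] and as qualitative anchors for the generator.
#'
#' @return Data frame `group, nutrient, baseline, scenario1, scenario2`.
#' @export
reported_prevalences <- function() {
  utils::read.csv(system.file("extdata", "reported_prevalences.csv",
                              package = "milksub", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# log-scale SDs fixed from the spread of the baseline quartile targets;
# vitamin D carries a zero point mass (its P25 target is 0)
#' @rdname population_config
#' @export
default_intake_model <- function() {
  refs <- default_reference_values()
  targets <- baseline_targets()
  base <- rbind(
    data.frame(group = "12_35",
               nutrient = c("energy_kcal", "protein_g", "vitc_mg"),
               mu = log(c(800, 22, 15)), sigma = c(0.35, 0.40, 0.90),
               p_zero = 0, stringsAsFactors = FALSE),
    data.frame(group = "36_60",
               nutrient = c("energy_kcal", "protein_g", "vitc_mg"),
               mu = log(c(950, 28, 18)), sigma = c(0.35, 0.40, 0.90),
               p_zero = 0, stringsAsFactors = FALSE))
  sig <- rbind(
    data.frame(group = "12_35",
               nutrient = c("vita_ug", "folate_ug", "vitd_ug",
                            "calcium_mg", "iron_mg", "zinc_mg"),
               sigma = c(1.75, 1.10, 2.14, 0.75, 0.70, 0.60),
               p_zero = c(0, 0, 0.30, 0, 0, 0), stringsAsFactors = FALSE),
    data.frame(group = "36_60",
               nutrient = c("vita_ug", "folate_ug", "vitd_ug",
                            "calcium_mg", "iron_mg", "zinc_mg"),
               sigma = c(1.46, 1.04, 1.99, 0.65, 0.69, 0.66),
               p_zero = c(0, 0, 0.30, 0, 0, 0), stringsAsFactors = FALSE))
  # analytic initial location: invert the zero-inflated log-normal CDF at
  # the target prevalence and the younger reference cut-point of the group
  sig$mu <- NA_real_
  for (i in seq_len(nrow(sig))) {
    t <- targets[targets$group == sig$group[i] &
                   targets$nutrient == sig$nutrient[i], ]
    age0 <- if (sig$group[i] == "12_35") 24 else 40
    cut <- ref_cutpoint(refs, sig$nutrient[i], age0)
    q <- (t$prevalence / 100 - sig$p_zero[i]) / (1 - sig$p_zero[i])
    sig$mu[i] <- log(cut) - sig$sigma[i] * stats::qnorm(q)
  }
  rbind(base, sig[, names(base)])
}

# Counter-based per-child seed stream: earlier children are unchanged
# when the population grows. Products stay below 2^53, exact in doubles.
child_seed <- function(root_seed, child_index, offset) {
  (root_seed * 69069 + 8 * child_index + offset) %% 2147483647
}

sample_one <- function(probs) names(probs)[
  findInterval(stats::runif(1), cumsum(probs), left.open = TRUE) + 1]

#' Generate a synthetic child population
#'
#' Children are drawn independently; child i's covariates come from a
#' seed stream derived from the root seed and i, so identical
#' (config, seed) yield identical output and enlarging n leaves earlier
#' children unchanged.
#'
#' @param config A [population_config()].
#' @param n Number of children (default `config$n_children`).
#' @param seed Root seed (default `config$seed`).
#' @return Data frame `child_id, child_index, age_months, sex, region,
#'   ses, mother_education`.
#' @export
generate_population <- function(config, n = config$n_children,
                                seed = config$seed) {
  validate_population_config(config)
  band_lo <- c("12_23" = 12, "24_35" = 24, "36_47" = 36, "48_60" = 48)
  band_n <- c("12_23" = 12, "24_35" = 12, "36_47" = 12, "48_60" = 13)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i, 0))
    band <- sample_one(config$age_probs)
    age <- band_lo[[band]] + floor(stats::runif(1) * band_n[[band]])
    out[[i]] <- data.frame(
      child_id = sprintf("c%06d", i), child_index = i,
      age_months = as.integer(age),
      sex = sample_one(config$covariate_probs$sex),
      region = sample_one(config$covariate_probs$region),
      ses = sample_one(config$covariate_probs$ses),
      mother_education = sample_one(config$covariate_probs$mother_education),
      stringsAsFactors = FALSE)
  }
  if (n == 0)
    return(data.frame(child_id = character(), child_index = integer(),
                      age_months = integer(), sex = character(),
                      region = character(), ses = character(),
                      mother_education = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assign a milk-consumer group to one child
#'
#' Draws one of the four mutually exclusive groups from the
#' age-band-specific distribution in `config$milk_group_probs`.
#'
#' @param profile One-row data frame from [generate_population()].
#' @param config A [population_config()].
#' @param seed Root seed of the population draw.
#' @return One of [MILK_GROUPS].
#' @export
assign_milk_group <- function(profile, config, seed = config$seed) {
  if (profile$age_months < 12 || profile$age_months > 60)
    stop("age ", profile$age_months,
         " months is outside the configured 12-60 month bands",
         call. = FALSE)
  band <- as.character(age_band(profile$age_months))
  if (!band %in% rownames(config$milk_group_probs))
    stop("no milk-group probabilities configured for age band ", band,
         call. = FALSE)
  set.seed(child_seed(seed, profile$child_index, 1))
  sample_one(config$milk_group_probs[band, ])
}

#' Generate one child's synthetic recall lines
#'
#' Emits one background-diet line per nutrient-bearing pseudo-food
#' (foods `BG_*` of [default_composition()], each carrying exactly one
#' nutrient at 100 units per 100 g, so the line amount in grams equals
#' the drawn daily intake), plus, for milk consumers, exactly one milk
#' line of the group's milk type with volume drawn from the portion
#' model. Young-child-milk consumers get the 1+ product below 36 months
#' and the 3+ product from 36 months.
#'
#' @param profile One-row data frame from [generate_population()].
#' @param group Milk group of the child.
#' @param config A [population_config()].
#' @param seed Root seed of the population draw.
#' @return Recall data frame `child_id, food_id, amount`.
#' @export
generate_recall <- function(profile, group, config, seed = config$seed) {
  mg <- modeling_group(profile$age_months)
  im <- config$intake_model[config$intake_model$group == mg, , drop = FALSE]
  im <- im[match(NUTRIENT_COLS, im$nutrient), , drop = FALSE]
  if (anyNA(im$mu))
    stop("intake_model must cover every nutrient for group ", mg,
         call. = FALSE)
  set.seed(child_seed(seed, profile$child_index, 2))
  u <- stats::runif(length(NUTRIENT_COLS))
  z <- stats::rnorm(length(NUTRIENT_COLS))
  amounts <- ifelse(u < im$p_zero, 0, exp(im$mu + im$sigma * z))
  lines <- data.frame(child_id = profile$child_id,
                      food_id = paste0("BG_", toupper(sub("_[a-zA-Z]+$", "",
                                                          NUTRIENT_COLS))),
                      amount = amounts, stringsAsFactors = FALSE)
  if (group != "non_milk") {
    pm <- config$milk_portion_model
    pm <- pm[pm$milk_group == group, , drop = FALSE]
    if (nrow(pm) != 1)
      stop("milk_portion_model missing group '", group, "'", call. = FALSE)
    vol <- stats::rlnorm(1, log(pm$median_mL), pm$sdlog)
    food <- switch(group,
                   ycm = if (profile$age_months < 36) "YCM1" else "YCM3",
                   condensed = "CONDENSED",
                   cow = "COW")
    lines <- rbind(lines,
                   data.frame(child_id = profile$child_id, food_id = food,
                              amount = vol, stringsAsFactors = FALSE))
  }
  rownames(lines) <- NULL
  lines
}

#' Simulate a full synthetic survey
#'
#' Population covariates, milk-group assignment and recall lines for n
#' children, deterministically from (config, seed).
#'
#' @inheritParams generate_population
#' @return List with `population` (covariates plus `milk_group`) and
#'   `recall` (stacked recall lines).
#' @export
simulate_survey <- function(config, n = config$n_children,
                            seed = config$seed) {
  pop <- generate_population(config, n, seed)
  if (n == 0)
    return(list(population = cbind(pop, milk_group = character(0)),
                recall = data.frame(child_id = character(),
                                    food_id = character(),
                                    amount = numeric(),
                                    stringsAsFactors = FALSE)))
  groups <- character(n)
  recalls <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- pop[i, , drop = FALSE]
    groups[i] <- assign_milk_group(prof, config, seed)
    recalls[[i]] <- generate_recall(prof, groups[i], config, seed)
  }
  pop$milk_group <- groups
  list(population = pop, recall = do.call(rbind, recalls))
}

#' Calibrate the intake model to baseline prevalence targets
#'
#' Deterministic moment matching on the log scale: for each modeling
#' group, a single set of common random numbers (background-diet normals,
#' zero-inflation uniforms, milk volumes, ages) is drawn from the seed at
#' the calibration size `n`; the log-scale location `mu` of each targeted
#' nutrient is then found by bisection so that the simulated baseline
#' prevalence of intake below the child-specific EAR cut-point among
#' target-milk consumers equals the target. Because the draw is fixed,
#' the search is deterministic given (config, targets, seed), and the
#' prevalence is monotone in `mu`, so bisection converges.
#'
#' @param targets Data frame `group, nutrient, prevalence` (see
#'   [baseline_targets()]); prevalences in percent.
#' @param config A [population_config()].
#' @param refs Reference values (default bundled).
#' @param table Composition table supplying the target milk's nutrient
#'   density (default bundled).
#' @param target_group Milk group whose baseline is being calibrated
#'   (default `"condensed"`).
#' @param n Calibration sample size (default 5000).
#' @param seed Seed of the calibration draw (default `config$seed`).
#' @param tol Acceptable absolute prevalence error, percentage points
#'   (default 3); targets that cannot be met raise a calibration failure
#'   listing them.
#' @return The config with updated `intake_model`, with a `"calibration"`
#'   attribute data frame `group, nutrient, target, achieved`.
#' @export
calibrate_to_baseline <- function(targets, config,
                                  refs = default_reference_values(),
                                  table = default_composition(),
                                  target_group = "condensed",
                                  n = 5000, seed = config$seed, tol = 3) {
  validate_population_config(config)
  if (any(targets$prevalence < 0 | targets$prevalence > 100))
    stop("targets must be prevalences in [0, 100]", call. = FALSE)
  milk_dens <- entry_per_100_mL(table,
                                switch(target_group, condensed = "CONDENSED",
                                       cow = "COW", ycm = "YCM1"))
  pm <- config$milk_portion_model
  pm <- pm[pm$milk_group == target_group, , drop = FALSE]
  report <- NULL
  for (g in unique(targets$group)) {
    # common random numbers for this modeling group
    set.seed(child_seed(seed, 0, 3 + match(g, c("12_35", "36_60"))))
    ages <- if (g == "12_35") sample(12:35, n, replace = TRUE) else
      sample(36:60, n, replace = TRUE)
    vol <- stats::rlnorm(n, log(pm$median_mL), pm$sdlog)
    tg <- targets[targets$group == g, , drop = FALSE]
    for (j in seq_len(nrow(tg))) {
      nut <- tg$nutrient[j]
      row <- which(config$intake_model$group == g &
                     config$intake_model$nutrient == nut)
      if (!length(row))
        stop("intake_model has no entry for (", g, ", ", nut, ")",
             call. = FALSE)
      sigma <- config$intake_model$sigma[row]
      p0 <- config$intake_model$p_zero[row]
      z <- stats::rnorm(n)
      u <- stats::runif(n)
      contrib <- vol / 100 * milk_dens[[nut]]
      cut <- ref_cutpoint(refs, nut, ages)
      prev <- function(mu)
        100 * mean(ifelse(u < p0, 0, exp(mu + sigma * z)) + contrib < cut)
      lo <- log(min(cut)) - 6 * sigma - 6
      hi <- log(max(cut)) + 6 * sigma + 6
      # prevalence is non-increasing in mu
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (prev(mid) > tg$prevalence[j]) lo <- mid else hi <- mid
      }
      mu <- (lo + hi) / 2
      config$intake_model$mu[row] <- mu
      report <- rbind(report, data.frame(
        group = g, nutrient = nut, target = tg$prevalence[j],
        achieved = prev(mu), stringsAsFactors = FALSE))
    }
  }
  unmet <- abs(report$achieved - report$target) > tol
  if (any(unmet))
    stop("calibration failed for target(s): ",
         paste(sprintf("%s/%s (target %.1f, achieved %.1f)",
                       report$group[unmet], report$nutrient[unmet],
                       report$target[unmet], report$achieved[unmet]),
               collapse = "; "), call. = FALSE)
  attr(config, "calibration") <- report
  config
}
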