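#' Reference (EAR) cut-point tables
#'
#' A reference-value set maps (nutrient, age band) to the estimated
#' average requirement used as the cut-point of the EAR cut-point method.
#' Age bands for reference lookup are 12-35, 36-47 and 48-60 months
#' (half-open on age in completed months). The bundled table
#' `inst/extdata/ear_reference_values.csv` carries the WHO EAR values for
#' the six micronutrients evaluated by default: vitamin A (ug RE), folate
#' (ug), vitamin D (ug), calcium (mg), iron (mg) and zinc (mg). Vitamin C
#' has no bundled cut-point; supply one in a user table to evaluate it.
#'
#' @name reference_values
NULL

REFERENCE_COLS <- c("nutrient", "age_band_lo", "age_band_hi", "cutpoint",
                    "unit")

#' Read a reference-value (EAR) table from CSV
#'
#' @param path CSV with header `nutrient,age_band_lo,age_band_hi,cutpoint,unit`.
#' @return Validated reference data frame.
#' @export
read_reference_values <- function(path) {
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reference_values(refs)
}

validate_reference_values <- function(refs) {
  missing_cols <- setdiff(REFERENCE_COLS, names(refs))
  if (length(missing_cols))
    stop("reference table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(!is.finite(refs$cutpoint) | refs$cutpoint <= 0))
    stop("all cut-points must be positive", call. = FALSE)
  if (any(refs$age_band_lo >= refs$age_band_hi))
    stop("age_band_lo must be below age_band_hi", call. = FALSE)
  refs
}

#' Bundled EAR reference values
#' @return Reference data frame (see [reference_values]).
#' @export
default_reference_values <- function() {
  read_reference_values(system.file("extdata", "ear_reference_values.csv",
                                    package = "milksub", mustWork = TRUE))
}

#' Look up the cut-point for a nutrient at given ages
#'
#' @param refs Reference data frame.
#' @param nutrient One of [NUTRIENT_COLS].
#' @param age_months Vector of ages in completed months.
#' @return Numeric vector of cut-points, one per age.
#' @export
ref_cutpoint <- function(refs, nutrient, age_months) {
  rows <- refs[refs$nutrient == nutrient, , drop = FALSE]
  if (!nrow(rows))
    stop("no reference value for nutrient '", nutrient, "'", call. = FALSE)
  out <- rep(NA_real_, length(age_months))
  for (i in seq_len(nrow(rows))) {
    hit <- age_months >= rows$age_band_lo[i] & age_months <= rows$age_band_hi[i]
    out[hit] <- rows$cutpoint[i]
  }
  if (anyNA(out)) {
    bad <- unique(age_months[is.na(out)])
    stop("no reference value for (", nutrient, ", age ",
         paste(bad, collapse = ","), " months)", call. = FALSE)
  }
  out
}

#' Prevalence of inadequate intake by the EAR cut-point method
#'
#' The prevalence of inadequacy is estimated as the percentage of
#' children whose single-day intake falls strictly below the EAR
#' cut-point for their own age band. When an analysis group spans
#' several reference bands (e.g. a 36-60 month modeling group with
#' separate 36-47 and 48-60 month cut-points), each child is judged
#' against the cut-point of the band their age falls in and a single
#' pooled prevalence is reported.
#'
#' @param intakes Data frame with columns `age_months` and the nutrient
#'   column being evaluated (as produced by [compute_intakes()] merged
#'   with the population table).
#' @param nutrient Name of the nutrient column to evaluate.
#' @param refs Reference data frame (see [reference_values]).
#' @return List with `prevalence` (percent), `count` (children below),
#'   and `n`.
#' @examples
#' refs <- default_reference_values()
#' d <- data.frame(age_months = c(20, 20, 20),
#'                 iron_mg = c(2.8, 5.9, 6.0))
#' prevalence_below_reference(d, "iron_mg", refs)$prevalence  # 33.33
#' @export
prevalence_below_reference <- function(intakes, nutrient, refs) {
  stopifnot(is.data.frame(intakes))
  if (nrow(intakes) == 0)
    stop("cannot estimate a prevalence from an empty population",
         call. = FALSE)
  if (!nutrient %in% names(intakes))
    stop("intakes has no column '", nutrient, "'", call. = FALSE)
  cut <- ref_cutpoint(refs, nutrient, intakes$age_months)
  below <- intakes[[nutrient]] < cut
  list(prevalence = 100 * sum(below) / length(below),
       count = sum(below), n = length(below))
}

#' Modeling age group (12-35 vs 36-60 months)
#'
#' Dietary-modeling analyses pool the four descriptive age bands into
#' two: 12-35 months ("1-2y") and 36-60 months ("3-4y").
#'
#' @param age_months Vector of ages in completed months.
#' @return Character vector, `"12_35"` or `"36_60"`.
#' @export
modeling_group <- function(age_months) {
  if (any(age_months < 12 | age_months > 60))
    stop("age_months outside the 12-60 month population", call. = FALSE)
  ifelse(age_months < 36, "12_35", "36_60")
}

#' Descriptive age band (12-23, 24-35, 36-47, 48-60 months)
#' @param age_months Vector of ages in completed months.
#' @return Character vector of band labels.
#' @export
age_band <- function(age_months) {
  if (any(age_months < 12 | age_months > 60))
    stop("age_months outside the 12-60 month population", call. = FALSE)
  cut(age_months, c(12, 24, 36, 48, 61), right = FALSE,
      labels = c("12_23", "24_35", "36_47", "48_60"))
}
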