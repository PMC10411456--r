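#' Food composition tables
#'
#' A composition table is a data frame with one row per food, giving the
#' nutrient content per 100 units as consumed (grams for `basis =
#' "per_100_g"`, millilitres for `basis = "per_100_mL"`), a milk-type tag
#' used for consumer classification and scenario substitution, and an
#' optional density (g/mL) used to convert between the two bases.
#'
#' Required columns:
#' `food_id, name, basis, density_g_per_mL, milk_type, ycm_ageband`,
#' followed by the nine nutrient columns of [NUTRIENT_COLS].
#' `ycm_ageband` tags young-child-milk entries with the age band the
#' product is formulated for (`"1plus"` for 12-35 months, `"3plus"` for
#' 36-60 months); it is empty for other foods.
#'
#' @name composition
NULL

COMPOSITION_COLS <- c("food_id", "name", "basis", "density_g_per_mL",
                      "milk_type", "ycm_ageband", NUTRIENT_COLS)

#' Validate a food composition data frame
#'
#' Checks column set, non-negative finite nutrient densities, known basis
#' and milk-type labels, uniqueness of `food_id`, and that every
#' `milk_type = "ycm"` entry carries an age-band tag.
#'
#' @param tab Data frame in the layout described in [composition].
#' @return The validated table, invisibly usable downstream.
#' @export
composition_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  missing_cols <- setdiff(COMPOSITION_COLS, names(tab))
  if (length(missing_cols))
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$food_id <- as.character(tab$food_id)
  dup <- tab$food_id[duplicated(tab$food_id)]
  if (length(dup))
    stop("duplicate food_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_basis <- which(!tab$basis %in% c("per_100_g", "per_100_mL"))
  if (length(bad_basis))
    stop("row ", bad_basis[1], ": unknown basis '", tab$basis[bad_basis[1]],
         "'", call. = FALSE)
  bad_milk <- which(!tab$milk_type %in% MILK_TYPES)
  if (length(bad_milk))
    stop("row ", bad_milk[1], ": unknown milk_type '",
         tab$milk_type[bad_milk[1]], "'", call. = FALSE)
  for (col in NUTRIENT_COLS) {
    x <- tab[[col]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad))
      stop("row ", bad[1], ": ", col, " must be a non-negative number",
           call. = FALSE)
  }
  ycm_rows <- tab$milk_type == "ycm"
  band <- as.character(tab$ycm_ageband)
  if (any(ycm_rows & !(band %in% c("1plus", "3plus"))))
    stop("every ycm entry needs ycm_ageband '1plus' or '3plus'",
         call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Read a food composition table from CSV
#'
#' @param path Path to a CSV file with the [composition] header.
#' @return Validated composition data frame.
#' @export
read_composition_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(food_id = "character",
                                        ycm_ageband = "character"))
  composition_table(tab)
}

#' Convert a composition entry between per-100-g and per-100-mL bases
#'
#' Rescales nutrient densities by the food's density (g/mL): 100 mL of a
#' food of density d weighs 100 d g, so per-100-mL values are the
#' per-100-g values times d. The round trip is the identity.
#'
#' @param entry One-row composition data frame.
#' @param target_basis `"per_100_g"` or `"per_100_mL"`.
#' @return One-row composition data frame on the target basis.
#' @export
convert_basis <- function(entry, target_basis) {
  stopifnot(is.data.frame(entry), nrow(entry) == 1)
  target_basis <- match.arg(target_basis, c("per_100_g", "per_100_mL"))
  if (entry$basis == target_basis) return(entry)
  d <- entry$density_g_per_mL
  if (!is.finite(d) || d <= 0)
    stop("density_g_per_mL required to convert basis for food '",
         entry$food_id, "'", call. = FALSE)
  factor <- if (target_basis == "per_100_mL") d else 1 / d
  entry[NUTRIENT_COLS] <- entry[NUTRIENT_COLS] * factor
  entry$basis <- target_basis
  entry
}

#' As-consumed profile of a reconstituted milk powder
#'
#' Young-child milks are sold as powder; recall lines and the substitution
#' scenarios are stated in consumed millilitres. This helper turns a
#' per-100-g powder profile plus the label reconstitution rate into a
#' per-100-mL as-consumed entry.
#'
#' @param powder_entry One-row composition data frame, `basis = "per_100_g"`,
#'   describing the dry powder.
#' @param grams_per_100_mL Powder grams dissolved per 100 mL of prepared
#'   beverage (label instruction, typically 13-15 g).
#' @return One-row per-100-mL composition entry for the prepared beverage.
#' @export
reconstitute_powder <- function(powder_entry, grams_per_100_mL) {
  stopifnot(is.data.frame(powder_entry), nrow(powder_entry) == 1,
            powder_entry$basis == "per_100_g")
  if (!is.finite(grams_per_100_mL) || grams_per_100_mL <= 0)
    stop("grams_per_100_mL must be positive", call. = FALSE)
  out <- powder_entry
  out[NUTRIENT_COLS] <- powder_entry[NUTRIENT_COLS] * grams_per_100_mL / 100
  out$basis <- "per_100_mL"
  out
}

#' Bundled synthetic composition table
#'
#' Loads `inst/extdata/composition_synthetic.csv`: nine single-nutrient
#' background pseudo-foods (used by the synthetic recall generator) plus
#' illustrative milk profiles (condensed milk as consumed, young-child
#' milk 1+ and 3+ as reconstituted, plain cow's milk). The milk profiles
#' are synthetic: commercial product compositions are not public inputs,
#' so these were fixed once to plausible label-level values consistent
#' with the intake shifts the package's bundled calibration targets
#' describe. They are suitable for simulation and testing, not for
#' analysing real survey data.
#'
#' @return Validated composition data frame.
#' @export
default_composition <- function() {
  path <- system.file("extdata", "composition_synthetic.csv",
                      package = "milksub", mustWork = TRUE)
  read_composition_table(path)
}
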