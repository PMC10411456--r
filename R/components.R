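#' Tracked nutrient components
#'
#' The package tracks a fixed, closed set of nine components per child-day:
#' energy (kcal), protein (g), and the micronutrients evaluated against
#' EAR cut-points: vitamin A (ug retinol equivalents), vitamin C (mg),
#' vitamin D (ug), folate (ug), calcium (mg), iron (mg) and zinc (mg).
#'
#' @format Character vector of column names used throughout the package.
#' @export
NUTRIENT_COLS <- c("energy_kcal", "protein_g", "vita_ug", "vitc_mg",
                   "vitd_ug", "folate_ug", "calcium_mg", "iron_mg", "zinc_mg")

#' Micronutrients evaluated against reference cut-points
#' @export
MICRONUTRIENTS <- c("vita_ug", "vitc_mg", "vitd_ug", "folate_ug",
                    "calcium_mg", "iron_mg", "zinc_mg")

#' Milk type labels
#'
#' `"ycm"` is young-child milk (growing-up milk), `"condensed"` sweetened
#' condensed milk on an as-consumed (diluted) basis, `"cow"` plain cow's
#' milk; `"none"` marks non-milk foods.
#' @export
MILK_TYPES <- c("none", "ycm", "condensed", "cow")

#' Mutually exclusive milk-consumer groups
#' @export
MILK_GROUPS <- c("non_milk", "ycm", "condensed", "cow")

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector over the fixed component set
#' [NUTRIENT_COLS]. Unspecified components default to zero.
#'
#' @param ... Named components, e.g. `energy_kcal = 70, iron_mg = 0.07`.
#' @return Named numeric vector over `NUTRIENT_COLS`.
#' @examples
#' nutrient_vector(energy_kcal = 67, vitd_ug = 2.2)
#' @export
nutrient_vector <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all components must be named", call. = FALSE)
  bad <- setdiff(names(args), NUTRIENT_COLS)
  if (length(bad))
    stop("unknown nutrient component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- stats::setNames(numeric(length(NUTRIENT_COLS)), NUTRIENT_COLS)
  v[names(args)] <- vapply(args, as.numeric, numeric(1))
  validate_nutrient_vector(v)
  v
}

validate_nutrient_vector <- function(v) {
  if (!all(NUTRIENT_COLS %in% names(v)))
    stop("nutrient vector is missing components", call. = FALSE)
  if (any(!is.finite(v[NUTRIENT_COLS])))
    stop("nutrient components must be finite", call. = FALSE)
  if (any(v[NUTRIENT_COLS] < 0))
    stop("nutrient components must be non-negative", call. = FALSE)
  invisible(v)
}
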