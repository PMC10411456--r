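#' Compute one child's daily nutrient intake from recall lines
#'
#' The standard food-composition computation behind any 24-h recall
#' instrument: intake = sum over lines of (amount / 100) x nutrient
#' content per 100 units as consumed. The result is linear in the lines:
#' additive over concatenation, invariant to their order, and the empty
#' recall maps to the zero vector.
#'
#' @param lines Data frame with columns `child_id, food_id, amount`
#'   (amount in g or mL matching each food's basis), for a single child.
#' @param table Composition data frame (see [composition_table()]).
#' @return Named numeric nutrient vector over [NUTRIENT_COLS].
#' @examples
#' tab <- composition_table(data.frame(
#'   food_id = "m", name = "milk", basis = "per_100_mL",
#'   density_g_per_mL = 1.03, milk_type = "cow", ycm_ageband = "",
#'   energy_kcal = 61, protein_g = 3.2, vita_ug = 28, vitc_mg = 0,
#'   vitd_ug = 5, folate_ug = 5, calcium_mg = 113, iron_mg = 0.03,
#'   zinc_mg = 0.4))
#' compute_intake(data.frame(child_id = 1, food_id = "m", amount = 150),
#'                tab)["vitd_ug"]  # 7.5
#' @export
compute_intake <- function(lines, table) {
  v <- stats::setNames(numeric(length(NUTRIENT_COLS)), NUTRIENT_COLS)
  if (is.null(lines) || nrow(lines) == 0) return(v)
  check_recall_lines(lines, table)
  idx <- match(as.character(lines$food_id), table$food_id)
  dens <- as.matrix(table[idx, NUTRIENT_COLS, drop = FALSE])
  colSums(dens * (lines$amount / 100))
}

check_recall_lines <- function(lines, table) {
  stopifnot(is.data.frame(lines))
  need <- c("food_id", "amount")
  missing_cols <- setdiff(need, names(lines))
  if (length(missing_cols))
    stop("recall lines missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  idx <- match(as.character(lines$food_id), table$food_id)
  if (anyNA(idx))
    stop("unresolved food_id: ",
         paste(unique(lines$food_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(lines$amount) | lines$amount < 0))
    stop("recall amounts must be finite and non-negative", call. = FALSE)
  invisible(idx)
}

#' Per-child intakes for a whole recall file
#'
#' Vectorised application of [compute_intake()] over all children present
#' in `recall`. Children listed in `child_ids` but absent from the recall
#' get a zero intake row.
#'
#' @param recall Data frame `child_id, food_id, amount` for many children.
#' @param table Composition data frame.
#' @param child_ids Optional vector fixing the output rows and their order;
#'   defaults to the children present in `recall`.
#' @return Data frame `child_id` + one column per [NUTRIENT_COLS] entry.
#' @export
compute_intakes <- function(recall, table, child_ids = NULL) {
  if (is.null(child_ids)) child_ids <- unique(as.character(recall$child_id))
  child_ids <- as.character(child_ids)
  out <- matrix(0, nrow = length(child_ids), ncol = length(NUTRIENT_COLS),
                dimnames = list(NULL, NUTRIENT_COLS))
  if (nrow(recall)) {
    idx <- check_recall_lines(recall, table)
    dens <- as.matrix(table[idx, NUTRIENT_COLS, drop = FALSE])
    contrib <- dens * (recall$amount / 100)
    grp <- factor(as.character(recall$child_id), levels = child_ids)
    if (anyNA(grp))
      stop("recall contains child_id values not in child_ids", call. = FALSE)
    agg <- rowsum(contrib, grp)
    out[match(rownames(agg), child_ids), ] <- agg
  }
  cbind(data.frame(child_id = child_ids, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Classify a child's milk-consumer group from recall lines
#'
#' A child with no milk-typed line is a `non_milk` consumer. Otherwise the
#' child is assigned to exactly one group: the milk type contributing the
#' most energy among the child's milk lines (dominant-energy rule), with
#' ties broken in the fixed order ycm > cow > condensed. The rule is
#' deterministic and partitions any population into the four exclusive
#' groups of [MILK_GROUPS].
#'
#' @param lines Recall data frame for one child.
#' @param table Composition data frame.
#' @return One of `"non_milk"`, `"ycm"`, `"condensed"`, `"cow"`.
#' @export
classify_consumer <- function(lines, table) {
  if (is.null(lines) || nrow(lines) == 0) return("non_milk")
  idx <- check_recall_lines(lines, table)
  milk <- table$milk_type[idx]
  keep <- milk != "none"
  if (!any(keep)) return("non_milk")
  energy <- table$energy_kcal[idx][keep] * lines$amount[keep] / 100
  by_type <- tapply(energy, milk[keep], sum)
  tie_order <- c("ycm", "cow", "condensed")
  by_type <- by_type[order(match(names(by_type), tie_order))]
  names(by_type)[which.max(by_type)]
}

#' Milk-consumer group for every child in a recall file
#'
#' @inheritParams compute_intakes
#' @return Data frame `child_id, milk_group`; children without recall
#'   lines are `non_milk`.
#' @export
classify_population <- function(recall, table, child_ids = NULL) {
  if (is.null(child_ids)) child_ids <- unique(as.character(recall$child_id))
  child_ids <- as.character(child_ids)
  grp <- rep("non_milk", length(child_ids))
  if (nrow(recall)) {
    idx <- check_recall_lines(recall, table)
    milk <- table$milk_type[idx]
    keep <- milk != "none"
    if (any(keep)) {
      energy <- table$energy_kcal[idx][keep] * recall$amount[keep] / 100
      cid <- as.character(recall$child_id)[keep]
      tie_order <- c("ycm", "cow", "condensed")
      etab <- rowsum(
        outer_energy(energy, factor(milk[keep], levels = tie_order)),
        factor(cid, levels = unique(cid)))
      winner <- tie_order[max.col(etab, ties.method = "first")]
      grp[match(rownames(etab), child_ids)] <- winner
    }
  }
  data.frame(child_id = child_ids, milk_group = grp,
             stringsAsFactors = FALSE)
}

# energy spread into one column per milk type, for rowsum aggregation
outer_energy <- function(energy, milk_factor) {
  m <- matrix(0, length(energy), nlevels(milk_factor),
              dimnames = list(NULL, levels(milk_factor)))
  m[cbind(seq_along(energy), as.integer(milk_factor))] <- energy
  m
}

#' Approximate energy/protein intake status
#'
#' Flags children below a configurable fraction of an age-band
#' energy/protein requirement. The national survey this package emulates
#' used its own classification of energy and protein status; that rule is
#' not public, so this is an explicit, configurable approximation and is
#' labelled as such in reports.
#'
#' @param intakes Data frame from [compute_intakes()] joined with
#'   `age_months`.
#' @param requirements Data frame `age_band_lo, age_band_hi, energy_kcal,
#'   protein_g` of daily requirements.
#' @param fraction Fraction of the requirement defining adequacy
#'   (default 1).
#' @return Input with logical columns `energy_adequate, protein_adequate`.
#' @export
energy_protein_status <- function(intakes, requirements, fraction = 1) {
  stopifnot(all(c("age_months", "energy_kcal", "protein_g") %in%
                  names(intakes)))
  band <- findInterval(intakes$age_months, requirements$age_band_lo)
  if (any(band == 0 | intakes$age_months > max(requirements$age_band_hi)))
    stop("age outside requirement bands", call. = FALSE)
  intakes$energy_adequate <-
    intakes$energy_kcal >= fraction * requirements$energy_kcal[band]
  intakes$protein_adequate <-
    intakes$protein_g >= fraction * requirements$protein_g[band]
  intakes
}
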