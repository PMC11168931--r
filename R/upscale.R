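## Inventory-scale arithmetic: apply a uniform emission-reduction factor to
## selected source categories of a country emission inventory and report
## the resulting percentage decreases.

.INVENTORY_CATEGORIES <- c("liquid_manure_applied", "solid_manure_applied",
                           "mineral_fertilizer", "plant_residues", "other")

#' Read or validate an emission inventory table
#'
#' Long-form inventory: one row per region and category with columns
#' `region`, `total_kt` (total anthropogenic N2O-N emission, kt yr-1),
#' `agric_kt` (agricultural share), `category`, `emission_kt`.
#'
#' @param x A data frame in the long schema, or a path to such a CSV.
#' @return Validated data frame of class `emission_inventory`.
#' @export
emission_inventory <- function(x) {
  d <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
       else as.data.frame(x)
  need <- c("region", "total_kt", "agric_kt", "category", "emission_kt")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("inventory is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(d$category), .INVENTORY_CATEGORIES)
  if (length(bad)) {
    stop("unknown categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), "; valid: ",
         paste(.INVENTORY_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  if (any(d$emission_kt < 0) || any(d$total_kt < 0)) {
    stop("emissions must be >= 0", call. = FALSE)
  }
  sums <- tapply(d$emission_kt, d$region, sum)
  tot <- tapply(d$total_kt, d$region, max)
  if (any(sums > tot[names(sums)] * (1 + 1e-9))) {
    stop("category emissions exceed the regional total", call. = FALSE)
  }
  class(d) <- c("emission_inventory", "data.frame")
  d
}

#' Apply an emission-reduction scenario to an inventory
#'
#' Multiplies the targeted categories' emissions by `1 - factor`, leaves
#' every other source unchanged, and recomputes each region's total and
#' agricultural emissions and their percentage decreases.
#'
#' @param inv An [emission_inventory()] (or data frame / CSV path).
#' @param factor Uniform reduction factor in [0, 1] (default 0.6).
#' @param categories Character vector of targeted category keys (default
#'   `"liquid_manure_applied"`).
#' @return Object of class `scenario_result`: the reduced long table and a
#'   per-region summary with `total_kt`, `new_total_kt`,
#'   `total_decrease_pct`, `agric_kt`, `new_agric_kt`,
#'   `agric_decrease_pct`.
#' @export
apply_scenario <- function(inv, factor = 0.6,
                           categories = "liquid_manure_applied") {
  if (!inherits(inv, "emission_inventory")) inv <- emission_inventory(inv)
  stopifnot(factor >= 0, factor <= 1)
  bad <- setdiff(categories, .INVENTORY_CATEGORIES)
  if (length(bad)) {
    stop("unknown target categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), "; valid: ",
         paste(.INVENTORY_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  d <- as.data.frame(inv)
  hit <- d$category %in% categories
  d$new_emission_kt <- ifelse(hit, d$emission_kt * (1 - factor),
                              d$emission_kt)
  d$reduction_kt <- d$emission_kt - d$new_emission_kt
  if (!nrow(d)) {
    empty <- data.frame(region = character(0), total_kt = numeric(0),
                        new_total_kt = numeric(0),
                        total_decrease_pct = numeric(0),
                        agric_kt = numeric(0), new_agric_kt = numeric(0),
                        agric_decrease_pct = numeric(0),
                        reduction_kt = numeric(0))
    return(structure(list(table = d, summary = empty, factor = factor,
                          categories = categories),
                     class = "scenario_result"))
  }
  per_region <- do.call(rbind, lapply(split(d, d$region), function(r) {
    cut_kt <- sum(r$reduction_kt)
    total <- r$total_kt[1]; agric <- r$agric_kt[1]
    data.frame(
      region = r$region[1],
      total_kt = total, new_total_kt = total - cut_kt,
      total_decrease_pct = if (total > 0) 100 * cut_kt / total else 0,
      agric_kt = agric, new_agric_kt = agric - cut_kt,
      agric_decrease_pct = if (agric > 0) 100 * cut_kt / agric else 0,
      reduction_kt = cut_kt, row.names = NULL)
  }))
  per_region <- per_region[order(per_region$region), ]
  rownames(per_region) <- NULL
  structure(list(table = d, summary = per_region, factor = factor,
                 categories = categories),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Reduction scenario: factor %.2f on %s\n", x$factor,
              paste(x$categories, collapse = ", ")))
  print(scenario_report(x), row.names = FALSE)
  invisible(x)
}

#' Formatted scenario report
#'
#' Deterministic per-region table of absolute and relative reductions,
#' with fixed column order and one-decimal percentages.
#'
#' @param result An [apply_scenario()] result.
#' @return Data frame with columns `region`, `total_kt`, `new_total_kt`,
#'   `reduction_kt`, `total_decrease_pct`, `agric_decrease_pct`
#'   (percentages rounded to one decimal).
#' @export
scenario_report <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  s <- result$summary
  data.frame(region = s$region,
             total_kt = s$total_kt,
             new_total_kt = s$new_total_kt,
             reduction_kt = s$reduction_kt,
             total_decrease_pct = round(s$total_decrease_pct, 1),
             agric_decrease_pct = round(s$agric_decrease_pct, 1))
}
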