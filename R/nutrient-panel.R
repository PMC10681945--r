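#' The fixed 18-nutrient reporting panel
#'
#' All intake tables in this package carry the same 18 nutrient columns, in
#' the order used throughout: energy and the macro- and micronutrients that
#' dominate discussions of beverage quality in children (the "nutrients of
#' public health concern" calcium, potassium, dietary fiber and vitamin D
#' among them). Added sugars are kept in USDA teaspoon equivalents
#' end-to-end; [tsp_to_grams()] exposes the conventional 4.2 g/tsp factor
#' for cross-checks only.
#'
#' @return A tibble with columns `nutrient` (canonical column name), `unit`,
#'   and `label` (display label).
#' @export
#' @examples
#' nutrient_panel()
nutrient_panel <- function() {
  tibble::tibble(
    nutrient = c(
      "energy", "carbohydrate", "dietary_fiber", "total_sugars",
      "added_sugars", "protein", "total_fat", "mufa", "pufa", "sfa",
      "calcium", "magnesium", "potassium", "sodium", "vitamin_a_re",
      "folate_dfe", "vitamin_b12", "vitamin_d"
    ),
    unit = c(
      "kcal", "g", "g", "g", "tsp eq", "g", "g", "g", "g", "g",
      "mg", "mg", "mg", "mg", "ug RE", "ug DFE", "ug", "ug"
    ),
    label = c(
      "Energy", "Carbohydrate", "Dietary fiber", "Total sugars",
      "Added sugars", "Protein", "Total fat", "Total MUFA", "Total PUFA",
      "Total SFA", "Calcium", "Magnesium", "Potassium", "Sodium",
      "Vitamin A, RE", "Folate, DFE", "Vitamin B12", "Vitamin D"
    )
  )
}

#' @rdname nutrient_panel
#' @export
nutrient_names <- function() nutrient_panel()$nutrient

#' Convert added-sugar teaspoon equivalents to grams
#'
#' Added sugars are reported in teaspoon equivalents throughout; this helper
#' applies the conventional gram weight of one teaspoon of sugar. It is
#' provided for cross-checks against gram-denominated statements and is not
#' used by any estimator.
#'
#' @param tsp Teaspoon equivalents.
#' @param grams_per_tsp Grams per teaspoon equivalent (default 4.2).
#' @return Grams of added sugar.
#' @export
tsp_to_grams <- function(tsp, grams_per_tsp = 4.2) tsp * grams_per_tsp

# Zero nutrient vector (named), used for zero-filling.
zero_nutrients <- function() {
  stats::setNames(numeric(18L), nutrient_names())
}

#' Validate a table of nutrient values
#'
#' Checks the internal-consistency rules every nutrient vector must obey:
#' all components nonnegative; each fatty-acid class at most 105% of total
#' fat (the 5% slack absorbs database rounding); and added sugars, once
#' converted to grams, no more than total sugars.
#'
#' @param x A data frame or named numeric vector containing the 18 panel
#'   columns (see [nutrient_names()]).
#' @param grams_per_tsp Gram weight of a teaspoon equivalent used for the
#'   added-vs-total sugar check.
#' @param tol Absolute slack for floating-point comparisons.
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
validate_nutrients <- function(x, grams_per_tsp = 4.2, tol = 1e-8) {
  if (is.numeric(x) && !is.null(names(x))) x <- as.data.frame(as.list(x))
  miss <- setdiff(nutrient_names(), names(x))
  if (length(miss) > 0) {
    stop("missing nutrient column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in nutrient_names()) {
    v <- x[[nm]]
    if (!is.numeric(v)) stop("nutrient column '", nm, "' is not numeric",
                             call. = FALSE)
    bad <- which(v < -tol)
    if (length(bad) > 0) {
      stop("negative ", nm, " at row(s) ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  fat_cap <- x$total_fat * 1.05 + tol
  for (nm in c("mufa", "pufa", "sfa")) {
    bad <- which(x[[nm]] > fat_cap)
    if (length(bad) > 0) {
      stop(nm, " exceeds 105% of total_fat at row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(x$added_sugars * grams_per_tsp > x$total_sugars + tol)
  if (length(bad) > 0) {
    stop("added_sugars (in gram terms) exceed total_sugars at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
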