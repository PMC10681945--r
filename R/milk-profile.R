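#' Milk (NFS) nutrient profile
#'
#' The engine of both substitution scenarios: the nutrient content of one
#' cup equivalent of "milk, not further specified" (USDA food code
#' 11100000, an average over fat levels), together with its per-kilocalorie
#' density vector used for isocaloric replacement.
#'
#' @param per_cup Named numeric vector over [nutrient_names()]: nutrient
#'   content of one cup equivalent. Energy must be positive and added
#'   sugars zero (plain milk carries no added sugar).
#' @param grams_per_cup Gram weight of one cup of fluid milk, used only to
#'   report cup equivalents and per-gram densities, never for energy math.
#' @return An object of class `milk_profile`: a list with elements
#'   `per_cup`, `per_kcal` (per_cup scaled by 1/energy, so
#'   `per_kcal["energy"]` is exactly 1), and `grams_per_cup`.
#' @export
#' @examples
#' prof <- default_milk_profile()
#' prof$per_cup[["energy"]]    # kcal in one cup
#' prof$per_kcal[["calcium"]]  # mg calcium per kcal of milk
milk_profile <- function(per_cup, grams_per_cup = 244) {
  per_cup <- per_cup[nutrient_names()]
  if (anyNA(per_cup)) {
    stop("per_cup must name all 18 panel nutrients", call. = FALSE)
  }
  per_cup <- stats::setNames(as.numeric(per_cup), nutrient_names())
  if (per_cup[["energy"]] <= 0) {
    stop("milk profile per-cup energy must be positive", call. = FALSE)
  }
  if (per_cup[["added_sugars"]] != 0) {
    stop("milk (NFS) carries no added sugars; per_cup added_sugars must be 0",
         call. = FALSE)
  }
  validate_nutrients(per_cup)
  per_kcal <- per_cup / per_cup[["energy"]]
  per_kcal[["energy"]] <- 1  # exact, by construction
  structure(
    list(per_cup = per_cup, per_kcal = per_kcal,
         grams_per_cup = grams_per_cup),
    class = "milk_profile"
  )
}

#' @export
print.milk_profile <- function(x, ...) {
  cat("<milk_profile> one cup equivalent =", x$grams_per_cup, "g,",
      x$per_cup[["energy"]], "kcal\n")
  print(round(x$per_cup, 3))
  invisible(x)
}

#' @description `default_milk_profile()` derives the per-cup vector from the
#'   published add-one-cup modeling table: for every nutrient the
#'   adjusted-minus-baseline difference is constant across the three age
#'   groups (the same cup of milk is added to everyone), so the per-cup
#'   content is recovered as the average of the three printed differences.
#'   Dietary fiber and added sugars are identically zero there, consistent
#'   with plain milk.
#' @rdname milk_profile
#' @export
default_milk_profile <- function(grams_per_cup = 244) {
  ref <- reference_milk_addition()
  delta <- ref$adjusted - ref$baseline
  per_cup <- tapply(delta, ref$nutrient, mean)[nutrient_names()]
  per_cup[["added_sugars"]] <- 0
  milk_profile(per_cup, grams_per_cup = grams_per_cup)
}

#' Load a milk profile from a structured config file
#'
#' Reads a YAML file with a `per_cup` mapping over the 18 panel nutrients
#' and an optional `grams_per_cup` scalar, e.g. produced by
#' [write_milk_profile()].
#'
#' @param path Path to a YAML config file, or a list with the same
#'   structure.
#' @return A [milk_profile()].
#' @export
load_milk_profile <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$per_cup)) stop("milk profile config lacks 'per_cup'",
                                 call. = FALSE)
  per_cup <- unlist(cfg$per_cup)
  milk_profile(per_cup,
               grams_per_cup = if (is.null(cfg$grams_per_cup)) 244
                               else cfg$grams_per_cup)
}

#' @param profile A [milk_profile()] to serialize.
#' @rdname load_milk_profile
#' @export
write_milk_profile <- function(profile, path) {
  stopifnot(inherits(profile, "milk_profile"))
  yaml::write_yaml(
    list(per_cup = as.list(profile$per_cup),
         grams_per_cup = profile$grams_per_cup),
    path
  )
  invisible(path)
}
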