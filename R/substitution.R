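# The two substitution scenarios. Both operate on per-subject daily
# nutrient totals; the item table is never rewritten. Scenario 1 adds one
# cup equivalent of milk (NFS) to every diet; scenario 2 removes the
# nutrients of nonmilk caloric beverages consumed at lunch and dinner and
# substitutes an isocaloric amount of milk, so total energy is unchanged
# by construction.

#' Per-subject daily nutrient totals
#'
#' Sums the 18-nutrient panel over all of a subject's items. Subjects in
#' `subject_ids` without items get explicit zero rows.
#'
#' @param items Item table (see [read_items()]).
#' @param subject_ids Subject universe; defaults to subjects present in
#'   `items`.
#' @return Tibble: `subject_id` plus the 18 nutrient columns.
#' @export
daily_totals <- function(items, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- unique(items$subject_id)
  subject_ids <- as.character(subject_ids)
  vals <- as.matrix(items[nutrient_names()])
  out <- matrix(0, length(subject_ids), 18L,
                dimnames = list(subject_ids, nutrient_names()))
  if (nrow(items) > 0) {
    agg <- rowsum(vals, items$subject_id)
    keep <- rownames(agg) %in% subject_ids
    out[rownames(agg)[keep], ] <- agg[keep, , drop = FALSE]
  }
  tibble::as_tibble(cbind(tibble::tibble(subject_id = subject_ids),
                          as.data.frame(out, row.names = NULL)))
}

new_model_result <- function(scenario, baseline, adjusted, replaced_energy,
                             cup_equivalents) {
  structure(
    list(scenario = scenario, baseline = baseline, adjusted = adjusted,
         replaced_energy = replaced_energy,
         cup_equivalents = cup_equivalents),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result>", x$scenario, "-", nrow(x$baseline), "subjects,",
      "mean cup equivalents", format(mean(x$cup_equivalents), digits = 3),
      "\n")
  invisible(x)
}

#' Scenario 1: add one cup of milk to every diet
#'
#' Adds the per-cup nutrient vector of milk (NFS) to each subject's daily
#' totals. No energy is replaced; every subject gains exactly one cup
#' equivalent. Because the same cup is added to every subject, ordinary
#' significance testing is inappropriate and results are judged with the
#' 10% meaningful-change rule ([flag_meaningful_change()]).
#'
#' @param baseline Per-subject totals from [daily_totals()] (or a single
#'   named nutrient vector).
#' @param profile A [milk_profile()].
#' @return A `model_result`: `baseline` and `adjusted` totals tibbles,
#'   `replaced_energy` (all zero) and `cup_equivalents` (all one).
#' @export
add_milk_serving <- function(baseline, profile = default_milk_profile()) {
  stopifnot(inherits(profile, "milk_profile"))
  single <- is.numeric(baseline) && !is.null(names(baseline))
  if (single) {
    baseline <- tibble::as_tibble(c(list(subject_id = "subject"),
                                    as.list(baseline[nutrient_names()])))
  }
  adjusted <- baseline
  for (nm in nutrient_names()) {
    adjusted[[nm]] <- baseline[[nm]] + profile$per_cup[[nm]]
  }
  n <- nrow(baseline)
  new_model_result("add_milk_serving", baseline, adjusted,
                   replaced_energy = rep(0, n),
                   cup_equivalents = rep(1, n))
}

#' Replacement scope
#'
#' Which beverages are eligible for isocaloric replacement. The headline
#' scope `all_caloric` replaces every nonmilk caloric beverage (the
#' caloric-beverages-excluding-milk group, which leaves plain milk,
#' flavored milk and milk substitutes untouched); `ssb_only` and
#' `milk_substitutes_only` make the narrower readings runnable.
#'
#' @param scope One of `"all_caloric"`, `"ssb_only"`,
#'   `"milk_substitutes_only"`.
#' @return A predicate `function(items, map, occasions)` returning the
#'   logical replacement-eligibility vector used to build the replaced set.
#' @export
replacement_scope_select <- function(scope = c("all_caloric", "ssb_only",
                                               "milk_substitutes_only")) {
  scope <- match.arg(scope)
  category <- switch(scope,
    all_caloric = "caloric_bev_excl_milk",
    ssb_only = "ssb",
    milk_substitutes_only = "milk_substitutes"
  )
  function(items, map = beverage_category_map(),
           occasions = occasion_map()) {
    is_meal_beverage(items, map, occasions, category = category)
  }
}

#' Scenario 2: isocaloric replacement of meal beverages with milk
#'
#' For each subject, the nutrients of all replacement-eligible beverages
#' (by default nonmilk caloric beverages consumed at lunch or dinner) are
#' removed from the daily totals and replaced by the nutrients of an
#' isocaloric amount of milk (NFS). Total energy is preserved exactly;
#' subjects with no eligible items are unchanged.
#'
#' @param items Item table.
#' @param profile A [milk_profile()].
#' @param map A [beverage_category_map()].
#' @param occasions An [occasion_map()].
#' @param scope Replacement scope (see [replacement_scope_select()]).
#' @param subject_ids Subject universe for the totals (pass the kept
#'   subject ids).
#' @return A `model_result` with per-subject `baseline`/`adjusted` totals,
#'   `replaced_energy` (kcal) and `cup_equivalents`
#'   (`replaced_energy / per-cup energy`).
#' @export
isocaloric_replace <- function(items, profile = default_milk_profile(),
                               map = beverage_category_map(),
                               occasions = occasion_map(),
                               scope = "all_caloric",
                               subject_ids = NULL) {
  stopifnot(inherits(profile, "milk_profile"))
  baseline <- daily_totals(items, subject_ids)
  eligible <- replacement_scope_select(scope)(items, map, occasions)
  ids <- baseline$subject_id
  removed <- matrix(0, length(ids), 18L,
                    dimnames = list(ids, nutrient_names()))
  if (any(eligible)) {
    agg <- rowsum(as.matrix(items[eligible, nutrient_names()]),
                  items$subject_id[eligible])
    keep <- rownames(agg) %in% ids
    removed[rownames(agg)[keep], ] <- agg[keep, , drop = FALSE]
  }
  E <- removed[, "energy"]
  milk_in <- outer(E, profile$per_kcal[nutrient_names()])
  adjusted <- baseline
  base_m <- as.matrix(baseline[nutrient_names()])
  adj_m <- base_m - removed + milk_in
  # per_kcal energy is exactly 1, so energy is conserved identically
  adj_m[, "energy"] <- base_m[, "energy"]
  for (k in seq_along(nutrient_names())) {
    adjusted[[nutrient_names()[k]]] <- unname(adj_m[, k])
  }
  new_model_result("isocaloric_replace", baseline, adjusted,
                   replaced_energy = unname(E),
                   cup_equivalents = unname(E / profile$per_cup[["energy"]]))
}
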