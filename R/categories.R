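# WWEIA beverage-group classification. Groups overlap by design: a cola is
# at once a soft drink, an SSB, and a caloric beverage; classification
# returns every matching group. The map is data, not code, so the grouping
# can be rerun under alternative readings by editing config only.

#' Beverage category map
#'
#' Rules mapping 4-digit WWEIA category codes to the ten beverage groups
#' used throughout: plain milk (subgroup 10), flavored milk (subgroup 12),
#' milk substitutes (category 1404), 100% fruit juice (subgroup 70), SSBs
#' (subgroup 72) with the soft-drink (7202) and fruit-drink (7204)
#' subcategories, coffee and tea (subgroup 73), and the two umbrella
#' groups: caloric beverages excluding milk (all beverage-range subgroups
#' except diet drinks 71 and waters 77/78) and caloric beverages including
#' milk (the former plus the three milk groups).
#'
#' Each rule matches on the leading 2-digit subgroup (`prefixes`) and/or
#' exact 4-digit categories (`codes`). `excluded_prefixes` lists
#' beverage-range subgroups that are deliberately outside every caloric
#' group; beverage-range codes matching nothing and not excluded trigger a
#' classification warning.
#'
#' @param config Optional list (or YAML path via [load_category_map()])
#'   overriding the default rules; same structure as the returned object.
#' @return A `beverage_category_map`: list with `groups` (named list of
#'   `prefixes`/`codes`), `beverage_range_prefixes`, `excluded_prefixes`.
#' @export
beverage_category_map <- function(config = NULL) {
  caloric_prefixes <- c(70L, 72L, 73L, 74L, 75L, 76L, 79L)
  map <- list(
    groups = list(
      milk = list(prefixes = 10L, codes = integer()),
      flavored_milk = list(prefixes = 12L, codes = integer()),
      milk_substitutes = list(prefixes = integer(), codes = 1404L),
      fruit_juice_100 = list(prefixes = 70L, codes = integer()),
      ssb = list(prefixes = 72L, codes = integer()),
      soft_drinks = list(prefixes = integer(), codes = 7202L),
      fruit_drinks = list(prefixes = integer(), codes = 7204L),
      coffee_tea = list(prefixes = 73L, codes = integer()),
      caloric_bev_excl_milk = list(prefixes = caloric_prefixes,
                                   codes = integer()),
      caloric_bev_incl_milk = list(prefixes = c(caloric_prefixes, 10L, 12L),
                                   codes = 1404L)
    ),
    beverage_range_prefixes = 70:79,
    excluded_prefixes = c(71L, 77L, 78L)
  )
  if (!is.null(config)) map <- utils::modifyList(map, config)
  validate_category_map(map)
  structure(map, class = "beverage_category_map")
}

#' @rdname beverage_category_map
#' @param path YAML file with the map structure above.
#' @export
load_category_map <- function(path) {
  beverage_category_map(yaml::read_yaml(path))
}

#' @export
print.beverage_category_map <- function(x, ...) {
  cat("<beverage_category_map>", length(x$groups), "groups\n")
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf("  %-22s prefixes: %-22s codes: %s\n", g,
                paste(r$prefixes, collapse = ","),
                paste(r$codes, collapse = ",")))
  }
  invisible(x)
}

# Disjointness/nesting checks by exhaustive enumeration of the 4-digit
# code space; cheap and immune to rule-representation subtleties.
validate_category_map <- function(map) {
  codes <- 1000:9999
  m <- membership_matrix(codes, map, warn = FALSE)
  dairy <- c("milk", "flavored_milk", "milk_substitutes")
  if (all(dairy %in% colnames(m))) {
    if (any(rowSums(m[, dairy, drop = FALSE]) > 1)) {
      stop("milk, flavored_milk and milk_substitutes must be pairwise disjoint",
           call. = FALSE)
    }
  }
  nest <- function(sub, super) {
    if (all(c(sub, super) %in% colnames(m)) && any(m[, sub] & !m[, super])) {
      stop("category map: ", sub, " must be a subset of ", super,
           call. = FALSE)
    }
  }
  nest("soft_drinks", "ssb")
  nest("fruit_drinks", "ssb")
  nest("caloric_bev_excl_milk", "caloric_bev_incl_milk")
  for (g in dairy) nest(g, "caloric_bev_incl_milk")
  invisible(TRUE)
}

# Logical matrix: n codes x groups. Central classification primitive.
membership_matrix <- function(wweia_code, map, warn = TRUE) {
  code <- as.integer(wweia_code)
  prefix <- code %/% 100L
  groups <- names(map$groups)
  m <- matrix(FALSE, length(code), length(groups),
              dimnames = list(NULL, groups))
  for (g in groups) {
    rule <- map$groups[[g]]
    m[, g] <- prefix %in% as.integer(rule$prefixes) |
      code %in% as.integer(rule$codes)
  }
  if (warn) {
    unmapped <- prefix %in% as.integer(map$beverage_range_prefixes) &
      !(prefix %in% as.integer(map$excluded_prefixes)) & rowSums(m) == 0
    if (any(unmapped)) {
      warning("unmapped beverage-range WWEIA code(s): ",
              paste(unique(code[unmapped]), collapse = ", "),
              call. = FALSE)
    }
  }
  m
}

#' Classify an item's WWEIA code into beverage groups
#'
#' Returns every group the code belongs to; groups overlap by design (a
#' cola is a soft drink, an SSB, and a caloric beverage both excluding and
#' including milk). Non-beverage codes return an empty set. Beverage-range
#' codes matched by no rule and not deliberately excluded (diet drinks,
#' waters) raise a warning and return the empty set.
#'
#' @param wweia_code 4-digit WWEIA category code (scalar or vector; with a
#'   vector, the union behavior is per-element and a list is returned).
#' @param map A [beverage_category_map()].
#' @return Character vector of group names (or list thereof for vector
#'   input).
#' @export
#' @examples
#' map <- beverage_category_map()
#' classify_item(7202, map)  # cola
#' classify_item(1004, map)  # plain milk
#' classify_item(7102, map)  # diet drink: no caloric group
classify_item <- function(wweia_code, map = beverage_category_map()) {
  m <- membership_matrix(wweia_code, map)
  res <- apply(m, 1L, function(r) colnames(m)[r], simplify = FALSE)
  if (length(wweia_code) == 1L) res[[1L]] else res
}

#' Per-subject daily intake by beverage group
#'
#' Sums grams and the 18-nutrient panel per subject within each beverage
#' group. Every subject in `subject_ids` appears in every group, with
#' explicit zeros for nonconsumers, so per-capita estimates average over
#' consumers and nonconsumers alike.
#'
#' @param items Item table (see [read_items()]).
#' @param map A [beverage_category_map()].
#' @param subject_ids Subject universe; defaults to the subjects present in
#'   `items`. Pass the kept subject table's ids so that recall-free
#'   subjects contribute zeros.
#' @return A tibble with columns `subject_id`, `group`, `grams`, and the 18
#'   nutrient columns; one row per subject per group.
#' @export
per_subject_category_intake <- function(items, map = beverage_category_map(),
                                        subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- unique(items$subject_id)
  subject_ids <- as.character(subject_ids)
  groups <- names(map$groups)
  m <- membership_matrix(items$wweia_code, map)
  vals <- as.matrix(cbind(grams = items$grams, items[nutrient_names()]))
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    zero <- matrix(0, length(subject_ids), ncol(vals),
                   dimnames = list(subject_ids, colnames(vals)))
    sel <- m[, groups[k]]
    if (any(sel)) {
      agg <- rowsum(vals[sel, , drop = FALSE], items$subject_id[sel])
      keep <- rownames(agg) %in% subject_ids
      zero[rownames(agg)[keep], ] <- agg[keep, , drop = FALSE]
    }
    out[[k]] <- tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subject_ids, group = groups[k]),
      as.data.frame(zero, row.names = NULL)
    ))
  }
  do.call(rbind, out)
}

#' Classification audit
#'
#' Item counts, total grams and total energy per beverage group; the audit
#' log written by the pipeline.
#'
#' @inheritParams per_subject_category_intake
#' @return Tibble with one row per group.
#' @export
audit_classification <- function(items, map = beverage_category_map()) {
  m <- membership_matrix(items$wweia_code, map)
  tibble::tibble(
    group = colnames(m),
    n_items = unname(colSums(m)),
    total_grams = as.numeric(crossprod(m, items$grams)),
    total_energy = as.numeric(crossprod(m, items$energy))
  )
}

#' Meal-occasion map
#'
#' Which occasion codes count as lunch and dinner. The defaults cover the
#' English and Spanish NHANES-style occasion labels; `known` lists all
#' occasion codes regarded as valid, and codes outside it are treated as
#' non-meal with a once-per-code note.
#'
#' @param lunch,dinner Integer occasion codes.
#' @param known All valid occasion codes.
#' @return A list with elements `lunch`, `dinner`, `known`.
#' @export
occasion_map <- function(lunch = c(2L, 10L), dinner = c(3L, 4L, 14L),
                         known = 1:15) {
  list(lunch = as.integer(lunch), dinner = as.integer(dinner),
       known = as.integer(known))
}

#' @rdname occasion_map
#' @param path YAML file with `lunch`/`dinner`/`known` entries.
#' @export
load_occasion_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(occasion_map, cfg[intersect(names(cfg),
                                      c("lunch", "dinner", "known"))])
}

#' Is an item a caloric beverage consumed at a meal?
#'
#' TRUE for items whose occasion maps to lunch or dinner, that belong to
#' the replacement category (by default caloric beverages excluding milk),
#' and that carry positive energy — "caloric" is operationalized as energy
#' strictly above 0 kcal, the only non-arbitrary cut. These are the items
#' eligible for isocaloric replacement with milk.
#'
#' @param items Item table.
#' @param map A [beverage_category_map()].
#' @param occasions An [occasion_map()].
#' @param category Beverage group defining replacement eligibility.
#' @return Logical vector along `items` rows.
#' @export
is_meal_beverage <- function(items, map = beverage_category_map(),
                             occasions = occasion_map(),
                             category = "caloric_bev_excl_milk") {
  occ <- as.integer(items$occasion_code)
  unknown <- unique(occ[!(occ %in% occasions$known)])
  if (length(unknown) > 0) {
    message("treating unknown occasion code(s) as non-meal: ",
            paste(sort(unknown), collapse = ", "))
  }
  at_meal <- occ %in% c(occasions$lunch, occasions$dinner)
  in_cat <- membership_matrix(items$wweia_code, map)[, category]
  at_meal & in_cat & items$energy > 0
}
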