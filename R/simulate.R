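# Synthetic NHANES-analog generator. Every estimator in the package is
# exercised against data whose ground truth (category means, age slopes,
# energy shares) is known in closed form; export_truth() writes that truth
# as a machine-readable ledger. Defaults are calibrated once to the
# published child beverage tables: per-capita category means and linear
# age trends match the published LS means and regression coefficients, and
# per-gram nutrient densities are set so that caloric beverages carry
# about 18% of daily energy.

#' Default beverage categories for the generator
#'
#' Per-capita consumption model and per-gram nutrient densities for eight
#' beverage categories. `mean_g_age6` and `slope_g_per_y` describe the
#' linear per-capita mean grams across ages 6-18 (so the slope is exactly
#' what trend regression should recover); `prob` is the daily probability
#' of consuming the category, constant in age. The milk density row is the
#' milk-NFS profile scaled to grams.
#'
#' @param profile [milk_profile()] used for the plain-milk density row.
#' @return Tibble: `category`, `wweia_code`, `food_code`, `prob`,
#'   `mean_g_age6`, `slope_g_per_y`, and one density column per panel
#'   nutrient (`d_energy`, ..., units per gram).
#' @export
default_generator_categories <- function(profile = default_milk_profile()) {
  base <- tibble::tibble(
    category = c("milk", "flavored_milk", "milk_substitutes",
                 "fruit_juice_100", "soft_drinks", "fruit_drinks",
                 "sports_energy", "coffee_tea"),
    wweia_code = c(1002L, 1202L, 1404L, 7002L, 7202L, 7204L, 7206L, 7302L),
    food_code = c(11100000, 11511100, 11320000, 61210000, 92410310,
                  92510610, 95310555, 92101000),
    prob = c(0.60, 0.25, 0.03, 0.40, 0.50, 0.45, 0.08, 0.30),
    mean_g_age6 = c(212.6, 97.9, 3.8, 94.6, 97.7, 123.6, 15.9, 20.5),
    slope_g_per_y = c(-2.64, -6.21, -0.01, -0.23, 25.3, 1.42, 4.08, 13.1)
  )
  dens <- rbind(
    milk = profile$per_cup[nutrient_names()] / profile$grams_per_cup,
    flavored_milk = c(0.78, 0.1066, 0, 0.0984, 0.0132, 0.0328, 0.0143,
                      0.004, 0.0012, 0.0087, 1.15, 0.135, 1.37, 0.68,
                      0.42, 0.05, 0.0044, 0.0114),
    milk_substitutes = c(0.30, 0.035, 0.002, 0.025, 0.004, 0.012, 0.012,
                         0.006, 0.003, 0.002, 1.2, 0.07, 0.5, 0.6, 0.4,
                         0.01, 0.004, 0.0105),
    fruit_juice_100 = c(0.45, 0.104, 0.002, 0.084, 0, 0.007, 0.002, 0, 0,
                        0, 0.11, 0.11, 2.0, 0.04, 0.01, 0.30, 0, 0),
    soft_drinks = c(0.41, 0.106, 0, 0.105, 0.0248, 0, 0, 0, 0, 0, 0.02,
                    0.01, 0.07, 0.04, 0, 0, 0, 0),
    fruit_drinks = c(0.44, 0.112, 0, 0.108, 0.0248, 0, 0, 0, 0, 0, 0.04,
                     0.02, 0.15, 0.10, 0.01, 0.02, 0, 0),
    sports_energy = c(0.26, 0.068, 0, 0.059, 0.0138, 0, 0, 0, 0, 0, 0.01,
                      0.01, 0.12, 0.40, 0, 0, 0, 0),
    coffee_tea = c(0.18, 0.045, 0, 0.042, 0.009, 0.003, 0.003, 0.001,
                   0.0005, 0.0018, 0.10, 0.03, 0.30, 0.10, 0, 0.01, 0, 0)
  )
  colnames(dens) <- paste0("d_", nutrient_names())
  cbind(base, tibble::as_tibble(as.data.frame(dens, row.names = NULL)))
}

#' Generator specification
#'
#' All knobs of the synthetic population and recall generator, with
#' defaults calibrated to published NHANES 2001-2018 child demographics
#' and beverage tables.
#'
#' @param n_subjects Number of children to generate.
#' @param n_strata,psus_per_stratum Sampling structure; PSUs are nested in
#'   strata and at least two per stratum are required.
#' @param weight_meanlog,weight_sdlog Lognormal day-1 weight parameters.
#' @param ages,age_probs Support and probabilities of integer age (years).
#' @param p_male Probability of male sex.
#' @param ethnicity_probs,pir_probs,activity_probs,weight_status_probs
#'   Named category probabilities (must each sum to 1).
#' @param prop_pregnant Overall expected fraction flagged pregnant or
#'   lactating (realized among females aged 12 and over).
#' @param prop_unreliable Expected fraction with unreliable recalls.
#' @param categories Beverage consumption model, see
#'   [default_generator_categories()].
#' @param occasion_probs Named probabilities over occasion codes for
#'   beverage items (defaults: breakfast 1, lunch 2, dinner 3, snack 6).
#' @param gamma_shape Gamma shape of the consumed-amount noise
#'   (right-skewed, strictly nonnegative grams).
#' @param rest_energy_age6,rest_energy_slope,rest_gamma_shape Energy (kcal)
#'   of the single composite rest-of-diet item: mean at age 6, change per
#'   year, and gamma shape.
#' @param rest_density Per-kcal nutrient densities of the rest of diet
#'   (named over the panel; energy component must be 1).
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(
    n_subjects = 5000,
    n_strata = 15,
    psus_per_stratum = 2,
    weight_meanlog = log(1000),
    weight_sdlog = 0.5,
    ages = 6:18,
    age_probs = rep(1 / 13, 13),
    p_male = 0.51,
    ethnicity_probs = c("Mexican American" = 0.14, "Other Hispanic" = 0.065,
                        "NH White" = 0.57, "NH Black" = 0.14,
                        "Other" = 0.085),
    pir_probs = c("<1.35" = 0.33, "1.35-1.85" = 0.11, ">1.85" = 0.56),
    activity_probs = c(sedentary = 0.14, moderate = 0.23, vigorous = 0.63),
    weight_status_probs = c(under = 0.035, normal = 0.62, over = 0.16,
                            obese = 0.185),
    prop_pregnant = 0.004,
    prop_unreliable = 0.203,
    categories = default_generator_categories(),
    occasion_probs = c("1" = 0.35, "2" = 0.13, "3" = 0.12, "6" = 0.40),
    gamma_shape = 1.5,
    rest_energy_age6 = 1506,
    rest_energy_slope = 27.9,
    rest_gamma_shape = 25,
    rest_density = NULL) {
  if (psus_per_stratum < 2) {
    stop("psus_per_stratum must be at least 2", call. = FALSE)
  }
  if (is.null(rest_density)) {
    rest_density <- stats::setNames(
      c(1, 0.1254, 0.00806, 0.0449, 0.00728, 0.0345, 0.04135, 0.01493,
        0.00909, 0.01374, 0.386, 0.1104, 0.9368, 1.755, 0.283, 0.3181,
        0.00214, 0.00134),
      nutrient_names()
    )
  }
  spec <- list(
    n_subjects = as.integer(n_subjects), n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    ages = as.integer(ages), age_probs = age_probs, p_male = p_male,
    ethnicity_probs = ethnicity_probs, pir_probs = pir_probs,
    activity_probs = activity_probs,
    weight_status_probs = weight_status_probs,
    prop_pregnant = prop_pregnant, prop_unreliable = prop_unreliable,
    categories = categories, occasion_probs = occasion_probs,
    gamma_shape = gamma_shape,
    rest_energy_age6 = rest_energy_age6,
    rest_energy_slope = rest_energy_slope,
    rest_gamma_shape = rest_gamma_shape,
    rest_density = rest_density
  )
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  check_probs <- function(p, what, sum_to_one = TRUE) {
    if (any(p < 0 | p > 1)) stop(what, " probabilities must lie in [0,1]",
                                 call. = FALSE)
    if (sum_to_one && abs(sum(p) - 1) > 1e-8) {
      stop(what, " probabilities must sum to 1", call. = FALSE)
    }
  }
  check_probs(spec$age_probs, "age")
  check_probs(spec$ethnicity_probs, "ethnicity")
  check_probs(spec$pir_probs, "PIR")
  check_probs(spec$activity_probs, "physical activity")
  check_probs(spec$weight_status_probs, "weight status")
  check_probs(spec$occasion_probs, "occasion")
  check_probs(c(spec$p_male, spec$prop_pregnant, spec$prop_unreliable,
                spec$categories$prob), "consumption/flag", sum_to_one = FALSE)
  dens <- as.matrix(spec$categories[paste0("d_", nutrient_names())])
  if (any(dens < 0)) stop("nutrient densities must be nonnegative",
                          call. = FALSE)
  age_span <- range(spec$ages)
  m_lo <- spec$categories$mean_g_age6 +
    spec$categories$slope_g_per_y * (age_span[1] - 6)
  m_hi <- spec$categories$mean_g_age6 +
    spec$categories$slope_g_per_y * (age_span[2] - 6)
  if (any(pmin(m_lo, m_hi) < 0)) {
    stop("implied per-capita category means must stay nonnegative over ",
         "the age range", call. = FALSE)
  }
  invisible(TRUE)
}

sample_cat <- function(n, probs) {
  if (n == 0) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic subject table
#'
#' Balanced round-robin assignment to strata and PSUs, lognormal day-1
#' weights, categorical demographics drawn from the spec probabilities,
#' and pregnancy/unreliable-recall flags at the configured rates (the
#' pregnancy flag is realized among females aged 12+, scaled so the
#' overall expected fraction equals `prop_pregnant`). Fully reproducible
#' given the seed.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer RNG seed.
#' @return Subject tibble in the [read_subjects()] schema.
#' @export
generate_population <- function(spec = generator_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n_subjects
  if (n == 0) {
    return(read_subjects_template())
  }
  i <- seq_len(n) - 1L
  stratum <- sprintf("ST%02d", (i %% spec$n_strata) + 1L)
  psu <- sprintf("P%d", ((i %/% spec$n_strata) %% spec$psus_per_stratum) + 1L)
  age <- sample(spec$ages, n, replace = TRUE, prob = spec$age_probs)
  sex <- ifelse(runif(n) < spec$p_male, "male", "female")
  preg_eligible <- sex == "female" & age >= 12
  p_elig <- (1 - spec$p_male) * sum(spec$age_probs[spec$ages >= 12])
  preg_rate <- min(1, spec$prop_pregnant / max(p_elig, 1e-12))
  pregnant <- preg_eligible & runif(n) < preg_rate
  tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    age_years = as.numeric(age),
    sex = sex,
    ethnicity = sample_cat(n, spec$ethnicity_probs),
    pir_level = sample_cat(n, spec$pir_probs),
    physical_activity = sample_cat(n, spec$activity_probs),
    weight_status = sample_cat(n, spec$weight_status_probs),
    pregnant_or_lactating = pregnant,
    recall_reliable = runif(n) >= spec$prop_unreliable,
    day1_weight = rlnorm(n, spec$weight_meanlog, spec$weight_sdlog),
    stratum_id = stratum,
    psu_id = psu
  )
}

read_subjects_template <- function() {
  tibble::tibble(
    subject_id = character(), age_years = numeric(), sex = character(),
    ethnicity = character(), pir_level = character(),
    physical_activity = character(), weight_status = character(),
    pregnant_or_lactating = logical(), recall_reliable = logical(),
    day1_weight = numeric(), stratum_id = character(), psu_id = character()
  )
}

#' Generate synthetic 24-h recall items
#'
#' Per subject and beverage category: Bernoulli daily consumption, a
#' gamma-distributed amount around the age-linear per-capita mean (divided
#' by the consumption probability), nutrients proportional to grams via
#' the category density vector, and a meal occasion drawn from the
#' allocation probabilities. A single composite "rest of diet" item per
#' subject carries the age-trended remainder of daily energy so that total
#' intake and contribution denominators are realistic.
#'
#' @param subjects Subject table, e.g. from [generate_population()].
#' @param spec A [generator_spec()].
#' @param seed Integer RNG seed.
#' @return Item tibble in the [read_items()] schema.
#' @export
generate_recalls <- function(subjects, spec = generator_spec(), seed = 1) {
  set.seed(seed)
  n <- nrow(subjects)
  age <- subjects$age_years
  occ_codes <- as.integer(names(spec$occasion_probs))
  dens_cols <- paste0("d_", nutrient_names())
  parts <- vector("list", nrow(spec$categories) + 1L)
  for (k in seq_len(nrow(spec$categories))) {
    cat_k <- spec$categories[k, ]
    m <- pmax(0, cat_k$mean_g_age6 + cat_k$slope_g_per_y * (age - 6))
    consume <- rbinom(n, 1L, cat_k$prob) == 1L & m > 0
    nk <- sum(consume)
    if (nk == 0) next
    cond_mean <- m[consume] / cat_k$prob
    grams <- rgamma(nk, shape = spec$gamma_shape,
                    scale = cond_mean / spec$gamma_shape)
    occasion <- sample(occ_codes, nk, replace = TRUE,
                       prob = spec$occasion_probs)
    nut <- outer(grams, as.numeric(cat_k[1, dens_cols]))
    colnames(nut) <- nutrient_names()
    parts[[k]] <- tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subjects$subject_id[consume],
                     food_code = cat_k$food_code,
                     wweia_code = cat_k$wweia_code,
                     occasion_code = occasion, grams = grams),
      as.data.frame(nut, row.names = NULL)
    ))
  }
  if (n > 0) {
    rest_mean <- pmax(0, spec$rest_energy_age6 +
                        spec$rest_energy_slope * (age - 6))
    energy <- rgamma(n, shape = spec$rest_gamma_shape,
                     scale = rest_mean / spec$rest_gamma_shape)
    nut <- outer(energy, spec$rest_density[nutrient_names()])
    colnames(nut) <- nutrient_names()
    parts[[length(parts)]] <- tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subjects$subject_id,
                     food_code = 99999999, wweia_code = 9006L,
                     occasion_code = 3L, grams = energy / 1.5),
      as.data.frame(nut, row.names = NULL)
    ))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    out <- tibble::tibble(subject_id = character(), food_code = numeric(),
                          wweia_code = integer(), occasion_code = integer(),
                          grams = numeric())
    for (nm in nutrient_names()) out[[nm]] <- numeric()
    return(out)
  }
  do.call(rbind, parts)
}

#' Truth ledger of a generator spec
#'
#' The exact population quantities implied by the spec, for
#' parameter-recovery testing: per-category consumption probability,
#' per-capita mean grams at age 6, linear slope (grams per year of age),
#' mean grams per age group and overall; mean daily energy from caloric
#' beverages including and excluding milk, rest-of-diet and total energy;
#' the energy shares (percent) of both umbrella beverage groups; and the
#' expected replaced energy and cup equivalents under meal replacement.
#' All values follow in closed form from the linear consumption model and
#' the age distribution; sampling weights are independent of intake, so
#' weighted estimators converge to the same truths.
#'
#' @param spec A [generator_spec()].
#' @return A nested list (class `generator_truth`).
#' @export
export_truth <- function(spec = generator_spec()) {
  age_mean_over <- function(ages_in) {
    p <- spec$age_probs[match(ages_in, spec$ages)]
    sum(ages_in * p) / sum(p)
  }
  groups <- list("6-8" = 6:8, "9-13" = 9:13, "14-18" = 14:18)
  mean_g_at <- function(cat_row, a) {
    pmax(0, cat_row$mean_g_age6 + cat_row$slope_g_per_y * (a - 6))
  }
  cats <- spec$categories
  per_cat <- lapply(seq_len(nrow(cats)), function(k) {
    row <- cats[k, ]
    by_group <- lapply(groups, function(g) mean_g_at(row, age_mean_over(g)))
    overall <- mean_g_at(row, age_mean_over(spec$ages))
    list(prob = row$prob, mean_g_age6 = row$mean_g_age6,
         slope_g_per_y = row$slope_g_per_y,
         mean_grams_by_age_group = by_group,
         mean_grams_overall = overall,
         mean_energy_overall = overall * row$d_energy)
  })
  names(per_cat) <- cats$category
  milk_groups <- intersect(c("milk", "flavored_milk", "milk_substitutes"),
                           names(per_cat))
  e_all <- sum(vapply(per_cat, `[[`, numeric(1), "mean_energy_overall"))
  e_milk <- sum(vapply(per_cat[milk_groups], `[[`, numeric(1),
                       "mean_energy_overall"))
  e_excl <- e_all - e_milk
  rest_energy <- spec$rest_energy_age6 +
    spec$rest_energy_slope * (age_mean_over(spec$ages) - 6)
  total_energy <- e_all + rest_energy
  meal_share <- sum(spec$occasion_probs[as.character(c(2L, 3L))], na.rm = TRUE)
  milk_kcal_per_cup <- default_milk_profile()$per_cup[["energy"]]
  structure(list(
    categories = per_cat,
    energy = list(
      caloric_bev_incl_milk = e_all,
      caloric_bev_excl_milk = e_excl,
      rest_of_diet = rest_energy,
      total = total_energy,
      share_incl_milk_pct = 100 * e_all / total_energy,
      share_excl_milk_pct = 100 * e_excl / total_energy
    ),
    replacement = list(
      meal_occasion_share = meal_share,
      expected_replaced_energy = meal_share * e_excl,
      expected_cup_equivalents = meal_share * e_excl / milk_kcal_per_cup
    )
  ), class = "generator_truth")
}

#' @rdname export_truth
#' @param truth A `generator_truth` object.
#' @param path YAML destination (or source) path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path, precision = 15)
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  structure(yaml::read_yaml(path), class = "generator_truth")
}
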