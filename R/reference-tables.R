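#' Published NHANES 2001-2018 reference estimates (children 6-18 y)
#'
#' Survey-weighted least-squares mean beverage intakes (g/d) by age group,
#' with the age-trend regression coefficient (g/d per year of age), from
#' published analyses of NHANES/WWEIA 2001-2018 day-1 recalls in children.
#' These values serve two purposes: they are the calibration targets for the
#' synthetic-data generator defaults, and they are the inputs to the printed
#' percent-change cross-checks (see [percent_change()]).
#'
#' @return A tibble with columns `quantity`, `age_6_8`, `age_9_13`,
#'   `age_14_18` (LS means), `beta` and `beta_se` (linear age trend and its
#'   SE), and `p_trend`.
#' @seealso [reference_caloric_nutrients()], [reference_milk_addition()],
#'   [reference_milk_replacement()]
#' @export
reference_beverage_means <- function() {
  tibble::tibble(
    quantity = c(
      "energy", "milk", "flavored_milk", "milk_substitutes",
      "caloric_bev_incl_milk", "caloric_bev_excl_milk", "fruit_juice_100",
      "soft_drinks", "ssb", "fruit_drinks", "coffee_tea"
    ),
    age_6_8   = c(1869, 210, 91.7, 3.83, 702, 396, 94.4, 123, 268, 125, 33.6),
    age_9_13  = c(2029, 208, 61.1, 2.23, 782, 511, 76.5, 211, 370, 123, 64.1),
    age_14_18 = c(2209, 190, 34.9, 3.18, 1004, 776, 84.9, 350, 546, 136, 145),
    beta      = c(35.9, -2.64, -6.21, -0.01, 34.8, 43.7, -0.23, 25.3, 30.8,
                  1.42, 13.1),
    beta_se   = c(2.5, 0.79, 0.45, 0.11, 2.1, 2.1, 0.66, 1.4, 1.6, 0.72, 1.2),
    p_trend   = c(1e-4, 0.0010, 1e-4, 0.8962, 1e-4, 1e-4, 0.7334, 1e-4, 1e-4,
                  0.0507, 1e-4)
  )
}

#' @description `reference_caloric_nutrients()` gives the corresponding LS
#'   means of daily nutrient intake contributed by caloric beverages
#'   including milk, with age-trend coefficients.
#' @rdname reference_beverage_means
#' @export
reference_caloric_nutrients <- function() {
  tibble::tibble(
    nutrient = nutrient_names(),
    age_6_8   = c(335, 60.7, 0.74, 56.1, 7.04, 10.4, 6.17, 1.60, 0.35, 3.62,
                  408, 50.6, 658, 190, 169, 26.0, 1.40, 3.76),
    age_9_13  = c(343, 65.8, 0.57, 61.3, 9.11, 9.46, 5.35, 1.39, 0.29, 3.12,
                  370, 46.6, 596, 183, 153, 25.5, 1.31, 3.36),
    age_14_18 = c(402, 83.5, 0.52, 77.8, 13.2, 8.44, 4.78, 1.22, 0.28, 2.68,
                  326, 47.7, 587, 185, 134, 29.0, 1.38, 2.87),
    beta      = c(8.00, 2.67, -0.02, 2.51, 0.70, -0.22, -0.15, -0.04, -0.01,
                  -0.11, -9.09, -0.24, -6.82, -0.63, -3.91, 0.42, 0.002, -0.10),
    beta_se   = c(0.87, 0.20, 0.004, 0.19, 0.04, 0.03, 0.02, 0.005, 0.001,
                  0.01, 1.07, 0.11, 1.60, 0.50, 0.48, 0.12, 0.01, 0.01)
  )
}

# Printed decimal places for the modeling tables, per nutrient row; used to
# express "one unit of the last printed digit" tolerances in cross-checks.
reference_table_decimals <- function() {
  stats::setNames(
    c(0, 0, 1, 0, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 2, 2),
    nutrient_names()
  )
}

#' @description `reference_milk_addition()` gives baseline and adjusted LS
#'   means of total daily nutrient intake per age group under the
#'   add-one-cup-of-milk scenario, and `reference_milk_replacement()` the
#'   analogous pairs under isocaloric replacement of caloric beverages at
#'   lunch and dinner with milk. `decimals` records the printed precision of
#'   each row (baseline/adjusted share it), defining the "one unit of the
#'   last printed digit" tolerance for arithmetic cross-checks.
#' @rdname reference_beverage_means
#' @export
reference_milk_addition <- function() {
  long <- function(age_group, baseline, adjusted) {
    tibble::tibble(
      nutrient = nutrient_names(), age_group = age_group,
      baseline = baseline, adjusted = adjusted,
      decimals = unname(reference_table_decimals())
    )
  }
  rbind(
    long("6-8",
         c(1869, 253, 13.1, 125, 18.2, 63.3, 69.6, 24.5, 14.3, 24.7,
           1000, 220, 2095, 2882, 603, 514, 4.68, 5.82),
         c(1991, 265, 13.1, 137, 18.2, 71.4, 74.4, 25.8, 14.6, 27.6,
           1291, 247, 2453, 2985, 727, 525, 5.82, 8.81)),
    long("9-13",
         c(2028, 270, 14.3, 129, 20.3, 71.1, 76.4, 27.0, 16.0, 26.8,
           1024, 237, 2207, 3244, 613, 546, 4.97, 5.55),
         c(2150, 282, 14.3, 142, 20.3, 79.2, 81.2, 28.3, 16.2, 29.7,
           1314, 265, 2565, 3347, 737, 558, 6.11, 8.54)),
    long("14-18",
         c(2209, 288, 14.3, 140, 23.6, 79.8, 83.3, 29.7, 17.9, 28.4,
           1032, 255, 2349, 3596, 573, 564, 5.36, 5.19),
         c(2331, 300, 14.3, 153, 23.6, 87.8, 88.1, 31.0, 18.1, 31.3,
           1322, 282, 2707, 3699, 696, 575, 6.50, 8.18))
  )
}

#' @rdname reference_beverage_means
#' @export
reference_milk_replacement <- function() {
  long <- function(age_group, baseline, adjusted) {
    tibble::tibble(
      nutrient = nutrient_names(), age_group = age_group,
      baseline = baseline, adjusted = adjusted,
      decimals = unname(reference_table_decimals())
    )
  }
  rbind(
    long("6-8",
         c(1869, 253, 13.1, 125, 18.2, 63.3, 69.6, 24.5, 14.3, 24.7,
           1000, 220, 2095, 2882, 603, 514, 4.68, 5.82),
         c(1869, 245, 13.0, 118, 15.9, 66.9, 71.7, 25.1, 14.4, 26.0,
           1120, 228, 2203, 2915, 657, 516, 5.19, 7.17)),
    long("9-13",
         c(2028, 270, 14.3, 129, 20.3, 71.1, 76.4, 27.0, 16.0, 26.8,
           1024, 237, 2207, 3244, 613, 546, 4.97, 5.55),
         c(2028, 261, 14.2, 122, 17.5, 75.0, 78.7, 27.6, 16.1, 28.3,
           1157, 247, 2339, 3280, 672, 549, 5.52, 7.02)),
    long("14-18",
         c(2209, 288, 14.3, 140, 23.6, 79.8, 83.3, 29.7, 17.9, 28.4,
           1032, 255, 2349, 3596, 573, 564, 5.36, 5.19),
         c(2209, 278, 14.2, 132, 20.4, 83.9, 85.8, 30.4, 18.0, 30.0,
           1178, 265, 2494, 3635, 638, 567, 5.93, 6.78))
  )
}
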