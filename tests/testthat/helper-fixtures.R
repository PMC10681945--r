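# Fixture builders. All synthetic; nothing is read from disk unless a test
# writes it first.

nv <- function(...) {
  out <- stats::setNames(numeric(18), nutrient_names())
  args <- list(...)
  out[names(args)] <- unlist(args)
  out
}

make_subject <- function(subject_id = "S1", age_years = 10, sex = "male",
                         ethnicity = "NH White", pir_level = ">1.85",
                         physical_activity = "vigorous",
                         weight_status = "normal",
                         pregnant_or_lactating = FALSE,
                         recall_reliable = TRUE, day1_weight = 1,
                         stratum_id = "A", psu_id = "P1") {
  tibble::tibble(
    subject_id = subject_id, age_years = age_years, sex = sex,
    ethnicity = ethnicity, pir_level = pir_level,
    physical_activity = physical_activity, weight_status = weight_status,
    pregnant_or_lactating = pregnant_or_lactating,
    recall_reliable = recall_reliable, day1_weight = day1_weight,
    stratum_id = stratum_id, psu_id = psu_id
  )
}

make_item <- function(subject_id = "S1", wweia_code = 7202,
                      occasion_code = 2, grams = 100,
                      food_code = 92410310, ...) {
  nut <- nv(...)
  tibble::as_tibble(c(
    list(subject_id = subject_id, food_code = food_code,
         wweia_code = wweia_code, occasion_code = occasion_code,
         grams = grams),
    as.list(nut)
  ))
}

# a cola-like item: energy/sugars scale with grams
cola_item <- function(subject_id = "S1", grams = 300, occasion_code = 2) {
  make_item(subject_id, wweia_code = 7202, occasion_code = occasion_code,
            grams = grams, energy = 0.41 * grams,
            carbohydrate = 0.106 * grams, total_sugars = 0.105 * grams,
            added_sugars = 0.0248 * grams, sodium = 0.04 * grams)
}

milk_item <- function(subject_id = "S1", grams = 244, occasion_code = 1) {
  prof <- default_milk_profile()
  dens <- prof$per_cup / prof$grams_per_cup
  args <- c(list(subject_id = subject_id, wweia_code = 1002,
                 occasion_code = occasion_code, grams = grams,
                 food_code = 11100000),
            as.list(dens * grams))
  do.call(make_item, args)
}

# small stratified design: H strata x P psus x k subjects, weights drawn
# lognormal under the caller's RNG state
random_design_data <- function(H = 3, P = 2, k = 4) {
  st <- rep(seq_len(H), each = P * k)
  psu <- rep(rep(seq_len(P), each = k), times = H)
  n <- H * P * k
  list(y = rnorm(n, 10, 3), w = rlnorm(n, 0, 0.5), strata = st, psu = psu)
}

# strata/psu assignment where every stratum really contains P PSUs
lattice_strata <- function(n, H = 4, P = 2) {
  i <- seq_len(n) - 1L
  list(strata = (i %% H) + 1L, psu = ((i %/% H) %% P) + 1L)
}
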