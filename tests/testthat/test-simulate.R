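test_that("generation is deterministic given the seed", {
  spec <- generator_spec(n_subjects = 500)
  s1 <- generate_population(spec, 7)
  s2 <- generate_population(spec, 7)
  expect_identical(s1, s2)
  i1 <- generate_recalls(s1, spec, 8)
  i2 <- generate_recalls(s2, spec, 8)
  expect_identical(i1, i2)
  expect_false(identical(i1, generate_recalls(s1, spec, 9)))
})

test_that("degenerate sizes are handled", {
  spec0 <- generator_spec(n_subjects = 0)
  expect_equal(nrow(generate_population(spec0, 1)), 0L)
  expect_error(generator_spec(psus_per_stratum = 1), "at least 2")
})

test_that("generated items satisfy the nutrient invariants", {
  spec <- generator_spec(n_subjects = 800)
  items <- generate_recalls(generate_population(spec, 3), spec, 4)
  expect_silent(validate_nutrients(items))
  expect_true(all(items$grams >= 0))
})

test_that("demographic and flag fractions hit their settings", {
  spec <- generator_spec(n_subjects = 8000)
  subj <- generate_population(spec, 5)
  d <- subject_design(subj)
  male <- sum(d$w * (subj$sex == "male")) / sum(d$w)
  expect_lt(abs(male - spec$p_male),
            3 * sqrt(spec$p_male * (1 - spec$p_male) / nrow(subj)))
  preg <- mean(subj$pregnant_or_lactating)
  expect_lt(abs(preg - spec$prop_pregnant),
            3 * sqrt(spec$prop_pregnant * (1 - spec$prop_pregnant) /
                       nrow(subj)))
  unrel <- mean(!subj$recall_reliable)
  expect_lt(abs(unrel - spec$prop_unreliable),
            3 * sqrt(spec$prop_unreliable * (1 - spec$prop_unreliable) /
                       nrow(subj)))
})

test_that("a category with zero consumption probability yields no items", {
  spec <- generator_spec(n_subjects = 300)
  spec$categories$prob[spec$categories$category == "soft_drinks"] <- 0
  items <- generate_recalls(generate_population(spec, 2), spec, 2)
  expect_false(any(items$wweia_code == 7202))
})

test_that("weighted sample moments converge to the ledger truths", {
  spec <- generator_spec(n_subjects = 50000)
  subj <- generate_population(spec, 12)
  items <- generate_recalls(subj, spec, 13)
  truth <- export_truth(spec)
  d <- subject_design(subj)
  for (cat in c("milk", "soft_drinks", "coffee_tea")) {
    code <- spec$categories$wweia_code[spec$categories$category == cat]
    g <- stats::setNames(rep(0, nrow(subj)), subj$subject_id)
    sums <- rowsum(items$grams[items$wweia_code == code],
                   items$subject_id[items$wweia_code == code])
    g[rownames(sums)] <- sums
    est <- sum(d$w * g) / sum(d$w)
    expect_lt(abs(est - truth$categories[[cat]]$mean_grams_overall) /
                truth$categories[[cat]]$mean_grams_overall, 0.02)
  }
})

test_that("the truth ledger carries the configured slopes and round-trips", {
  spec <- generator_spec()
  truth <- export_truth(spec)
  expect_equal(truth$categories$flavored_milk$slope_g_per_y, -6.21)
  # ledger slope equals the closed-form derivative of the per-capita mean
  fm <- truth$categories$flavored_milk
  m <- function(a) fm$mean_g_age6 + fm$slope_g_per_y * (a - 6)
  expect_equal(fm$slope_g_per_y, m(11) - m(10), tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$categories$flavored_milk$slope_g_per_y, -6.21)
  expect_equal(back$energy$share_incl_milk_pct,
               truth$energy$share_incl_milk_pct, tolerance = 1e-9)
})

test_that("trend regression recovers a configured decline in one draw", {
  spec <- generator_spec(n_subjects = 5000)
  subj <- generate_population(spec, 42)
  items <- generate_recalls(subj, spec, 43)
  g <- stats::setNames(rep(0, nrow(subj)), subj$subject_id)
  sums <- rowsum(items$grams[items$wweia_code == 1202],
                 items$subject_id[items$wweia_code == 1202])
  g[rownames(sums)] <- sums
  fit <- trend_regression(unname(g), subj$age_years, subject_design(subj),
                          data.frame(sex = subj$sex,
                                     ethnicity = subj$ethnicity,
                                     pir_level = subj$pir_level))
  expect_lt(abs(fit$beta - (-6.21)), 3 * fit$se)
})

test_that("a constructed energy share is reproduced by the ratio estimator", {
  # shrink to one beverage and a rest-of-diet tuned so beverages carry
  # exactly 20% of expected energy at every age
  spec <- generator_spec(n_subjects = 20000)
  spec$categories <- spec$categories[spec$categories$category ==
                                       "soft_drinks", ]
  spec$categories$mean_g_age6 <- 200
  spec$categories$slope_g_per_y <- 0
  bev_e <- 200 * spec$categories$d_energy  # 82 kcal at all ages
  spec$rest_energy_age6 <- 4 * bev_e
  spec$rest_energy_slope <- 0
  truth <- export_truth(spec)
  expect_equal(truth$energy$share_excl_milk_pct, 20, tolerance = 1e-9)
  subj <- generate_population(spec, 9)
  items <- generate_recalls(subj, spec, 10)
  kept <- subj
  intake <- per_subject_category_intake(items, beverage_category_map(),
                                        kept$subject_id)
  excl <- intake[intake$group == "caloric_bev_excl_milk", ]
  excl <- excl[match(kept$subject_id, excl$subject_id), ]
  totals <- daily_totals(items, kept$subject_id)
  pr <- population_ratio(excl$energy, totals$energy, subject_design(kept))
  expect_lt(abs(pr$estimate - 20), 4 * pr$se + 0.25)
})
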