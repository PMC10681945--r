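prof <- default_milk_profile()
map <- beverage_category_map()

test_that("adding a cup of milk shifts every nutrient by the per-cup vector", {
  base <- nv(energy = 1869, vitamin_d = 5.82, calcium = 1032)
  res <- add_milk_serving(base, prof)
  expect_equal(res$adjusted$vitamin_d, 8.81, tolerance = 1e-9)
  expect_equal(res$adjusted$calcium, 1322, tolerance = 0.5)
  expect_equal(res$replaced_energy, 0)
  expect_equal(res$cup_equivalents, 1)

  zero <- add_milk_serving(nv(), prof)
  got <- unlist(zero$adjusted[nutrient_names()])
  expect_equal(unname(got), unname(prof$per_cup))

  totals <- daily_totals(rbind(cola_item("S1"), milk_item("S2")))
  res2 <- add_milk_serving(totals, prof)
  for (nm in nutrient_names()) {
    expect_equal(res2$adjusted[[nm]] - res2$baseline[[nm]],
                 rep(prof$per_cup[[nm]], 2), tolerance = 1e-12)
  }
})

test_that("isocaloric replacement swaps a lunch cola for milk nutrients", {
  # one 122-kcal cola at lunch plus a fixed rest-of-diet item
  cola <- cola_item("S1", grams = 122 / 0.41, occasion_code = 2)
  rest <- make_item("S1", wweia_code = 9006, occasion_code = 3,
                    grams = 500, energy = 1500, protein = 50,
                    added_sugars = 2, total_sugars = 40, calcium = 600,
                    total_fat = 60, sfa = 20)
  res <- isocaloric_replace(rbind(cola, rest), prof, map)
  expect_equal(res$replaced_energy, 122)
  expect_equal(res$cup_equivalents, 1, tolerance = 1e-12)
  # energy unchanged; added sugars lose the cola's tsp; protein gains a cup
  expect_identical(res$adjusted$energy, res$baseline$energy)
  expect_equal(res$baseline$added_sugars - res$adjusted$added_sugars,
               0.0248 * 122 / 0.41, tolerance = 1e-9)
  expect_equal(res$adjusted$protein - res$baseline$protein,
               prof$per_cup[["protein"]], tolerance = 1e-9)
  expect_equal(res$adjusted$calcium - res$baseline$calcium,
               prof$per_cup[["calcium"]], tolerance = 1e-9)
})

test_that("breakfast-only drinkers and milk-at-lunch are untouched", {
  bfast <- rbind(cola_item("S1", occasion_code = 1),
                 milk_item("S2", occasion_code = 2))
  res <- isocaloric_replace(bfast, prof, map)
  expect_equal(res$adjusted, res$baseline)
  expect_equal(res$replaced_energy, c(0, 0))
})

test_that("energy is conserved exactly across random item sets", {
  set.seed(51)
  for (rep in 1:10) {
    items <- do.call(rbind, lapply(1:25, function(i) {
      cola_item(paste0("S", sample(1:6, 1)), grams = runif(1, 10, 600),
                occasion_code = sample(c(1, 2, 3, 6, 99), 1))
    }))
    suppressMessages(res <- isocaloric_replace(items, prof, map))
    expect_lt(max(abs(res$adjusted$energy - res$baseline$energy)), 1e-9)
  }
})

test_that("a bigger lunch soda means more replacement milk, same energy", {
  grams <- c(100, 200, 400)
  vit_d <- calcium <- energy_delta <- numeric(3)
  for (k in seq_along(grams)) {
    res <- isocaloric_replace(cola_item("S1", grams = grams[k],
                                        occasion_code = 2), prof, map)
    vit_d[k] <- res$adjusted$vitamin_d
    calcium[k] <- res$adjusted$calcium
    energy_delta[k] <- res$adjusted$energy - res$baseline$energy
  }
  expect_true(all(diff(vit_d) > 0))
  expect_true(all(diff(calcium) > 0))
  expect_equal(energy_delta, rep(0, 3))
})

test_that("replacement is idempotent once beverages have become milk", {
  cola <- cola_item("S1", grams = 300, occasion_code = 2)
  res <- isocaloric_replace(cola, prof, map)
  E <- res$replaced_energy
  # rebuild the item table as the model imagines it: milk in, cola out
  milk_equiv <- make_item("S1", wweia_code = 1002, occasion_code = 2,
                          grams = E / (prof$per_cup[["energy"]] /
                                         prof$grams_per_cup))
  for (nm in nutrient_names()) {
    milk_equiv[[nm]] <- prof$per_kcal[[nm]] * E
  }
  res2 <- isocaloric_replace(milk_equiv, prof, map)
  expect_equal(res2$adjusted, res2$baseline)
  expect_equal(res2$replaced_energy, 0)
})

test_that("replacement scopes select the advertised beverage sets", {
  items <- rbind(
    cola_item("S1", occasion_code = 2),                       # ssb
    make_item("S1", wweia_code = 7002, occasion_code = 2,     # 100% juice
              grams = 240, energy = 110, total_sugars = 20,
              carbohydrate = 26),
    make_item("S1", wweia_code = 1404, occasion_code = 3,     # substitute
              grams = 240, energy = 70, protein = 3,
              total_fat = 3, mufa = 1.5, calcium = 300),
    make_item("S1", wweia_code = 7302, occasion_code = 6,     # snack coffee
              grams = 300, energy = 60, total_sugars = 12)
  )
  ssb <- replacement_scope_select("ssb_only")(items, map)
  expect_identical(ssb, c(TRUE, FALSE, FALSE, FALSE))
  subs <- replacement_scope_select("milk_substitutes_only")(items, map)
  expect_identical(subs, c(FALSE, FALSE, TRUE, FALSE))
  all_cal <- replacement_scope_select("all_caloric")(items, map)
  # nonmilk caloric beverages at meals: the cola and the juice, never the
  # milk substitute (a milk-group beverage) nor the snack-time coffee
  expect_identical(all_cal, c(TRUE, TRUE, FALSE, FALSE))
  # set algebra: all_caloric at least covers every meal-time SSB selection
  expect_true(all(all_cal[ssb]))
  expect_error(replacement_scope_select("everything"), "arg")
})
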