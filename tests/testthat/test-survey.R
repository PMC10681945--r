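test_that("with equal weights and independent PSUs the mean reduces to SRS", {
  set.seed(31)
  for (rep in 1:5) {
    y <- rnorm(30, 5, 2)
    d <- survey_design(rep(1, 30), rep("A", 30), seq_len(30))
    m <- svy_mean(y, d)
    expect_equal(m$estimate, mean(y), tolerance = 1e-12)
    expect_equal(m$se, stats::sd(y) / sqrt(30), tolerance = 1e-12)
  }
  y <- c(1, 2, 3)
  m <- svy_mean(y, survey_design(rep(1, 3), rep("A", 3), 1:3))
  expect_equal(m$estimate, 2)
  expect_equal(m$se, stats::sd(y) / sqrt(3), tolerance = 1e-12)
})

test_that("identical observations have zero variance", {
  d <- survey_design(runif(12, 0.5, 2), rep(1:2, each = 6),
                     rep(rep(1:2, each = 3), 2))
  m <- svy_mean(rep(7.5, 12), d)
  expect_identical(m$se, 0)
})

test_that("the linearized variance matches a hand-expanded two-by-two design", {
  # 2 strata x 2 PSUs x 2 subjects, unequal weights; expand the 8-term
  # formula longhand, independent of the package's vectorized path
  y <- c(1, 4, 2, 8, 3, 5, 7, 6)
  w <- c(1, 2, 1.5, 0.5, 2, 1, 0.8, 1.2)
  st <- c(1, 1, 1, 1, 2, 2, 2, 2)
  psu <- c(1, 1, 2, 2, 1, 1, 2, 2)
  W <- sum(w)
  est <- sum(w * y) / W
  z <- w * (y - est) / W
  zz <- function(s, p) sum(z[st == s & psu == p])
  var_hand <- 0
  for (s in 1:2) {
    zh <- c(zz(s, 1), zz(s, 2))
    var_hand <- var_hand + 2 / (2 - 1) * sum((zh - mean(zh))^2)
  }
  m <- svy_mean(y, survey_design(w, st, psu))
  expect_equal(m$estimate, est, tolerance = 1e-14)
  expect_equal(m$se, sqrt(var_hand), tolerance = 1e-14)
  expect_equal(m$df, 2L)
})

test_that("a lone-PSU stratum is a named error, never silently collapsed", {
  d <- survey_design(rep(1, 6), c(1, 1, 1, 1, 2, 2), c(1, 2, 1, 2, 1, 1))
  expect_error(svy_mean(rnorm(6), d), "single PSU.*2")
  # but a lone-PSU stratum whose weight is all zero is inert
  d0 <- survey_design(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 1, 2, 2),
                      c(1, 2, 1, 2, 1, 1))
  expect_silent(svy_mean(rnorm(6), d0))
})

test_that("Taylor SEs track a delete-one-PSU jackknife on random designs", {
  set.seed(32)
  for (rep in 1:10) {
    dat <- random_design_data(H = sample(2:4, 1), P = sample(2:3, 1),
                              k = sample(3:8, 1))
    m <- svy_mean(dat$y, survey_design(dat$w, dat$strata, dat$psu))
    jk <- jackknife_se_mean(dat$y, dat$w, dat$strata, dat$psu)
    expect_lt(abs(m$se - jk) / jk, 0.15)
  }
})

test_that("a noiseless linear outcome is recovered exactly with zero SE", {
  set.seed(33)
  n <- 60
  age <- sample(6:18, n, replace = TRUE)
  d <- survey_design(rlnorm(n), rep(1:3, length.out = n),
                     rep(1:2, length.out = n))
  fit <- trend_regression(2.5 - 0.75 * age, age, d)
  expect_equal(fit$beta, -0.75, tolerance = 1e-10)
  expect_equal(fit$se, 0, tolerance = 1e-10)
})

test_that("trend fits are invariant to subject order", {
  set.seed(34)
  n <- 200
  age <- sample(6:18, n, replace = TRUE)
  y <- 3 * age + rnorm(n, 0, 5)
  w <- rlnorm(n)
  lat <- lattice_strata(n, 4, 2)
  st <- lat$strata; psu <- lat$psu
  covs <- data.frame(sex = sample(c("male", "female"), n, TRUE))
  fit1 <- trend_regression(y, age, survey_design(w, st, psu), covs)
  o <- sample(n)
  fit2 <- trend_regression(y[o], age[o], survey_design(w[o], st[o], psu[o]),
                           covs[o, , drop = FALSE])
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-12)
  expect_equal(fit1$se, fit2$se, tolerance = 1e-12)
})

test_that("collinear covariates are dropped with a note; df<=0 errors", {
  set.seed(35)
  n <- 40
  age <- sample(6:18, n, replace = TRUE)
  covs <- data.frame(a = rep("x", n))  # constant, aliased with intercept
  d <- survey_design(rep(1, n), rep(1:2, length.out = n),
                     rep(1:2, each = 2, length.out = n))
  expect_message(trend_regression(rnorm(n), age, d, covs), "constant covariate")
  d1 <- survey_design(rep(1, n), rep(1:2, length.out = n),
                      rep(1, n))  # one PSU per stratum
  expect_error(trend_regression(rnorm(n), age, d1, NULL),
               "degrees of freedom")
})

test_that("constant covariates leave LS means equal to weighted group means", {
  set.seed(36)
  n <- 120
  age <- sample(6:18, n, replace = TRUE)
  grp <- age_group_factor(age)
  y <- rnorm(n, 100, 20)
  w <- rlnorm(n)
  d <- survey_design(w, rep(1:3, length.out = n),
                     rep(1:2, length.out = n))
  suppressMessages({
    ls <- lsmeans_by_age_group(y, grp, d,
                               data.frame(c1 = rep("k", n)))
  })
  for (g in levels(grp)) {
    idx <- grp == g
    expect_equal(ls$estimate[ls$age_group == g],
                 sum(w[idx] * y[idx]) / sum(w[idx]), tolerance = 1e-10)
  }
  expect_equal(ls$n, as.vector(table(grp)))
})

test_that("a single age group collapses to the overall weighted mean", {
  set.seed(37)
  n <- 50
  y <- rnorm(n)
  w <- rlnorm(n)
  d <- survey_design(w, rep(1:2, length.out = n), rep(1:2, each = 2,
                                                      length.out = n))
  ls <- lsmeans_by_age_group(y, factor(rep("6-8", n)), d)
  expect_equal(nrow(ls), 1L)
  expect_equal(ls$estimate, sum(w * y) / sum(w), tolerance = 1e-12)
})

test_that("LS means recover known group means under balanced covariates", {
  set.seed(38)
  n <- 3000
  age <- sample(6:18, n, replace = TRUE)
  grp <- age_group_factor(age)
  truth <- c("6-8" = 100, "9-13" = 80, "14-18" = 60)
  sex <- sample(c("male", "female"), n, TRUE)
  y <- truth[as.character(grp)] + 5 * (sex == "male") + rnorm(n, 0, 10)
  d <- survey_design(rlnorm(n, 0, 0.4), rep(1:10, length.out = n),
                     rep(1:3, length.out = n))
  ls <- lsmeans_by_age_group(y, grp, d, data.frame(sex = sex))
  shift <- 5 * mean(sex == "male")  # margin over the observed distribution
  for (g in names(truth)) {
    row <- ls[ls$age_group == g, ]
    expect_lt(abs(row$estimate - (truth[[g]] + shift)), 3 * row$se)
  }
})

test_that("population ratios behave like shares", {
  d2 <- survey_design(c(1, 1), c(1, 1), c(1, 2))
  expect_equal(population_ratio(c(10, 0), c(50, 50), d2)$estimate, 10)
  s <- c(3, 7); expect_equal(population_ratio(s, s, d2)$estimate, 100)
  expect_error(population_ratio(c(1, 1), c(0, 0), d2), "zero")
  expect_warning(population_ratio(c(2, 1), c(1, 1), d2), "exceeds")
})

test_that("contributions of a partition of the total sum to 100 percent", {
  set.seed(39)
  n <- 200
  lat <- lattice_strata(n, 4, 2)
  d <- survey_design(rlnorm(n), lat$strata, lat$psu)
  parts <- matrix(runif(n * 5), n, 5)
  total <- rowSums(parts)
  shares <- vapply(seq_len(5), function(k) {
    population_ratio(parts[, k], total, d)$estimate
  }, numeric(1))
  expect_equal(sum(shares), 100, tolerance = 1e-9)
})

test_that("the weighted paired t test is the mean test on differences", {
  set.seed(40)
  n <- 80
  base <- rnorm(n, 100, 10)
  adj <- base + rnorm(n, 2, 3)
  lat <- lattice_strata(n, 4, 2)
  d <- survey_design(rlnorm(n), lat$strata, lat$psu)
  pt1 <- paired_t(base, adj, d)
  m <- svy_mean(adj - base, d)
  expect_equal(pt1$mean_difference, m$estimate, tolerance = 1e-12)
  expect_equal(pt1$se, m$se, tolerance = 1e-12)
  expect_equal(pt1$t, m$estimate / m$se, tolerance = 1e-12)

  zero <- paired_t(base, base, d)
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)

  const <- paired_t(base, base + 5, d)
  expect_true(const$flagged)
  expect_equal(const$mean_difference, 5, tolerance = 1e-12)
  expect_lte(const$p, .Machine$double.xmin)
})

test_that("percent changes reproduce printed conventions", {
  expect_equal(percent_change(91.7, 34.9, "decrease"), 62)
  expect_equal(percent_change(396, 776, "increase"), 96)
  expect_equal(percent_change(33.6, 145, "increase"), 332)
  expect_equal(percent_change(5, 5, "increase"), 0)
  expect_equal(percent_change(210, 190, "decrease"), 9.5)  # one decimal < 10
  expect_error(percent_change(0, 5, "increase"), "from")
  expect_equal(round_half_up(87.5), 88)   # half away from zero
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(2.45, 1), 2.5)
})

test_that("the 10 percent rule flags meaningful modeled changes", {
  up <- flag_meaningful_change(1000, 1291)
  expect_equal(up$percent, 29.1, tolerance = 1e-9)
  expect_true(up$meaningful)
  small <- flag_meaningful_change(1869, 1991)
  expect_false(small$meaningful)
  expect_equal(small$percent, 100 * 122 / 1869, tolerance = 1e-9)
  expect_false(flag_meaningful_change(3, 3)$meaningful)
  expect_true(flag_meaningful_change(0, 1)$undefined)
})

test_that("age groups must partition 6-18", {
  expect_error(age_group_factor(10, list(a = 6:9, b = 9:18)), "partition")
  expect_error(age_group_factor(10, list(a = 6:8, b = 10:18)), "partition")
  g <- age_group_factor(c(6, 9, 18, 25))
  expect_equal(as.character(g), c("6-8", "9-13", "14-18", NA))
})
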