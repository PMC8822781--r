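test_that("annual update applies death, comorbidity change, and ageing in order", {
  cat <- covariate_categorizer()
  state <- list(age = rep(70, 50), cci = rep(1, 50), dci = rep(0.5, 50),
                alive = rep(TRUE, 50))
  # certain death: covariates untouched, everyone dead
  m1 <- const_models(q = 1)
  st <- advance_one_year(state, m1, rng_streams(5))
  expect_true(all(!st$alive))
  expect_identical(st$age, state$age)
  expect_identical(st$cci, state$cci)
  expect_identical(st$dci, state$dci)
  # no death, no changes: age + 1, covariates identical
  m0 <- const_models(q = 0, p_cci = 0, p_dci = 0)
  st <- advance_one_year(state, m0, rng_streams(5))
  expect_true(all(st$alive))
  expect_identical(st$age, state$age + 1L)
  expect_identical(st$cci, state$cci)
  expect_identical(st$dci, state$dci)
  # dead input is misuse
  st$alive[1] <- FALSE
  expect_error(advance_one_year(st, m0, rng_streams(5)), "alive")
})

test_that("CCI and DCI blocks commute bit-exactly under the named streams", {
  m <- example_transition_models()
  state <- withr::with_seed(31, list(
    age = sample(65:95, 1000, replace = TRUE),
    cci = sample(0:6, 1000, replace = TRUE),
    dci = sample(seq(-0.75, 6, 0.25), 1000, replace = TRUE),
    alive = rep(TRUE, 1000)))
  a <- advance_one_year(state, m, rng_streams(42), dci_first = FALSE)
  b <- advance_one_year(state, m, rng_streams(42), dci_first = TRUE)
  expect_identical(a, b)
})

test_that("identical seeds give bit-identical survival curves", {
  m <- example_transition_models()
  cfg <- sim_config(seed = 9, n_individuals = 500)
  c1 <- simulate_cohort(list(age = 80, cci = 1, dci = 1), m, cfg)
  c2 <- simulate_cohort(list(age = 80, cci = 1, dci = 1), m, cfg)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(list(age = 80, cci = 1, dci = 1), m,
                        sim_config(seed = 10, n_individuals = 500))
  expect_false(identical(c1$survival, c3$survival))
})

test_that("constant hazard reproduces the geometric closed form", {
  m <- const_models(q = 0.2)
  cfg <- sim_config(seed = 17, n_individuals = 10000)
  curve <- simulate_cohort(list(age = 65, cci = 0, dci = 0), m, cfg)
  for (t in 1:10) {
    s <- 0.8^t
    expect_lt(abs(curve$survival[t + 1] - s),
              3 * sqrt(s * (1 - s) / 10000))
  }
  le <- life_expectancy(curve)
  closed <- 0.5 + sum(0.8^(1:40))
  expect_lt(abs(le - closed), 3 * sqrt(0.8 / 0.04) / sqrt(10000))
})

test_that("zero mortality runs to the age cap and terminates there", {
  m <- const_models(q = 0)
  cfg <- sim_config(seed = 3, n_individuals = 200)
  curve <- simulate_cohort(list(age = 65, cci = 0, dci = 0), m, cfg)
  expect_equal(max(curve$time), 105 - 65 + 1)
  expect_true(all(curve$survival[1:41] == 1))
  expect_equal(curve$survival[42], 0)
  # start at the cap: at most one year of credit
  short <- simulate_cohort(list(age = 105, cci = 0, dci = 0), m, cfg)
  expect_lte(life_expectancy(short), 1)
})

test_that("life expectancy integrates the curve by trapezoid", {
  expect_equal(life_expectancy(survival_curve(0:1, c(1, 0))), 0.5)
  expect_equal(life_expectancy(survival_curve(0:2, c(1, 1, 0))), 1.5)
  expect_equal(life_expectancy(survival_curve(0:2, c(1, 1, 0)),
                               quadrature = "step"), 2)
  bad <- data.frame(time = 0:2, survival = c(1, 0.2, 0.7))
  expect_error(life_expectancy(bad), "non-increasing")
  expect_error(survival_curve(0:1, c(0.9, 0.2)), "time 0")
})

test_that("the life-expectancy grid covers the configured start states", {
  cfg_default <- sim_config()
  expect_identical(length(cfg_default$start_ages), 26L)
  expect_identical(length(cfg_default$start_cci), 11L)
  expect_identical(length(cfg_default$start_dci), 58L)

  m <- const_models(q = 0.5)
  cfg <- sim_config(seed = 4, n_individuals = 300, start_ages = c(70, 90),
                    start_cci = c(0, 3), start_dci = c(0, 1))
  tab <- life_expectancy_grid(m, cfg)
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$life_expectancy >= 0 &
                    tab$life_expectancy <= 105 - tab$age + 1))
  expect_true(all(tab$n == 300L & tab$seed == 4L))
  # combination order does not matter: a sub-grid reproduces its entries
  sub <- life_expectancy_grid(m, sim_config(seed = 4, n_individuals = 300,
                                            start_ages = 90, start_cci = 3,
                                            start_dci = 1))
  expect_equal(sub$life_expectancy,
               tab$life_expectancy[tab$age == 90 & tab$cci == 3 &
                                     tab$dci == 1])
})
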