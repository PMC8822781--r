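test_that("Kaplan-Meier reduces to empirical survival without censoring", {
  # 4 individuals: deaths at years 1, 2, 2; one alive through year 3
  tab <- rbind(
    py_row(1, 0L, 70L, 0L, 0, died = 1L),
    py_row(2, 0L, 70L, 0L, 0, cci_next = 0L, dci_next = 0),
    py_row(2, 1L, 71L, 0L, 0, died = 1L),
    py_row(3, 0L, 70L, 0L, 0, cci_next = 0L, dci_next = 0),
    py_row(3, 1L, 71L, 0L, 0, died = 1L),
    py_row(4, 0L, 70L, 0L, 0, cci_next = 0L, dci_next = 0),
    py_row(4, 1L, 71L, 0L, 0, cci_next = 0L, dci_next = 0),
    py_row(4, 2L, 72L, 0L, 0, censored = 1L))
  curve <- observed_survival(tab)
  expect_equal(curve$survival, c(1, 3 / 4, 1 / 4, 1 / 4))
  expect_equal(attr(curve, "events"), 3L)
})

test_that("universal one-year censoring gives a flat curve with no events", {
  tab <- py_row(1:20, 0L, 70L, 0L, 0, censored = 1L)
  curve <- observed_survival(tab)
  expect_equal(curve$survival, c(1, 1))
  expect_equal(attr(curve, "events"), 0L)
})

test_that("entry filters select subgroups and reject empty ones", {
  tab <- rbind(py_row(1, 0L, 70L, 0L, 0, died = 1L),
               py_row(2, 0L, 80L, 2L, 1, died = 1L))
  c70 <- observed_survival(tab, function(e) e$age == 70)
  expect_equal(attr(c70, "n"), 1L)
  expect_error(observed_survival(tab, function(e) e$age == 99), "empty")
})

test_that("years lost complements the restricted area under the curve", {
  flat <- survival_curve(0:10, rep(1, 11))
  expect_equal(years_lost(flat, 10), 0)
  drop1 <- survival_curve(0:10, c(1, rep(0, 10)))
  expect_equal(years_lost(drop1, 10), 9.5)
  geom <- survival_curve(0:12, 0.8^(0:12))
  expect_equal(years_lost(geom, 10),
               10 - (0.5 + sum(0.8^(1:9)) + 0.5 * 0.8^10))
  # conservation for arbitrary valid curves
  for (seed in 1:5) {
    s <- withr::with_seed(seed, cumprod(c(1, runif(12, 0.6, 1))))
    curve <- survival_curve(0:12, s)
    area <- sum((s[1:10] + s[2:11]) / 2)
    expect_equal(years_lost(curve, 10) + area, 10)
  }
  expect_error(years_lost(survival_curve(0:3, c(1, 0.9, 0.8, 0.7)), 10),
               "before the horizon")
})

test_that("mean trajectories are exact under frozen and drifting dynamics", {
  # frozen comorbidity: observed and simulated means constant and equal
  m <- const_models(q = 0.1)
  sp <- synthetic_cohort_spec(n_individuals = 800, seed = 61, truth = m,
                              annual_censor_prob = 0,
                              entry_cci_dist = c(0, 0, 1, rep(0, 8)),
                              entry_dci_dist = {w <- numeric(58)
                                w[match(1, seq(-0.75, 13.5, 0.25))] <- 1; w})
  co <- generate_cohort(sp)
  sim <- simulate_cohort(list(age = 75, cci = 2, dci = 1), m,
                         sim_config(seed = 62, n_individuals = 800))
  tr <- mean_trajectories(co, attr(sim, "trajectories"))
  expect_true(all(tr$mean_cci_obs == 2 & tr$mean_cci_sim == 2))
  expect_true(all(tr$diff_dci == 0))
  # certain unit drift: simulated mean CCI at year t is start + t exactly
  drift <- const_models(q = 0.1, p_cci = 1)
  simd <- simulate_cohort(list(age = 75, cci = 0, dci = 0), drift,
                          sim_config(seed = 63, n_individuals = 500))
  traj <- attr(simd, "trajectories")
  ok <- traj$n_alive > 0
  expect_equal(traj$mean_cci[ok], traj$time[ok])
})

test_that("generator and simulator trajectories agree under one truth", {
  m <- example_transition_models()
  sp <- synthetic_cohort_spec(
    n_individuals = 4000, seed = 64, truth = m, annual_censor_prob = 0,
    entry_age_weights = c(rep(0, 5), 1, rep(0, 20)),  # all aged 70
    entry_cci_dist = c(1, rep(0, 10)),
    entry_dci_dist = {w <- numeric(58); w[4] <- 1; w})  # DCI 0
  co <- generate_cohort(sp)
  sim <- simulate_cohort(list(age = 70, cci = 0, dci = 0), m,
                         sim_config(seed = 65, n_individuals = 4000))
  tr <- mean_trajectories(co, attr(sim, "trajectories"))
  for (i in seq_len(nrow(tr))) {
    o <- co[co$year_index == tr$time[i], ]
    bound_cci <- 3 * stats::sd(o$cci) * sqrt(2 / nrow(o)) + 1e-6
    bound_dci <- 3 * stats::sd(o$dci) * sqrt(2 / nrow(o)) + 1e-6
    expect_lt(abs(tr$diff_cci[i]), bound_cci)
    expect_lt(abs(tr$diff_dci[i]), bound_dci)
  }
})

test_that("calibration recovers a perfectly calibrated model within binomial error", {
  p <- withr::with_seed(71, runif(20000, 0.01, 0.6))
  y <- withr::with_seed(72, rbinom(length(p), 1, p))
  tab <- calibration(p, y, n_bins = 10)
  expect_s3_class(tab, "calibration_table")
  expect_equal(sum(tab$n), length(p))
  expect_true(all(abs(tab$observed_fraction - tab$mean_predicted) <
                    3 * sqrt(tab$mean_predicted *
                               (1 - tab$mean_predicted) / tab$n)))
})

test_that("degenerate calibration inputs take the reduced-bin path", {
  expect_warning(tab <- calibration(rep(0.5, 50), rep(1, 50)), "fewer")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$observed_fraction, 1)
  expect_equal(tab$mean_predicted, 0.5)
  expect_error(calibration(numeric(0), numeric(0)), "non-empty")
  expect_error(calibration(c(0.2, 1.2), c(0, 1)), "probabilities")
})

test_that("comparison reports are antisymmetric in their arguments", {
  a <- survival_curve(0:12, 0.9^(0:12))
  b <- survival_curve(0:12, 0.85^(0:12))
  r1 <- comparison_report(a, b)
  r2 <- comparison_report(b, a)
  expect_equal(r1$table$difference, -r2$table$difference)
  expect_equal(r1$years_lost_diff, -r2$years_lost_diff)
  expect_equal(r1$max_abs_diff, r2$max_abs_diff)
  expect_equal(r1$years_lost_observed, years_lost(a, 10))
})

test_that("single-region cohorts cannot be cross-validated", {
  tab <- py_row(1:30, 0L, 70L, 0L, 0, died = rep(0:1, 15),
                censored = rep(1:0, 15))
  tab$cci_next[tab$died == 0 & tab$censored == 0] <- 0L
  expect_error(region_cross_validation(tab), "two regions")
})
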