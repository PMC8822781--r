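test_that("generated person-years satisfy every record invariant", {
  sp <- synthetic_cohort_spec(n_individuals = 2000, seed = 51)
  co <- generate_cohort(sp)
  expect_true(all(co$age >= 65 & co$age <= 105))
  expect_true(all(co$cci >= 0))
  expect_true(all(co$dci >= -0.75))
  expect_true(all(abs(co$dci / 0.25 - round(co$dci / 0.25)) < 1e-9))
  expect_true(all(co$died + co$censored <= 1))
  expect_true(all(co$region %in% 1:6))
  done <- co$died == 1 | co$censored == 1
  expect_true(all(is.na(co$cci_next[done]) & is.na(co$dci_next[done])))
  expect_true(all(!is.na(co$cci_next[!done]) & !is.na(co$dci_next[!done])))
  expect_true(all(co$cci_next[!done] >= co$cci[!done]))
  # follow-up is contiguous and ends with death or censoring
  per <- split(co, co$person_id)
  expect_true(all(vapply(per, function(p) {
    all(p$year_index == seq_len(nrow(p)) - 1) &&
      sum(p$died + p$censored) == 1 &&
      (p$died + p$censored)[nrow(p)] == 1
  }, logical(1))))
  expect_true(all(co$year_index < sp$max_followup))
})

test_that("certain censoring yields one censored record per individual", {
  sp <- synthetic_cohort_spec(n_individuals = 300, seed = 52,
                              annual_censor_prob = 1,
                              truth = const_models(q = 0))
  co <- generate_cohort(sp)
  expect_equal(nrow(co), 300L)
  expect_true(all(co$censored == 1L & co$year_index == 0L))
})

test_that("a frozen truth freezes the comorbidity paths", {
  sp <- synthetic_cohort_spec(n_individuals = 500, seed = 53,
                              truth = const_models(q = 0.15))
  co <- generate_cohort(sp)
  done <- co$died == 1 | co$censored == 1
  expect_true(all(co$cci_next[!done] == co$cci[!done]))
  expect_true(all(co$dci_next[!done] == co$dci[!done]))
})

test_that("entry distributions reproduce the configured age gradient", {
  sp <- synthetic_cohort_spec(n_individuals = 20000, seed = 54)
  co <- generate_cohort(sp)
  summ <- summarize_entry_distributions(co)
  # the configured prevalence of CCI = 0 falls strictly with age ...
  p0 <- vapply(summ$age, function(a) sp$entry_cci_dist(a)[1], numeric(1))
  expect_true(all(diff(p0) < 0))
  # ... and every sampled prevalence sits within binomial error of it
  expect_true(all(abs(summ$prev_cci0 - p0) <
                    4 * sqrt(p0 * (1 - p0) / summ$n) + 1e-9))
  # DCI > 0 becomes more common with age, qualitatively
  expect_gt(mean(summ$prev_dci_pos[summ$age >= 85]),
            mean(summ$prev_dci_pos[summ$age <= 70]))

  # degenerate entry distribution: all mass on CCI = 0
  sp0 <- synthetic_cohort_spec(n_individuals = 500, seed = 55,
                               entry_cci_dist = c(1, rep(0, 10)))
  s0 <- summarize_entry_distributions(generate_cohort(sp0))
  expect_true(all(s0$prev_cci0 == 1))

  # a single entry age yields a single row, no division by zero
  sp1 <- synthetic_cohort_spec(n_individuals = 200, seed = 56,
                               entry_age_weights = c(1, rep(0, 25)))
  s1 <- summarize_entry_distributions(generate_cohort(sp1))
  expect_identical(s1$age, 65L)
})

test_that("generator and simulator agree on survival from a fixed entry state", {
  m <- example_transition_models()
  n <- 5000
  sp <- synthetic_cohort_spec(
    n_individuals = n, seed = 57, truth = m, annual_censor_prob = 0,
    max_followup = 11L,
    entry_age_weights = c(rep(0, 10), 1, rep(0, 15)),  # all aged 75
    entry_cci_dist = c(0, 1, rep(0, 9)),               # CCI 1
    entry_dci_dist = {w <- numeric(58); w[match(1, seq(-0.75, 13.5, 0.25))] <- 1; w})
  co <- generate_cohort(sp)
  gen <- observed_survival(co)
  sim <- simulate_cohort(list(age = 75, cci = 1, dci = 1), m,
                         sim_config(seed = 58, n_individuals = n))
  tt <- seq_len(min(max(gen$time), max(sim$time)))
  s <- sim$survival[tt + 1]
  # two independent Monte-Carlo estimates of the same distribution
  tol <- 3 * sqrt(2 * pmax(s * (1 - s), 1e-12) / n)
  expect_true(all(abs(gen$survival[tt + 1] - s) < tol + 1e-9))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_cohort_spec(entry_age_weights = rep(-1, 26)),
               "non-negative")
  expect_error(synthetic_cohort_spec(entry_cci_dist = c(0.5, 0.5)),
               "11")
  expect_error(synthetic_cohort_spec(annual_censor_prob = 1.5))
})
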