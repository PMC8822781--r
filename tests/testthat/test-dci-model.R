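test_that("DCI change and direction probabilities follow their predictors", {
  cat <- covariate_categorizer()
  null <- dci_change_params(flat_sub(0), flat_sub(0),
                            increase = list(shape = 2, mean = flat_sub(0)),
                            decrease = list(shape = 2, mean = flat_sub(0)))
  pr <- dci_transition_probabilities(70, 1, 0.5, null, cat)
  expect_equal(pr$p_change, 0.5)
  expect_equal(pr$p_increase, 0.5)

  m <- example_transition_models()$dci
  # hand-computed pair: age 70 (ref), cci 1 (+0.10 / +0.05), dci 2 -> (1,3]
  pr <- dci_transition_probabilities(70, 1, 2, m, cat)
  expect_equal(pr$p_change, plogis(0 + 0.10 + 0.15))
  expect_equal(pr$p_increase, plogis(0.35 + 0.05 - 0.35))
  grid <- expand.grid(age = c(65, 80, 95), cci = c(0, 4), dci = c(-0.75, 2, 9))
  pr <- dci_transition_probabilities(grid$age, grid$cci, grid$dci, m, cat)
  expect_true(all(pr$p_change > 0 & pr$p_change < 1 &
                    pr$p_increase > 0 & pr$p_increase < 1))
})

test_that("DCI steps live on the grid and respect the floor", {
  cat <- covariate_categorizer()
  m <- example_transition_models()$dci
  steps <- withr::with_seed(21, sample_dci_step(rep(75, 5e4), 1, 2,
                                                "increase", m, cat))
  expect_true(all(steps >= 0.25))
  expect_true(all(abs(steps / 0.25 - round(steps / 0.25)) < 1e-12))
  # decreases from the floor are truncated to a zero step
  at_floor <- withr::with_seed(22, sample_dci_step(rep(70, 100), 0, -0.75,
                                                   "decrease", m, cat))
  expect_true(all(at_floor == 0))
  # and generally never push DCI below the floor
  near <- withr::with_seed(23, sample_dci_step(rep(70, 1e4), 0, -0.25,
                                               "decrease", m, cat))
  expect_true(all(-0.25 - near >= -0.75))
  # empirical mean of rounded steps tracks the Gamma mean exp(eta)
  mu <- morbsim:::dci_step_mean(75, 1, 2, "increase", m, cat)
  se <- mu / sqrt(2 * 5e4)  # sd = mu/sqrt(shape)
  expect_lt(abs(mean(steps) - mu), 4 * se + 0.02)  # 0.02 grid-rounding slack
})

test_that("four-step DCI fit recovers known parameters", {
  cat <- covariate_categorizer()
  truth <- example_transition_models()$dci
  cov <- draw_covariates(80000, seed = 421)
  tab <- withr::with_seed(422, {
    pr <- dci_transition_probabilities(cov$age, cov$cci, cov$dci, truth, cat)
    changed <- rbinom(nrow(cov), 1, pr$p_change) == 1
    up <- rbinom(nrow(cov), 1, pr$p_increase) == 1
    step <- numeric(nrow(cov))
    iu <- changed & up; idn <- changed & !up
    step[iu] <- sample_dci_step(cov$age[iu], cov$cci[iu], cov$dci[iu],
                                "increase", truth, cat)
    step[idn] <- -sample_dci_step(cov$age[idn], cov$cci[idn], cov$dci[idn],
                                  "decrease", truth, cat)
    cbind(cov, died = 0L, censored = 0L, cci_next = cov$cci,
          dci_next = pmax(cov$dci + step, -0.75))
  })
  fit <- fit_dci_models(tab, cat)
  parts <- list(occurrence = list(fit$occurrence, truth$occurrence),
                direction = list(fit$direction, truth$direction),
                increase = list(fit$increase$mean, truth$increase$mean),
                decrease = list(fit$decrease$mean, truth$decrease$mean))
  for (nm in names(parts)) {
    f <- parts[[nm]][[1]]; t <- parts[[nm]][[2]]
    tc <- t$coefs[names(f$coefs)]
    tc[is.na(tc)] <- 0
    expect_true(all(abs((f$coefs - tc) / attr(f, "se")) < 3),
                label = paste("DCI", nm, "recovery"))
  }
  expect_lt(abs(fit$increase$shape - 2), 0.25)
  expect_lt(abs(fit$decrease$shape - 2), 0.25)
})

test_that("mirroring all DCI changes exactly negates the direction model", {
  cat <- covariate_categorizer()
  cov <- draw_covariates(20000, seed = 423)
  cov$dci <- cov$dci + 6  # keep both versions far from the floor
  tab <- withr::with_seed(424, {
    changed <- rbinom(nrow(cov), 1, 0.5) == 1
    up <- rbinom(nrow(cov), 1, plogis(0.3)) == 1
    step <- 0.25 * sample(1:4, nrow(cov), replace = TRUE)
    delta <- ifelse(changed, ifelse(up, step, -step), 0)
    cbind(cov, died = 0L, censored = 0L, cci_next = cov$cci,
          dci_next = cov$dci + delta)
  })
  mirrored <- transform(tab, dci_next = dci - (dci_next - dci))
  f1 <- fit_dci_models(tab, cat)
  f2 <- fit_dci_models(mirrored, cat)
  expect_equal(f2$direction$coefs, -f1$direction$coefs, tolerance = 1e-6)
  expect_equal(f1$occurrence$coefs, f2$occurrence$coefs, tolerance = 1e-9)
  # the size models swap sides
  expect_equal(f2$increase$mean$coefs, f1$decrease$mean$coefs,
               tolerance = 1e-4)
})

test_that("degenerate DCI tables are reported as such", {
  cat <- covariate_categorizer()
  tab <- py_row(1:60, 0L, 70L, 0L, rep(c(0, 1, 2), 20),
                cci_next = 0L, dci_next = rep(c(0, 1, 2), 20))
  expect_error(fit_dci_models(tab, cat), "never changes")
  one_way <- transform(tab, dci_next = dci + 0.25)
  expect_error(fit_dci_models(one_way, cat), "in every row")
  mixed <- transform(tab, dci_next = dci + rep(c(0, 0.25, 0.25), 20))
  expect_error(fit_dci_models(mixed, cat), "decrease")
})
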