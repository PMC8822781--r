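# Model-set builders used across the test files.

# intercept-only sub-model (categorized design with no terms)
flat_sub <- function(intercept) {
  cat_submodel(c("(Intercept)" = intercept), character(0), list())
}

logit_or_off <- function(p) if (p <= 0) -40 else if (p >= 1) 40 else qlogis(p)

# Model set with constant probabilities everywhere: death q, CCI change
# p_cci, DCI change p_dci (increase w.p. p_up given change). Probabilities
# of 0/1 are realized as +/-40 on the logit scale (numerically exact at
# double precision). Size distributions default to degenerate single steps.
const_models <- function(q = 0.2, p_cci = 0, p_dci = 0, p_up = 0.5,
                         size_fixed = 1L, step_fixed = 0.25,
                         cat = covariate_categorizer()) {
  transition_model_set(
    death = death_model_params(logit_or_off(q), 0, 0, 0, 0, 0),
    cci = cci_change_params(flat_sub(logit_or_off(p_cci)),
                            size0 = flat_sub(-2), size1 = flat_sub(-2),
                            size_fixed = size_fixed),
    dci = dci_change_params(flat_sub(logit_or_off(p_dci)),
                            flat_sub(logit_or_off(p_up)),
                            increase = list(shape = 2, mean = flat_sub(-0.5)),
                            decrease = list(shape = 2, mean = flat_sub(-0.5)),
                            step_fixed = step_fixed),
    categorizer = cat
  )
}

# randomized model set with degenerate sizes (CCI +1, DCI +/-0.25), a
# finite Markov chain suitable for the exact oracle
rand_degenerate_models <- function(seed) {
  withr::with_seed(seed, {
    cat <- covariate_categorizer()
    death <- death_model_params(
      intercept = runif(1, -6.5, -4.5), beta_age = runif(1, 0.02, 0.06),
      beta_cci = runif(1, -0.012, -0.004),
      beta_dci = runif(1, -0.004, -0.001),
      gamma_cci = runif(1, -8e-6, -2e-6), gamma_dci = runif(1, -4e-6, -1e-6))
    rand_sub <- function(intercept_range) {
      cat_submodel_from_effects(
        cat, intercept = runif(1, intercept_range[1], intercept_range[2]),
        age = runif(2, -0.3, 0.3), cci = runif(3, -0.3, 0.3),
        dci = runif(3, -0.3, 0.3))
    }
    cci <- cci_change_params(rand_sub(c(-2.5, -1.5)),
                             size0 = flat_sub(-2), size1 = flat_sub(-2),
                             size_fixed = 1L)
    dci <- dci_change_params(rand_sub(c(-1, 0.5)), rand_sub(c(-0.5, 0.5)),
                             increase = list(shape = 2, mean = flat_sub(-0.5)),
                             decrease = list(shape = 2, mean = flat_sub(-0.5)),
                             step_fixed = 0.25)
    transition_model_set(death, cci, dci, cat)
  })
}

# person-year table drawn directly from given model components (covariates
# sampled independently; one row per person-year, all completed)
draw_covariates <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    age = sample(65:95, n, replace = TRUE),
    cci = sample(0:8, n, replace = TRUE,
                 prob = 0.5^(0:8)),
    dci = sample(seq(-0.75, 8, 0.25), n, replace = TRUE,
                 prob = 0.75^(seq_len(36)))
  ))
}

# minimal complete person-year table (hand-buildable rows)
py_row <- function(person_id, year_index, age, cci, dci, died = 0L,
                   censored = 0L, cci_next = NA_integer_,
                   dci_next = NA_real_, region = 1L) {
  data.frame(person_id = person_id, region = region,
             year_index = year_index, age = age, cci = cci, dci = dci,
             died = died, censored = censored, cci_next = cci_next,
             dci_next = dci_next)
}

# Monte-Carlo envelope for a simulated survival fraction around its exact
# value: the usual 3-standard-error band where the normal approximation is
# sound (expected count >= 5), and the exact binomial band of equal nominal
# coverage (99.73%) in the tails, where sqrt(S(1-S)/n) degenerates.
surv_within_mc <- function(sim_s, exact_s, n) {
  ok <- logical(length(sim_s))
  for (i in seq_along(sim_s)) {
    s <- exact_s[i]
    if (n * s * (1 - s) >= 5) {
      ok[i] <- abs(sim_s[i] - s) <= 3 * sqrt(s * (1 - s) / n) + 1e-12
    } else {
      k <- round(sim_s[i] * n)
      ok[i] <- k >= qbinom(0.00135, n, s) && k <= qbinom(1 - 0.00135, n, s)
    }
  }
  ok
}

# variance of the (step-quadrature) lifetime implied by a survival curve,
# for Monte-Carlo standard errors of life-expectancy estimates:
# T = sum_t 1{alive at t}, E T = sum S_t, E T^2 = sum (2t-1) S_t
curve_lifetime_var <- function(curve) {
  s <- curve$survival[-1]
  t <- seq_along(s)
  max(sum((2 * t - 1) * s) - sum(s)^2, 0)
}
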