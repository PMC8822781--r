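#' Simulation configuration
#'
#' Defaults reproduce the reference study design: 10,000 identical men per
#' start-state combination, start ages 65 to 90, start CCI 0 to 10, start
#' DCI from -0.75 to 13.5 in steps of 0.25, and termination of anyone still
#' alive at age 105.
#'
#' @param seed integer master seed; every random draw in a run derives from
#'   it through named sub-streams.
#' @param n_individuals identical individuals per start-state combination.
#' @param max_age simulation age cap in years.
#' @param start_ages,start_cci,start_dci start-state grids for
#'   [life_expectancy_grid()].
#' @param quadrature area rule for [life_expectancy()]: `"trapezoid"`
#'   (half-year credit in the year of death) or `"step"` (full-year credit).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_individuals = 10000L, max_age = 105L,
                       start_ages = 65:90, start_cci = 0:10,
                       start_dci = seq(-0.75, 13.5, by = 0.25),
                       quadrature = c("trapezoid", "step")) {
  quadrature <- match.arg(quadrature)
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_individuals >= 1L, max_age >= 65L,
            all(start_ages >= 65 & start_ages <= max_age),
            all(start_cci >= 0),
            all(start_dci >= -0.75),
            all(abs(start_dci / 0.25 - round(start_dci / 0.25)) < 1e-9))
  structure(list(seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 max_age = as.integer(max_age),
                 start_ages = as.integer(start_ages),
                 start_cci = as.integer(start_cci),
                 start_dci = as.numeric(start_dci),
                 quadrature = quadrature),
            class = "sim_config")
}

#' Survival curve at annual anniversaries
#'
#' @param times integer times 0..T in years since the start state.
#' @param survival survival fractions: `survival[1] = 1` at time 0,
#'   non-increasing, within `[0, 1]`.
#' @return object of class `survival_curve` (a data.frame with columns
#'   `time` and `survival`).
#' @export
survival_curve <- function(times, survival) {
  if (length(times) != length(survival) || length(times) < 1L) {
    stop("survival_curve: times and survival must be equal-length, ",
         "non-empty", call. = FALSE)
  }
  if (!isTRUE(all.equal(times, seq_along(times) - 1))) {
    stop("survival_curve: times must be 0, 1, ..., T", call. = FALSE)
  }
  if (abs(survival[1] - 1) > 1e-12) {
    stop("survival_curve: survival at time 0 must be 1", call. = FALSE)
  }
  if (any(survival < -1e-12 | survival > 1 + 1e-12)) {
    stop("survival_curve: survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival_curve: survival must be non-increasing", call. = FALSE)
  }
  structure(data.frame(time = as.integer(times),
                       survival = pmin(1, pmax(0, survival))),
            class = c("survival_curve", "data.frame"))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve, ", nrow(x) - 1L, " years",
      if (!is.null(attr(x, "n"))) sprintf(" (n = %d)", attr(x, "n")),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("  ...\n")
  invisible(x)
}

# ---- annual update ---------------------------------------------------------

# Vectorized annual update of (age, cci, dci, alive). All random blocks draw
# a fixed number of variates per stream from start-of-year covariates, so
# stream consumption never depends on this year's outcomes and the CCI and
# DCI blocks commute exactly.
advance_cohort_year <- function(age, cci, dci, alive, models, streams,
                                max_age = 105L, dci_first = FALSE) {
  n <- length(age)
  cat <- models$categorizer

  # step 2: death (individuals starting the year at the age cap are
  # terminated; "no man alive beyond age 105")
  p_death <- death_probability(age, cci, dci, models$death)
  u_death <- with_stream(streams, "mortality", function() stats::runif(n))
  dies <- alive & (age >= max_age | u_death < p_death)
  survives <- alive & !dies

  cci_block <- function() {
    p <- cci_change_probability(age, cci, dci, models$cci, cat)
    with_stream(streams, "cci", function() {
      u <- stats::runif(n)
      inc <- sample_cci_increment(age, cci, dci, models$cci, cat)
      list(change = u < p, inc = inc)
    })
  }
  dci_block <- function() {
    pr <- dci_transition_probabilities(age, cci, dci, models$dci, cat)
    with_stream(streams, "dci", function() {
      u1 <- stats::runif(n)
      u2 <- stats::runif(n)
      s_inc <- sample_dci_step(age, cci, dci, "increase", models$dci, cat)
      s_dec <- sample_dci_step(age, cci, dci, "decrease", models$dci, cat)
      list(change = u1 < pr$p_change, up = u2 < pr$p_increase,
           s_inc = s_inc, s_dec = s_dec)
    })
  }

  if (dci_first) { d <- dci_block(); cc <- cci_block() }
  else           { cc <- cci_block(); d <- dci_block() }

  cci_new <- cci
  idx <- survives & cc$change
  cci_new[idx] <- cci[idx] + cc$inc[idx]

  dci_new <- dci
  idx_up <- survives & d$change & d$up
  idx_dn <- survives & d$change & !d$up
  dci_new[idx_up] <- dci[idx_up] + d$s_inc[idx_up]
  dci_new[idx_dn] <- pmax(-0.75, dci[idx_dn] - d$s_dec[idx_dn])

  age_new <- age
  age_new[survives] <- age[survives] + 1L

  list(age = age_new, cci = cci_new, dci = dci_new, alive = survives)
}

#' Advance simulated individuals by one year
#'
#' Applies the annual update cycle to one or more living individuals:
#' death draw first (a death ends the update with covariates untouched),
#' then CCI change and size, then DCI change, direction and size, then
#' age + 1. Each block consumes its own named RNG sub-stream, so performing
#' the DCI block before the CCI block gives bit-identical output.
#'
#' @param state list or data.frame with numeric fields `age`, `cci`, `dci`
#'   and logical `alive` (equal-length vectors; all must be alive).
#' @param models a [transition_model_set()].
#' @param streams an [rng_streams()] object (mutated in place).
#' @param max_age simulation age cap; individuals starting the year at this
#'   age are terminated.
#' @param dci_first perform the DCI block before the CCI block (the result
#'   is identical; exposed to make that property checkable).
#' @return state list with updated `age`, `cci`, `dci`, `alive`.
#' @export
advance_one_year <- function(state, models, streams, max_age = 105L,
                             dci_first = FALSE) {
  stopifnot(inherits(models, "transition_model_set"),
            all(c("age", "cci", "dci", "alive") %in% names(state)))
  if (!all(state$alive)) {
    stop("advance_one_year: all input individuals must be alive",
         call. = FALSE)
  }
  advance_cohort_year(state$age, state$cci, state$dci, state$alive,
                      models, streams, max_age = max_age,
                      dci_first = dci_first)
}

# ---- cohort simulation -----------------------------------------------------

# run n copies of possibly heterogeneous start states to death or the age
# cap (or for at most `horizon` years); shared engine for simulate_cohort
# and the cross-validation simulator
run_microsim <- function(age0, cci0, dci0, models, n_years = Inf,
                         max_age = 105L, streams) {
  n <- length(age0)
  age <- as.numeric(age0); cci <- as.numeric(cci0); dci <- as.numeric(dci0)
  alive <- rep(TRUE, n)
  surv <- 1
  mean_cci <- mean(cci); mean_dci <- mean(dci)
  t <- 0L
  while (any(alive) && t < n_years) {
    st <- advance_cohort_year(age, cci, dci, alive, models, streams,
                              max_age = max_age)
    age <- st$age; cci <- st$cci; dci <- st$dci; alive <- st$alive
    t <- t + 1L
    surv[t + 1L] <- mean(alive)
    mean_cci[t + 1L] <- if (any(alive)) mean(cci[alive]) else NA_real_
    mean_dci[t + 1L] <- if (any(alive)) mean(dci[alive]) else NA_real_
  }
  curve <- survival_curve(0:t, surv)
  attr(curve, "n") <- n
  attr(curve, "trajectories") <- data.frame(
    time = 0:t, n_alive = round(surv * n), mean_cci = mean_cci,
    mean_dci = mean_dci)
  curve
}

#' Simulate a cohort of identical men from one start state
#'
#' Runs `config$n_individuals` independent copies of the annual update from
#' an identical (age, CCI, DCI) start until death or the age cap, and
#' returns the fraction alive at each anniversary. The RNG sub-streams are
#' keyed by `(seed, start state)`, so grid combinations are independent and
#' reproducible regardless of execution order.
#'
#' @param start list with `age`, `cci`, `dci` (single values).
#' @param models a [transition_model_set()].
#' @param config a [sim_config()].
#' @return a [survival_curve()] with attributes `n` (cohort size), `start`,
#'   and `trajectories` (per-year mean CCI/DCI among survivors).
#' @export
simulate_cohort <- function(start, models, config = sim_config()) {
  stopifnot(inherits(models, "transition_model_set"),
            inherits(config, "sim_config"),
            all(c("age", "cci", "dci") %in% names(start)))
  if (start$age < 65 || start$age > config$max_age || start$cci < 0 ||
      start$dci < -0.75) {
    stop("simulate_cohort: start state outside legal ranges", call. = FALSE)
  }
  streams <- rng_streams(stream_seed(config$seed, round(start$age * 4),
                                     round(start$cci * 4),
                                     round(start$dci * 4)))
  n <- config$n_individuals
  curve <- run_microsim(rep(start$age, n), rep(start$cci, n),
                        rep(start$dci, n), models,
                        max_age = config$max_age, streams = streams)
  attr(curve, "start") <- start
  curve
}

#' Life expectancy as the area under a survival curve
#'
#' Trapezoidal quadrature over the annual knots,
#' \eqn{\sum_t (S_{t-1} + S_t)/2} — equivalently, half a year of credit in
#' the year of death. A step-function rule (full-year credit) is available
#' for sensitivity analyses.
#'
#' @param curve a [survival_curve()].
#' @param quadrature `"trapezoid"` (default) or `"step"`.
#' @return expected remaining years (>= 0).
#' @export
life_expectancy <- function(curve, quadrature = c("trapezoid", "step")) {
  quadrature <- match.arg(quadrature)
  curve <- survival_curve(curve$time, curve$survival)  # re-validate
  s <- curve$survival
  if (length(s) == 1L) return(0)
  switch(quadrature,
         trapezoid = sum((s[-1] + s[-length(s)]) / 2),
         step = sum(s[-length(s)]))
}

#' Life-expectancy table over a grid of start states
#'
#' Runs one [simulate_cohort()] per combination of the configured start
#' ages, CCI and DCI values and integrates each curve. Combinations use
#' independent RNG sub-streams keyed by the seed and the start state, so
#' results do not depend on execution order.
#'
#' @param models a [transition_model_set()].
#' @param config a [sim_config()].
#' @return a data.frame of class `life_expectancy_table` with columns
#'   `age`, `cci`, `dci`, `life_expectancy`, `n`, `seed`, and the config in
#'   attribute `config`.
#' @export
life_expectancy_grid <- function(models, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(dci = config$start_dci, cci = config$start_cci,
                      age = config$start_ages,
                      KEEP.OUT.ATTRS = FALSE)[, c("age", "cci", "dci")]
  le <- vapply(seq_len(nrow(grid)), function(i) {
    curve <- simulate_cohort(as.list(grid[i, ]), models, config)
    life_expectancy(curve, config$quadrature)
  }, numeric(1))
  out <- cbind(grid, life_expectancy = le, n = config$n_individuals,
               seed = config$seed)
  attr(out, "config") <- config
  class(out) <- c("life_expectancy_table", "data.frame")
  out
}

#' @export
print.life_expectancy_table <- function(x, ...) {
  cat("Life-expectancy table:", nrow(x), "start states, n =", x$n[1],
      "per state, quadrature =", attr(x, "config")$quadrature, "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
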