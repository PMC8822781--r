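#' Specification of a synthetic person-year cohort
#'
#' Describes a register-like cohort of elderly men generated from known
#' ground-truth transition models: entry ages 65-90, an age-shifted entry
#' CCI distribution (prevalence of CCI = 0 falling from about 80% at 65
#' towards about 45% at 90), entry DCI on the 0.25 grid with positive
#' values becoming more common with age, six exchangeable health-care
#' regions, an annual emigration-style censoring hazard, and an
#' administrative follow-up cap.
#'
#' @param n_individuals number of men in the cohort.
#' @param truth the ground-truth [transition_model_set()] driving the
#'   annual updates (default [example_transition_models()]).
#' @param seed integer seed.
#' @param entry_age_weights probability weights over entry ages 65:90
#'   (normalized internally; default mildly decreasing with age).
#' @param entry_cci_dist weights over CCI 0:10, or a `function(age)`
#'   returning them (default: age-shifted, CCI = 0 prevalence
#'   `0.8 - 0.35 (age - 65)/25`, remainder geometric).
#' @param entry_dci_dist weights over the DCI grid `seq(-0.75, 13.5, 0.25)`,
#'   or a `function(age)` returning them (default: age-shifted share of
#'   non-positive values, exponential decay above 0).
#' @param n_regions number of exchangeable region labels.
#' @param max_followup administrative follow-up cap in years; an individual
#'   still under follow-up in year `max_followup - 1` contributes that year
#'   as a censored row.
#' @param annual_censor_prob annual probability of censoring (emigration
#'   surrogate), decided at the start of each year.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_individuals = 25000L,
                                  truth = example_transition_models(),
                                  seed = 1L,
                                  entry_age_weights = NULL,
                                  entry_cci_dist = NULL,
                                  entry_dci_dist = NULL,
                                  n_regions = 6L,
                                  max_followup = 11L,
                                  annual_censor_prob = 0.02) {
  stopifnot(n_individuals >= 1L, inherits(truth, "transition_model_set"),
            n_regions >= 1L, max_followup >= 1L,
            annual_censor_prob >= 0, annual_censor_prob <= 1)
  if (is.null(entry_age_weights)) {
    entry_age_weights <- seq(1, 0.4, length.out = 26L)
  }
  if (length(entry_age_weights) != 26L || any(entry_age_weights < 0) ||
      sum(entry_age_weights) <= 0) {
    stop("synthetic_cohort_spec: entry_age_weights must be 26 non-negative ",
         "weights over ages 65:90", call. = FALSE)
  }
  if (is.null(entry_cci_dist)) {
    entry_cci_dist <- function(age) {
      p0 <- 0.8 - 0.35 * (age - 65) / 25
      c(p0, (1 - p0) * 0.45^(0:9) / sum(0.45^(0:9)))
    }
  }
  if (is.null(entry_dci_dist)) {
    entry_dci_dist <- function(age) {
      grid <- seq(-0.75, 13.5, by = 0.25)
      p_nonpos <- 0.30 - 0.15 * (age - 65) / 25
      w <- ifelse(grid <= 0, p_nonpos / 4, 0)
      pos <- grid > 0
      w[pos] <- (1 - p_nonpos) * exp(-grid[pos] / 1.2) /
        sum(exp(-grid[pos] / 1.2))
      w
    }
  }
  check_dist <- function(d, len, what) {
    if (is.function(d)) return(d)
    if (!is.numeric(d) || length(d) != len || any(d < 0) || sum(d) <= 0) {
      stop("synthetic_cohort_spec: ", what, " must be ", len,
           " non-negative weights (or a function of age)", call. = FALSE)
    }
    force(d)
    function(age) d
  }
  structure(
    list(n_individuals = as.integer(n_individuals), truth = truth,
         seed = as.integer(seed),
         entry_age_weights = entry_age_weights / sum(entry_age_weights),
         entry_cci_dist = check_dist(entry_cci_dist, 11L, "entry_cci_dist"),
         entry_dci_dist = check_dist(entry_dci_dist, 58L, "entry_dci_dist"),
         n_regions = as.integer(n_regions),
         max_followup = as.integer(max_followup),
         annual_censor_prob = annual_censor_prob),
    class = "synthetic_cohort_spec"
  )
}

#' Generate a synthetic person-year cohort
#'
#' Draws entry states per individual, then evolves each man annually under
#' the ground-truth models using the same update engine as the
#' microsimulation, emitting one person-year row per observed year. A year
#' is a death year, a censoring year (the man survives it, but emigration
#' or the administrative cut leaves next-year comorbidity unmeasured), or
#' a completed year carrying next-year CCI and DCI. Vital status is
#' observed in every emitted year — as when deaths come from a national
#' death register — so censored rows contribute valid non-events to the
#' death model. CCI paths are non-decreasing; DCI paths stay on the 0.25
#' grid at or above -0.75.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return person-year data.frame with columns `person_id`, `region`,
#'   `year_index`, `age`, `cci`, `dci`, `died`, `censored`, `cci_next`,
#'   `dci_next` (the last two `NA` on death/censoring years).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_individuals
  streams <- rng_streams(spec$seed,
                         names = c("entry", "censor",
                                   "mortality", "cci", "dci"))
  dci_grid <- seq(-0.75, 13.5, by = 0.25)
  entry <- with_stream(streams, "entry", function() {
    age <- sample(65:90, n, replace = TRUE, prob = spec$entry_age_weights)
    cci <- integer(n)
    dci <- numeric(n)
    for (a in sort(unique(age))) {
      idx <- which(age == a)
      wc <- spec$entry_cci_dist(a)
      wd <- spec$entry_dci_dist(a)
      if (length(wc) != 11L || length(wd) != 58L ||
          any(wc < 0) || any(wd < 0) || sum(wc) <= 0 || sum(wd) <= 0) {
        stop("generate_cohort: invalid entry distribution at age ", a,
             call. = FALSE)
      }
      cci[idx] <- sample(0:10, length(idx), replace = TRUE, prob = wc)
      dci[idx] <- sample(dci_grid, length(idx), replace = TRUE, prob = wd)
    }
    region <- sample.int(spec$n_regions, n, replace = TRUE)
    list(age = age, cci = cci, dci = dci, region = region)
  })

  active <- seq_len(n)
  age <- as.numeric(entry$age); cci <- as.numeric(entry$cci)
  dci <- entry$dci
  rows <- vector("list", spec$max_followup)
  for (t in seq_len(spec$max_followup) - 1L) {
    m <- length(active)
    if (m == 0L) break
    last_year <- t == spec$max_followup - 1L
    # vital status is observed for the whole year (as in a death register);
    # censoring means next-year comorbidity goes unmeasured, so it applies
    # only to survivors and leaves `died` truthfully observed
    cens_draw <- with_stream(streams, "censor",
                             function() stats::runif(m) < spec$annual_censor_prob)
    st <- advance_cohort_year(age, cci, dci, rep(TRUE, m), spec$truth,
                              streams)
    died <- !st$alive
    cens <- st$alive & (cens_draw | last_year)
    completed <- st$alive & !cens
    rows[[t + 1L]] <- data.frame(
      person_id = active, region = entry$region[active], year_index = t,
      age = as.integer(age), cci = as.integer(cci), dci = dci,
      died = as.integer(died), censored = as.integer(cens),
      cci_next = ifelse(completed, as.integer(st$cci), NA_integer_),
      dci_next = ifelse(completed, st$dci, NA_real_)
    )
    keep <- completed
    active <- active[keep]
    age <- st$age[keep]; cci <- st$cci[keep]; dci <- st$dci[keep]
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$person_id, out$year_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Entry-state prevalences by age
#'
#' Per entry age: number of men, prevalence of CCI = 0 and of DCI > 0 at
#' cohort entry. Ages without entrants are simply absent.
#'
#' @param cohort person-year data.frame (schema of [generate_cohort()]).
#' @return data.frame with columns `age`, `n`, `prev_cci0`, `prev_dci_pos`.
#' @export
summarize_entry_distributions <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("summarize_entry_distributions: empty cohort", call. = FALSE)
  }
  e <- cohort[cohort$year_index == 0L, , drop = FALSE]
  ages <- sort(unique(e$age))
  out <- do.call(rbind, lapply(ages, function(a) {
    s <- e[e$age == a, , drop = FALSE]
    data.frame(age = a, n = nrow(s), prev_cci0 = mean(s$cci == 0),
               prev_dci_pos = mean(s$dci > 0))
  }))
  rownames(out) <- NULL
  out
}
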