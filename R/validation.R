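#' Observed survival from a person-year cohort
#'
#' Product-limit (Kaplan-Meier) estimate on annual follow-up. Each
#' individual's follow-up is collapsed to a time-to-event pair at the
#' anniversary ending their last observed year: a death in year *t* is an
#' event at *t* + 1 (deaths are placed at the year's end, as in the
#' simulation); a censoring in year *t* — a survived year whose next-year
#' comorbidity went unmeasured — contributes risk time up to *t* + 1.
#'
#' @param cohort person-year data.frame (schema of [generate_cohort()]).
#' @param entry_filter optional function taking the entry rows
#'   (`year_index == 0`) and returning a logical vector selecting the
#'   subgroup to estimate on.
#' @return a [survival_curve()] at annual anniversaries, with attributes
#'   `n` (individuals) and `events` (deaths).
#' @export
observed_survival <- function(cohort, entry_filter = NULL) {
  stopifnot(is.data.frame(cohort))
  entry <- cohort[cohort$year_index == 0L, , drop = FALSE]
  if (!is.null(entry_filter)) {
    keep_ids <- entry$person_id[entry_filter(entry)]
    cohort <- cohort[cohort$person_id %in% keep_ids, , drop = FALSE]
  }
  if (nrow(cohort) == 0L) {
    stop("observed_survival: empty stratum after filtering", call. = FALSE)
  }
  ord <- order(cohort$person_id, cohort$year_index)
  cohort <- cohort[ord, , drop = FALSE]
  last <- !duplicated(cohort$person_id, fromLast = TRUE)
  lr <- cohort[last, , drop = FALSE]
  event <- lr$died == 1L
  time <- lr$year_index + 1L
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tmax <- max(time)
  s <- summary(fit, times = 0:tmax, extend = TRUE)$surv
  curve <- survival_curve(0:tmax, s)
  attr(curve, "n") <- length(time)
  attr(curve, "events") <- sum(event)
  curve
}

#' Years lost over a horizon
#'
#' The area *above* the survival curve over the first `horizon` years:
#' `horizon` minus the trapezoidal area under the curve up to the horizon.
#' Together with the restricted area under the curve it always sums to the
#' horizon.
#'
#' @param curve a [survival_curve()] extending at least to `horizon`.
#' @param horizon restriction horizon in years (default 10).
#' @return years lost, `>= 0`.
#' @export
years_lost <- function(curve, horizon = 10L) {
  curve <- survival_curve(curve$time, curve$survival)
  if (max(curve$time) < horizon) {
    stop("years_lost: curve ends at ", max(curve$time),
         " years, before the horizon ", horizon, call. = FALSE)
  }
  s <- curve$survival[curve$time <= horizon]
  horizon - sum((s[-1] + s[-length(s)]) / 2)
}

#' Observed versus simulated mean comorbidity trajectories
#'
#' Per year of follow-up, compares the mean CCI and DCI among individuals
#' still under observation (cohort rows at that `year_index`) with the
#' simulated means among survivors. Cohorts carrying a `stratum` column are
#' compared stratum by stratum against a named list of simulated
#' trajectories; year-stratum cells absent on either side are omitted.
#'
#' @param cohort person-year data.frame, optionally with a `stratum`
#'   column.
#' @param simulated a trajectory data.frame with columns `time`,
#'   `mean_cci`, `mean_dci` (the `trajectories` attribute of
#'   [simulate_cohort()]), or a named list of them keyed by stratum.
#' @return data.frame with per-(stratum, year) observed and simulated
#'   means and their differences.
#' @export
mean_trajectories <- function(cohort, simulated) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
  strata <- if ("stratum" %in% names(cohort)) {
    split(cohort, cohort$stratum)
  } else list(all = cohort)
  if (is.data.frame(simulated)) simulated <- list(all = simulated)
  out <- lapply(names(strata), function(sname) {
    if (!sname %in% names(simulated)) return(NULL)
    obs <- strata[[sname]]
    sim <- simulated[[sname]]
    years <- intersect(sort(unique(obs$year_index)), sim$time)
    if (!length(years)) return(NULL)
    do.call(rbind, lapply(years, function(t) {
      o <- obs[obs$year_index == t, , drop = FALSE]
      s <- sim[sim$time == t, , drop = FALSE]
      data.frame(stratum = sname, time = t, n_obs = nrow(o),
                 mean_cci_obs = mean(o$cci), mean_cci_sim = s$mean_cci,
                 mean_dci_obs = mean(o$dci), mean_dci_sim = s$mean_dci)
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    stop("mean_trajectories: no overlapping year-stratum cells",
         call. = FALSE)
  }
  out$diff_cci <- out$mean_cci_obs - out$mean_cci_sim
  out$diff_dci <- out$mean_dci_obs - out$mean_dci_sim
  rownames(out) <- NULL
  out
}

#' Calibration table for a probability model
#'
#' Bins predictions into equal-frequency bins and compares the mean
#' predicted probability with the observed event fraction per bin.
#'
#' @param predicted predicted probabilities.
#' @param outcomes binary outcomes (0/1), same length.
#' @param n_bins number of equal-frequency bins (default 10); reduced with
#'   a warning when there are fewer distinct predictions.
#' @return data.frame of class `calibration_table` with columns `bin`,
#'   `n`, `mean_predicted`, `observed_fraction`.
#' @export
calibration <- function(predicted, outcomes, n_bins = 10L) {
  if (length(predicted) == 0L || length(predicted) != length(outcomes)) {
    stop("calibration: predicted and outcomes must be non-empty and of ",
         "equal length", call. = FALSE)
  }
  if (n_bins < 2L) stop("calibration: n_bins must be >= 2", call. = FALSE)
  if (any(predicted < 0 | predicted > 1) || !all(outcomes %in% c(0, 1))) {
    stop("calibration: predicted must be probabilities, outcomes 0/1",
         call. = FALSE)
  }
  edges <- unique(stats::quantile(predicted, probs = seq(0, 1,
                                                         length.out = n_bins + 1L)))
  if (length(edges) - 1L < n_bins) {
    warning("calibration: fewer distinct predictions than bins; using ",
            max(1L, length(edges) - 1L), " bins")
  }
  if (length(edges) < 2L) {
    bin <- factor(rep(1L, length(predicted)))
  } else {
    bin <- cut(predicted, breaks = edges, include.lowest = TRUE)
  }
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- bin == b
    data.frame(bin = b, n = sum(idx),
               mean_predicted = mean(predicted[idx]),
               observed_fraction = mean(outcomes[idx]))
  }))
  rownames(out) <- NULL
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Observed-versus-simulated survival comparison
#'
#' Pointwise comparison of two survival curves over their common time
#' range, with restricted years lost for both sides when the curves reach
#' the horizon.
#'
#' @param observed,simulated [survival_curve()] objects.
#' @param horizon years-lost horizon (default 10).
#' @return object of class `comparison_report`: a list with `table`
#'   (per-time observed, simulated, difference), `max_abs_diff`,
#'   `years_lost_observed`, `years_lost_simulated`, `years_lost_diff`
#'   (the last three `NA` if either curve ends before the horizon).
#' @export
comparison_report <- function(observed, simulated, horizon = 10L) {
  times <- intersect(observed$time, simulated$time)
  if (!length(times)) {
    stop("comparison_report: curves share no time points", call. = FALSE)
  }
  o <- observed$survival[match(times, observed$time)]
  s <- simulated$survival[match(times, simulated$time)]
  tab <- data.frame(time = times, observed = o, simulated = s,
                    difference = o - s)
  reach <- max(observed$time) >= horizon && max(simulated$time) >= horizon
  ylo <- if (reach) years_lost(observed, horizon) else NA_real_
  yls <- if (reach) years_lost(simulated, horizon) else NA_real_
  structure(list(table = tab, max_abs_diff = max(abs(tab$difference)),
                 years_lost_observed = ylo, years_lost_simulated = yls,
                 years_lost_diff = ylo - yls, horizon = horizon),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Observed vs simulated survival (", nrow(x$table), " time points)\n",
      sep = "")
  cat(sprintf("  max |difference|: %.4f\n", x$max_abs_diff))
  if (!is.na(x$years_lost_diff)) {
    cat(sprintf("  years lost over %d y: observed %.3f, simulated %.3f (diff %+.3f)\n",
                x$horizon, x$years_lost_observed, x$years_lost_simulated,
                x$years_lost_diff))
  }
  invisible(x)
}

#' Leave-one-region-out cross-validation
#'
#' For each region present in the cohort, transition models are fitted on
#' the other regions' person-years; a cohort is then simulated from the
#' held-out region's empirical entry-state distribution (resampled to
#' `config$n_individuals` individuals, followed for the region's observed
#' follow-up span) and compared with the held-out region's Kaplan-Meier
#' survival.
#'
#' @param cohort person-year data.frame with a `region` column holding at
#'   least two regions.
#' @param fit_fun fitting procedure mapping a person-year table to a
#'   [transition_model_set()] (default [fit_transition_models()]).
#' @param config a [sim_config()]; its seed and `n_individuals` drive the
#'   per-region simulations.
#' @param horizon years-lost horizon for the per-region reports.
#' @return named list of [comparison_report()]s (one per region), of class
#'   `crossval_report`; regions without entry rows are skipped with a note
#'   in attribute `skipped`.
#' @export
region_cross_validation <- function(cohort, fit_fun = fit_transition_models,
                                    config = sim_config(), horizon = 10L) {
  regions <- sort(unique(cohort$region))
  if (length(regions) < 2L) {
    stop("region_cross_validation: at least two regions required",
         call. = FALSE)
  }
  skipped <- character(0)
  reports <- list()
  for (r in regions) {
    held <- cohort[cohort$region == r, , drop = FALSE]
    entry <- held[held$year_index == 0L, , drop = FALSE]
    if (nrow(entry) == 0L) {
      skipped <- c(skipped, paste0("region ", r, ": no entry rows"))
      next
    }
    models <- fit_fun(cohort[cohort$region != r, , drop = FALSE])
    obs <- observed_survival(held)
    # stream keyed by the held-out entry-state content (not the region
    # label), so permuting region labels permutes the reports unchanged
    key <- (nrow(entry) + sum(entry$age * 13 + entry$cci * 101 +
                                round(entry$dci * 4) * 211)) %% 2147483647
    streams <- rng_streams(stream_seed(config$seed, 7919, key))
    idx <- with_stream(streams, "mortality", function() {
      sample.int(nrow(entry), config$n_individuals, replace = TRUE)
    })
    sim <- run_microsim(entry$age[idx], entry$cci[idx], entry$dci[idx],
                        models, n_years = max(obs$time),
                        max_age = config$max_age, streams = streams)
    reports[[paste0("region_", r)]] <-
      comparison_report(obs, sim, horizon = horizon)
  }
  structure(reports, class = "crossval_report", skipped = skipped)
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Leave-one-region-out cross-validation (", length(x), " regions)\n",
      sep = "")
  for (nm in names(x)) {
    cat(sprintf("  %s: max |diff| %.4f, years-lost diff %+.3f\n",
                nm, x[[nm]]$max_abs_diff, x[[nm]]$years_lost_diff))
  }
  if (length(attr(x, "skipped"))) {
    cat("  skipped:", paste(attr(x, "skipped"), collapse = "; "), "\n")
  }
  invisible(x)
}
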