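#' Bundle of all annual transition models
#'
#' A transition model set holds everything needed to advance one simulated
#' man through one year: the death model, the CCI-change models, the
#' DCI-change models, and the covariate categorizer shared by the change
#' models.
#'
#' @param death a [death_model_params()].
#' @param cci a [cci_change_params()].
#' @param dci a [dci_change_params()].
#' @param categorizer the shared [covariate_categorizer()].
#' @return object of class `transition_model_set`.
#' @export
transition_model_set <- function(death, cci, dci, categorizer) {
  stopifnot(inherits(death, "death_model_params"),
            inherits(cci, "cci_change_params"),
            inherits(dci, "dci_change_params"),
            inherits(categorizer, "covariate_categorizer"))
  structure(list(death = death, cci = cci, dci = dci,
                 categorizer = categorizer),
            class = "transition_model_set")
}

#' @export
print.transition_model_set <- function(x, ...) {
  cat("Transition model set (annual cycle)\n")
  print(x$death)
  cat("CCI change: occurrence + 1 + Poisson size (strata CCI = 0 / > 0)",
      if (!is.null(x$cci$size_fixed))
        sprintf("[size fixed at %d]", as.integer(x$cci$size_fixed)), "\n")
  cat("DCI change: occurrence + direction + Gamma sizes (shapes ",
      if (is.null(x$dci$step_fixed))
        sprintf("%.3g / %.3g", x$dci$increase$shape, x$dci$decrease$shape)
      else sprintf("[step fixed at %.2f]", x$dci$step_fixed),
      ")\n", sep = "")
  print(x$categorizer)
  invisible(x)
}

#' Fit all transition models from a person-year table
#'
#' Convenience wrapper running [fit_death_model()], [fit_cci_models()] and
#' [fit_dci_models()] on one long-format cohort table.
#'
#' @param table person-year data.frame (schema of
#'   [read_person_year_table()]).
#' @param categorizer a [covariate_categorizer()]; default bins if omitted.
#' @param cut_cci,cut_dci,cut_age QCS cut points for the death model.
#' @return a [transition_model_set()].
#' @export
fit_transition_models <- function(table, categorizer = covariate_categorizer(),
                                  cut_cci = 7, cut_dci = 14, cut_age = 100) {
  transition_model_set(
    death = fit_death_model(table, cut_cci, cut_dci, cut_age),
    cci = fit_cci_models(table, categorizer),
    dci = fit_dci_models(table, categorizer),
    categorizer = categorizer
  )
}
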