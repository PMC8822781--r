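#' Example ground-truth transition models
#'
#' A fully specified [transition_model_set()] with realistic magnitudes for
#' an elderly male population: annual death probability about 1.3% at age
#' 65 with no comorbidity rising to about 17% at age 90, odds of death
#' increasing in CCI and DCI with the effect attenuating with age (and
#' vanishing at 100 through the age-QCS interaction); roughly 10% annual
#' probability of a CCI increase; DCI changing in about half of all years,
#' slightly more often up than down, with mean step sizes below one unit.
#'
#' Used as the default ground truth of the synthetic-cohort generator and
#' as a worked-example model set.
#'
#' @param categorizer a [covariate_categorizer()].
#' @return a [transition_model_set()].
#' @export
example_transition_models <- function(categorizer = covariate_categorizer()) {
  death <- death_model_params(
    intercept = -7.27, beta_age = 0.075,
    beta_cci = -0.008, beta_dci = -0.003,
    gamma_cci = -6e-6, gamma_dci = -2.5e-6
  )
  cci <- cci_change_params(
    occurrence = cat_submodel_from_effects(
      categorizer, intercept = -2.2,
      age = c(0.30, 0.50), cci = c(0.30, 0.40, 0.50),
      dci = c(0.20, 0.30, 0.40)),
    size0 = cat_submodel_from_effects(
      categorizer, intercept = -1.2,
      age = c(0.10, 0.15), dci = c(0.10, 0.15, 0.20)),
    size1 = cat_submodel_from_effects(
      categorizer, intercept = -1.0,
      age = c(0.10, 0.15), cci = c(0.10, 0.20),
      dci = c(0.10, 0.15, 0.20),
      cci_levels = categorizer_levels(categorizer, "cci")[-1])
  )
  dci <- dci_change_params(
    occurrence = cat_submodel_from_effects(
      categorizer, intercept = 0.0,
      age = c(0.15, 0.25), cci = c(0.10, 0.15, 0.20),
      dci = c(0.10, 0.15, 0.20)),
    direction = cat_submodel_from_effects(
      categorizer, intercept = 0.35,
      age = c(0.10, 0.15), cci = c(0.05, 0.10, 0.15),
      dci = c(-0.20, -0.35, -0.50)),
    increase = list(shape = 2.0, mean = cat_submodel_from_effects(
      categorizer, intercept = -0.22,
      age = c(0.05, 0.10), dci = c(0.10, 0.15, 0.20))),
    decrease = list(shape = 2.0, mean = cat_submodel_from_effects(
      categorizer, intercept = -0.35,
      age = c(0.05, 0.08), dci = c(0.15, 0.30, 0.45)))
  )
  transition_model_set(death, cci, dci, categorizer)
}
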