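#' Annual death model parameters
#'
#' The probability of death within one year follows a person-year
#' ("life-table") logistic model with a linear age term, QCS main effects of
#' CCI and DCI, and age interactions through a QCS in age:
#' \deqn{\eta = \beta_0 + \beta_a\,\mathrm{age}
#'   + \beta_c\, g(\mathrm{CCI}; 7) + \beta_d\, g(\mathrm{DCI}; 14)
#'   + \gamma_c\, g(\mathrm{age}; 100)\, g(\mathrm{CCI}; 7)
#'   + \gamma_d\, g(\mathrm{age}; 100)\, g(\mathrm{DCI}; 14)}
#' with \eqn{g} the [qcs_value()] basis. Because \eqn{g} is decreasing,
#' comorbidity that raises mortality carries negative weights; the age-QCS
#' interaction (cut point 100 years) makes the comorbidity effect attenuate
#' with age and vanish at and beyond age 100.
#'
#' @param intercept,beta_age,beta_cci,beta_dci,gamma_cci,gamma_dci finite
#'   model coefficients (see Details for the linear predictor).
#' @param cut_cci,cut_dci,cut_age QCS cut points (defaults 7, 14, 100).
#' @return object of class `death_model_params`.
#' @export
death_model_params <- function(intercept, beta_age, beta_cci, beta_dci,
                               gamma_cci, gamma_dci,
                               cut_cci = 7, cut_dci = 14, cut_age = 100) {
  co <- c(intercept = intercept, beta_age = beta_age, beta_cci = beta_cci,
          beta_dci = beta_dci, gamma_cci = gamma_cci, gamma_dci = gamma_dci)
  if (anyNA(co) || any(!is.finite(co))) {
    stop("death_model_params: all coefficients must be finite", call. = FALSE)
  }
  structure(
    c(as.list(co), list(cut_cci = cut_cci, cut_dci = cut_dci,
                        cut_age = cut_age)),
    class = "death_model_params"
  )
}

#' @export
print.death_model_params <- function(x, ...) {
  cat("Annual death model (QCS life-table logistic)\n")
  cat(sprintf("  logit p = %.4g + %.4g age + %.4g g(CCI;%g) + %.4g g(DCI;%g)\n",
              x$intercept, x$beta_age, x$beta_cci, x$cut_cci,
              x$beta_dci, x$cut_dci))
  cat(sprintf("          + %.3g g(age;%g) g(CCI;%g) + %.3g g(age;%g) g(DCI;%g)\n",
              x$gamma_cci, x$cut_age, x$cut_cci,
              x$gamma_dci, x$cut_age, x$cut_dci))
  invisible(x)
}

# linear predictor, vectorized
death_eta <- function(age, cci, dci, params) {
  gc <- qcs_value(cci, params$cut_cci)
  gd <- qcs_value(dci, params$cut_dci)
  ga <- qcs_value(age, params$cut_age)
  params$intercept + params$beta_age * age +
    params$beta_cci * gc + params$beta_dci * gd +
    params$gamma_cci * ga * gc + params$gamma_dci * ga * gd
}

#' Annual probability of death
#'
#' Inverse-logit of the QCS life-table linear predictor (see
#' [death_model_params()]). Constant in CCI above the CCI cut point and in
#' DCI above the DCI cut point.
#'
#' @param age age in years, in `[65, 105]`.
#' @param cci Charlson Comorbidity Index, `>= 0`.
#' @param dci Drug Comorbidity Index, `>= -0.75`.
#' @param params a [death_model_params()].
#' @return vector of probabilities strictly inside (0, 1).
#' @export
death_probability <- function(age, cci, dci, params) {
  stopifnot(inherits(params, "death_model_params"))
  if (any(age < 65 | age > 105)) {
    stop("death_probability: age must be within [65, 105]", call. = FALSE)
  }
  if (any(cci < 0)) {
    stop("death_probability: cci must be >= 0", call. = FALSE)
  }
  if (any(dci < -0.75)) {
    stop("death_probability: dci must be >= -0.75", call. = FALSE)
  }
  stats::plogis(death_eta(age, cci, dci, params))
}

#' Fit the annual death model
#'
#' Maximum-likelihood logistic regression of the annual death indicator on
#' the QCS design of [death_probability()], over all person-year rows
#' (rows censored within the year contribute with `died = 0`).
#'
#' @param table person-year data.frame with columns `age`, `cci`, `dci`,
#'   `died` (see [read_person_year_table()] for the schema).
#' @param cut_cci,cut_dci,cut_age QCS cut points.
#' @return a [death_model_params()] with attributes `se` (named standard
#'   errors) and `n` (person-years used).
#' @export
fit_death_model <- function(table, cut_cci = 7, cut_dci = 14, cut_age = 100) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("fit_death_model: empty person-year table", call. = FALSE)
  }
  if (length(unique(table$died)) < 2L) {
    stop("fit_death_model: degenerate fit, outcome 'died' has a single ",
         "level", call. = FALSE)
  }
  dat <- data.frame(
    died = table$died,
    age  = table$age,
    qcci = qcs_value(table$cci, cut_cci),
    qdci = qcs_value(table$dci, cut_dci)
  )
  dat$qage_cci <- qcs_value(table$age, cut_age) * dat$qcci
  dat$qage_dci <- qcs_value(table$age, cut_age) * dat$qdci
  fit <- stats::glm(died ~ age + qcci + qdci + qage_cci + qage_dci,
                    family = stats::binomial(), data = dat)
  if (!fit$converged) {
    stop("fit_death_model: logistic fit did not converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_death_model: rank-deficient design (aliased: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")", call. = FALSE)
  }
  params <- death_model_params(
    intercept = cf[["(Intercept)"]], beta_age = cf[["age"]],
    beta_cci = cf[["qcci"]], beta_dci = cf[["qdci"]],
    gamma_cci = cf[["qage_cci"]], gamma_dci = cf[["qage_dci"]],
    cut_cci = cut_cci, cut_dci = cut_dci, cut_age = cut_age
  )
  se <- summary(fit)$coefficients[, "Std. Error"]
  attr(params, "se") <- stats::setNames(
    se[c("(Intercept)", "age", "qcci", "qdci", "qage_cci", "qage_dci")],
    c("intercept", "beta_age", "beta_cci", "beta_dci",
      "gamma_cci", "gamma_dci"))
  attr(params, "n") <- nrow(table)
  params
}
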