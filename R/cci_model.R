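#' CCI-change model parameters
#'
#' Annual changes in the (cumulative, never-decreasing) Charlson Comorbidity
#' Index are modelled in two steps: (1) a logistic occurrence model for
#' whether any change happens; (2) given a change, its size is
#' `1 + Poisson(exp(eta))`, with two Poisson regression models stratified by
#' current CCI = 0 versus CCI > 0. All sub-models use categorized covariates
#' (see [covariate_categorizer()]).
#'
#' @param occurrence logistic [cat_submodel()] for any-change (yes/no).
#' @param size0 Poisson [cat_submodel()] for the extra increment
#'   (size minus 1) among individuals with current CCI = 0.
#' @param size1 Poisson [cat_submodel()] for individuals with CCI > 0.
#' @param size_fixed optional positive integer: when set, the size step is
#'   deterministic at this value (used by the exact finite-state survival
#'   oracle, where the state space must stay finite).
#' @return object of class `cci_change_params`.
#' @export
cci_change_params <- function(occurrence, size0, size1, size_fixed = NULL) {
  stopifnot(inherits(occurrence, "cat_submodel"),
            inherits(size0, "cat_submodel"),
            inherits(size1, "cat_submodel"))
  if (!is.null(size_fixed)) {
    stopifnot(length(size_fixed) == 1L, size_fixed >= 1,
              size_fixed == round(size_fixed))
  }
  structure(list(occurrence = occurrence, size0 = size0, size1 = size1,
                 size_fixed = size_fixed),
            class = "cci_change_params")
}

#' Probability that CCI changes during the next year
#'
#' @param age,cci,dci current covariates (vectorized).
#' @param params a [cci_change_params()].
#' @param cat the [covariate_categorizer()] the model was built with.
#' @return probabilities in (0, 1).
#' @export
cci_change_probability <- function(age, cci, dci, params, cat) {
  stopifnot(inherits(params, "cci_change_params"))
  stats::plogis(cat_eta(params$occurrence, cat, age, cci, dci))
}

# Poisson mean of the extra increment (size - 1), using the stratum
# matching each individual's current CCI.
cci_increment_mean <- function(age, cci, dci, params, cat) {
  n <- max(length(age), length(cci), length(dci))
  age <- rep_len(age, n); cci <- rep_len(cci, n); dci <- rep_len(dci, n)
  mu <- numeric(n)
  s0 <- cci == 0
  if (any(s0)) {
    mu[s0] <- exp(cat_eta(params$size0, cat, age[s0], cci[s0], dci[s0]))
  }
  if (any(!s0)) {
    mu[!s0] <- exp(cat_eta(params$size1, cat, age[!s0], cci[!s0], dci[!s0]))
  }
  mu
}

#' Draw the size of a CCI change
#'
#' Given that a change occurs, the new CCI is the old one plus
#' `1 + Poisson(exp(eta))` where `eta` is the categorized linear predictor
#' of the stratum (CCI = 0 or CCI > 0) the individual is in. The draw is
#' always `>= 1`: CCI is cumulative and never decreases.
#'
#' @inheritParams cci_change_probability
#' @return integer increments `>= 1`, one per input state.
#' @export
sample_cci_increment <- function(age, cci, dci, params, cat) {
  stopifnot(inherits(params, "cci_change_params"))
  n <- max(length(age), length(cci), length(dci))
  if (!is.null(params$size_fixed)) {
    return(rep.int(as.integer(params$size_fixed), n))
  }
  mu <- cci_increment_mean(age, cci, dci, params, cat)
  1L + stats::rpois(n, mu)
}

#' Fit the two-step CCI-change model
#'
#' Occurrence is fitted on the indicator `cci_next > cci` over completed
#' person-years (rows with `cci_next` present); the size models are Poisson
#' regressions of `cci_next - cci - 1` among changed rows, stratified by
#' current CCI = 0 versus CCI > 0.
#'
#' @param table person-year data.frame.
#' @param cat a [covariate_categorizer()].
#' @return a [cci_change_params()]; each sub-model carries `se` and `n`
#'   attributes.
#' @export
fit_cci_models <- function(table, cat) {
  ok <- !is.na(table$cci_next)
  if (!any(ok)) {
    stop("fit_cci_models: no completed person-years (cci_next all absent)",
         call. = FALSE)
  }
  tab <- table[ok, , drop = FALSE]
  changed <- tab$cci_next > tab$cci
  if (length(unique(changed)) < 2L) {
    stop("fit_cci_models: degenerate occurrence fit, CCI ",
         if (any(changed)) "changes in every row" else "never changes",
         call. = FALSE)
  }
  fr <- categorize(cat, tab$age, tab$cci, tab$dci)
  occurrence <- fit_cat_glm(as.integer(changed), fr,
                            c("age_cat", "cci_cat", "dci_cat"),
                            stats::binomial(), "CCI occurrence model")
  ch <- tab[changed, , drop = FALSE]
  frc <- fr[changed, , drop = FALSE]
  y <- ch$cci_next - ch$cci - 1L
  s0 <- ch$cci == 0
  if (!any(s0) || all(s0)) {
    stop("fit_cci_models: size stratum for CCI ",
         if (all(s0)) "> 0" else "= 0",
         " has no changed rows", call. = FALSE)
  }
  fit_size <- function(idx, terms, what) {
    if (all(y[idx] == 0L)) {
      # every change in this stratum has size exactly 1: the extra-increment
      # rate sits on the boundary (log-mean -> -Inf); fix it at a mean
      # numerically indistinguishable from zero instead of failing
      warning(what, ": all change sizes are 1; increment rate fixed at ",
              "exp(-40)", call. = FALSE)
      sub <- cat_submodel(c("(Intercept)" = -40), character(0), list())
      attr(sub, "n") <- sum(idx)
      return(sub)
    }
    fit_cat_glm(y[idx], frc[idx, , drop = FALSE], terms, stats::poisson(),
                what)
  }
  size0 <- fit_size(s0, c("age_cat", "dci_cat"),
                    "CCI size model (CCI = 0 stratum)")
  size1 <- fit_size(!s0, c("age_cat", "cci_cat", "dci_cat"),
                    "CCI size model (CCI > 0 stratum)")
  cci_change_params(occurrence, size0, size1)
}
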