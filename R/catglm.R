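# Categorized-covariate GLM sub-models.
#
# Every comorbidity-change sub-model (CCI occurrence, CCI size strata, DCI
# occurrence/direction/size) is a GLM on treatment-coded dummies of the
# categorized covariates. A `cat_submodel` stores the coefficient vector
# together with the terms and factor levels of its design, so a fitted or
# hand-specified model is fully self-describing and predicts identically
# at fit and simulation time.

#' Construct a categorized-design GLM sub-model
#'
#' @param coefs named numeric coefficients, names as produced by
#'   [stats::model.matrix()] on the term factors (`"(Intercept)"`,
#'   `"age_cat[75,85)"`, ...).
#' @param terms character vector among `"age_cat"`, `"cci_cat"`, `"dci_cat"`.
#' @param xlev named list of factor levels for each term (levels observed /
#'   allowed at prediction time).
#' @return object of class `cat_submodel`.
#' @export
cat_submodel <- function(coefs, terms, xlev) {
  stopifnot(is.numeric(coefs), !is.null(names(coefs)),
            all(terms %in% c("age_cat", "cci_cat", "dci_cat")),
            is.list(xlev), all(terms %in% names(xlev)))
  if (anyNA(coefs) || any(!is.finite(coefs))) {
    stop("cat_submodel: coefficients must be finite (rank-deficient or ",
         "non-converged fit?)", call. = FALSE)
  }
  expected <- c("(Intercept)",
                unlist(lapply(terms, function(t) paste0(t, xlev[[t]][-1])),
                       use.names = FALSE))
  if (!identical(sort(names(coefs)), sort(expected))) {
    stop("cat_submodel: coefficient names do not conform to the design (",
         "expected: ", paste(expected, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(coefs = coefs[expected], terms = terms, xlev = xlev[terms]),
            class = "cat_submodel")
}

#' Build a sub-model from per-level effects
#'
#' Convenience constructor for specifying ground-truth models: effects are
#' given per non-reference level of each categorized covariate, in level
#' order.
#'
#' @param cat a [covariate_categorizer()].
#' @param intercept intercept on the linear-predictor scale.
#' @param age,cci,dci numeric effect vectors of length `nlevels - 1`
#'   (omit or `NULL` to leave the covariate out of the model).
#' @param cci_levels optional subset of CCI levels the model is defined on
#'   (used for the size model restricted to CCI > 0).
#' @return a [cat_submodel()].
#' @export
cat_submodel_from_effects <- function(cat, intercept = 0, age = NULL,
                                      cci = NULL, dci = NULL,
                                      cci_levels = NULL) {
  stopifnot(inherits(cat, "covariate_categorizer"))
  xlev <- list(age_cat = categorizer_levels(cat, "age"),
               cci_cat = if (is.null(cci_levels)) categorizer_levels(cat, "cci")
                         else cci_levels,
               dci_cat = categorizer_levels(cat, "dci"))
  eff <- list(age_cat = age, cci_cat = cci, dci_cat = dci)
  terms <- names(eff)[!vapply(eff, is.null, logical(1))]
  coefs <- c("(Intercept)" = intercept)
  for (t in terms) {
    lev <- xlev[[t]]
    if (length(eff[[t]]) != length(lev) - 1L) {
      stop("cat_submodel_from_effects: '", t, "' needs ", length(lev) - 1L,
           " effects (one per non-reference level)", call. = FALSE)
    }
    v <- eff[[t]]
    names(v) <- paste0(t, lev[-1])
    coefs <- c(coefs, v)
  }
  cat_submodel(coefs, terms, xlev)
}

# linear predictor of a cat_submodel at given covariates; treatment-coded
# dummies evaluated by direct level lookup (equivalent to model.matrix %*%
# coefs, but without materializing the design)
cat_eta <- function(sub, cat, age, cci, dci) {
  fr <- categorize(cat, age, cci, dci)
  eta <- rep.int(sub$coefs[["(Intercept)"]], nrow(fr))
  for (t in sub$terms) {
    lev <- sub$xlev[[t]]
    codemap <- match(levels(fr[[t]]), lev)
    ii <- codemap[as.integer(fr[[t]])]
    if (anyNA(ii)) {
      bad <- setdiff(unique(as.character(fr[[t]])), lev)
      stop("covariate category ", paste(bad, collapse = ", "),
           " outside the categories of the fitted '", t, "' term",
           call. = FALSE)
    }
    eta <- eta + c(0, unname(sub$coefs[paste0(t, lev[-1])]))[ii]
  }
  eta
}

# Fit a GLM on categorized covariates; returns a cat_submodel carrying
# standard errors and the glm dispersion info as attributes.
fit_cat_glm <- function(y, fr, terms, family, what = "sub-model",
                        keep_fit = FALSE) {
  fr <- droplevels(fr)
  # a factor constant in this stratum cannot enter the design
  terms <- terms[vapply(terms, function(t) nlevels(fr[[t]]) >= 2L, logical(1))]
  dat <- cbind(data.frame(.y = y), fr)
  form <- if (length(terms)) stats::reformulate(terms, response = ".y")
          else stats::as.formula(".y ~ 1")
  fit <- stats::glm(form, family = family, data = dat)
  if (!fit$converged) {
    stop("estimation of ", what, " did not converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("estimation of ", what, " is rank deficient (aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")", call. = FALSE)
  }
  xlev <- lapply(fr[terms], levels)
  names(xlev) <- terms
  sub <- cat_submodel(cf, terms, xlev)
  attr(sub, "se") <- summary(fit)$coefficients[names(sub$coefs), "Std. Error"]
  attr(sub, "n") <- length(y)
  if (keep_fit) attr(sub, "glm_fit") <- fit
  sub
}

#' @export
print.cat_submodel <- function(x, ...) {
  cat("Categorized GLM sub-model (terms:",
      paste(x$terms, collapse = ", "), ")\n")
  print(round(x$coefs, 4))
  invisible(x)
}
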