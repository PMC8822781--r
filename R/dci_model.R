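#' DCI-change model parameters
#'
#' Annual changes in the Drug Comorbidity Index can go both ways; they are
#' modelled in four steps: (1) logistic occurrence of any change; (2)
#' logistic direction (increase versus decrease) given a change; (3)/(4)
#' the size of an increase or a decrease, each a Gamma model with log link.
#' Raw Gamma draws are rounded to the DCI grid (0.25 steps, minimum step
#' 0.25); a decrease is truncated so DCI never falls below the grid floor
#' of -0.75.
#'
#' @param occurrence logistic [cat_submodel()] for any change (yes/no).
#' @param direction logistic [cat_submodel()] for increase given change.
#' @param increase,decrease lists `list(shape = <positive real>,
#'   mean = <cat_submodel>)`: Gamma shape and log-link mean model for the
#'   size of a change in that direction.
#' @param step_fixed optional positive grid multiple of 0.25: when set, the
#'   step size is deterministic at this value (used by the exact
#'   finite-state survival oracle).
#' @return object of class `dci_change_params`.
#' @export
dci_change_params <- function(occurrence, direction, increase, decrease,
                              step_fixed = NULL) {
  stopifnot(inherits(occurrence, "cat_submodel"),
            inherits(direction, "cat_submodel"))
  for (side in list(increase, decrease)) {
    stopifnot(is.list(side), is.numeric(side$shape), side$shape > 0,
              inherits(side$mean, "cat_submodel"))
  }
  if (!is.null(step_fixed)) {
    stopifnot(length(step_fixed) == 1L, step_fixed > 0,
              abs(step_fixed / 0.25 - round(step_fixed / 0.25)) < 1e-9)
  }
  structure(list(occurrence = occurrence, direction = direction,
                 increase = increase, decrease = decrease,
                 step_fixed = step_fixed),
            class = "dci_change_params")
}

#' Probabilities of DCI change and of its direction
#'
#' @param age,cci,dci current covariates (vectorized).
#' @param params a [dci_change_params()].
#' @param cat the [covariate_categorizer()] the model was built with.
#' @return a list with components `p_change` (probability of any change)
#'   and `p_increase` (probability the change is an increase, given change),
#'   both in (0, 1).
#' @export
dci_transition_probabilities <- function(age, cci, dci, params, cat) {
  stopifnot(inherits(params, "dci_change_params"))
  list(
    p_change   = stats::plogis(cat_eta(params$occurrence, cat, age, cci, dci)),
    p_increase = stats::plogis(cat_eta(params$direction, cat, age, cci, dci))
  )
}

# Gamma mean of the raw (pre-rounding) step size in one direction
dci_step_mean <- function(age, cci, dci, direction, params, cat) {
  side <- params[[direction]]
  mu <- exp(cat_eta(side$mean, cat, age, cci, dci))
  if (any(mu <= 0)) {
    stop("dci_step_mean: non-positive predicted mean step", call. = FALSE)
  }
  mu
}

#' Draw the size of a DCI change
#'
#' Given that a change occurs in the stated direction, draws a Gamma step
#' with the direction's shape and mean `exp(eta)`, rounds it to the nearest
#' 0.25 with a minimum of 0.25, and for decreases truncates the step so the
#' resulting DCI stays at or above -0.75 (at the floor, the recorded step
#' is 0 and the DCI stays at -0.75).
#'
#' @inheritParams dci_transition_probabilities
#' @param direction `"increase"` or `"decrease"`.
#' @return non-negative grid steps (multiples of 0.25), one per state; to be
#'   added to (increase) or subtracted from (decrease) the current DCI.
#' @export
sample_dci_step <- function(age, cci, dci, direction, params, cat) {
  stopifnot(inherits(params, "dci_change_params"))
  direction <- match.arg(direction, c("increase", "decrease"))
  n <- max(length(age), length(cci), length(dci))
  dci <- rep_len(dci, n)
  if (!is.null(params$step_fixed)) {
    step <- rep.int(params$step_fixed, n)
  } else {
    side <- params[[direction]]
    mu <- dci_step_mean(age, cci, dci, direction, params, cat)
    raw <- stats::rgamma(n, shape = side$shape, rate = side$shape / mu)
    step <- pmax(0.25, round(raw / 0.25) * 0.25)
  }
  if (direction == "decrease") {
    step <- pmin(step, dci + 0.75)  # floor at DCI = -0.75
  }
  step
}

# Gamma regression with log-link mean, by maximum likelihood on the DCI
# grid. A recorded step y is the raw Gamma draw rounded to the nearest
# 0.25 (minimum 0.25) and capped at the truncation bound (current DCI +
# 0.75, from the -0.75 floor; Inf for increases). Each observation
# therefore contributes the Gamma probability of its rounding cell —
# [y - 0.125, y + 0.125), widened to [0, 0.375) at the grid minimum — and
# steps at the bound contribute the upper tail beyond bound - 0.125. This
# interval likelihood removes the discretization and truncation bias a
# continuous-density fit would have at coarse grid steps.
fit_gamma_grid <- function(y, bound, fr, terms, what) {
  fr <- droplevels(fr)
  terms <- terms[vapply(terms, function(t) nlevels(fr[[t]]) >= 2L,
                        logical(1))]
  form <- if (length(terms)) stats::reformulate(terms)
          else stats::as.formula(~1)
  X <- stats::model.matrix(form, fr)
  cens <- y >= bound - 1e-9
  if (all(cens)) {
    stop("estimation of ", what, ": every observed step is truncated",
         call. = FALSE)
  }
  lo <- pmax(y - 0.125, 0)
  lo[abs(y - 0.25) < 1e-9] <- 0  # grid minimum absorbs all smaller draws
  hi <- y + 0.125
  clo <- pmax(bound - 0.125, 0)
  # a bound at the grid minimum captures every draw (the minimum step is
  # applied before the cap), so such rows are uninformative about the size
  clo[bound <= 0.25 + 1e-9] <- 0
  init <- stats::glm.fit(X[!cens, , drop = FALSE], y[!cens],
                         family = stats::Gamma(link = "log"))
  negll <- function(par) {
    shape <- exp(par[1L])
    rate <- shape / exp(drop(X %*% par[-1L]))
    ll <- suppressWarnings({
      cell <- stats::pgamma(hi[!cens], shape, rate[!cens]) -
        stats::pgamma(lo[!cens], shape, rate[!cens])
      sum(log(pmax(cell, 1e-300))) +
        sum(stats::pgamma(clo[cens], shape, rate[cens],
                          lower.tail = FALSE, log.p = TRUE))
    })
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(c(0, stats::coef(init)), negll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  if (opt$convergence != 0) {
    stop("estimation of ", what, " did not converge", call. = FALSE)
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, ncol(X))
        else sqrt(pmax(diag(vc)[-1L], 0))
  cf <- stats::setNames(opt$par[-1L], colnames(X))
  xlev <- lapply(fr[terms], levels)
  names(xlev) <- terms
  sub <- cat_submodel(cf, terms, xlev)
  attr(sub, "se") <- stats::setNames(se, names(sub$coefs))
  attr(sub, "n") <- length(y)
  attr(sub, "n_truncated") <- sum(cens)
  list(shape = unname(exp(opt$par[1L])), mean = sub)
}

#' Fit the four-step DCI-change model
#'
#' Over completed person-years (rows with `dci_next` present): occurrence is
#' fitted on `dci_next != dci`; direction on `dci_next > dci` among changed
#' rows; the size of a change is a Gamma model with log link fitted within
#' each direction, with mean coefficients and shape estimated jointly by
#' maximum likelihood on the 0.25 grid (each recorded step contributes the
#' Gamma probability of its rounding cell, so the coarse grid introduces no
#' bias).
#'
#' Two corrections deal with the DCI floor at -0.75. Person-years starting
#' exactly at the floor are excluded from all four fits: a decrease there is
#' unobservable (the index stays at the floor), so those rows are
#' uninformative about the change process. Decreases from above the floor
#' are observable but their size is right-truncated at `dci + 0.75`; steps
#' landing on the floor contribute the Gamma upper-tail probability.
#'
#' @param table person-year data.frame.
#' @param cat a [covariate_categorizer()].
#' @return a [dci_change_params()]; sub-models carry `se` and `n` attributes.
#' @export
fit_dci_models <- function(table, cat) {
  ok <- !is.na(table$dci_next) & table$dci > -0.75 + 1e-9
  if (!any(ok)) {
    stop("fit_dci_models: no completed person-years above the DCI floor",
         call. = FALSE)
  }
  tab <- table[ok, , drop = FALSE]
  delta <- tab$dci_next - tab$dci
  changed <- abs(delta) > 1e-9
  if (length(unique(changed)) < 2L) {
    stop("fit_dci_models: degenerate occurrence fit, DCI ",
         if (any(changed)) "changes in every row" else "never changes",
         call. = FALSE)
  }
  fr <- categorize(cat, tab$age, tab$cci, tab$dci)
  terms <- c("age_cat", "cci_cat", "dci_cat")
  occurrence <- fit_cat_glm(as.integer(changed), fr, terms,
                            stats::binomial(), "DCI occurrence model")
  up <- delta > 0
  if (!any(changed & up) || !any(changed & !up)) {
    stop("fit_dci_models: direction stratum (",
         if (any(changed & up)) "decrease" else "increase",
         ") has no changed rows", call. = FALSE)
  }
  direction <- fit_cat_glm(as.integer(up[changed]),
                           fr[changed, , drop = FALSE], terms,
                           stats::binomial(), "DCI direction model")
  iu <- changed & up
  inc <- fit_gamma_grid(delta[iu], rep(Inf, sum(iu)),
                        fr[iu, , drop = FALSE], terms,
                        "DCI increase-size model")
  id <- changed & !up
  dec <- fit_gamma_grid(-delta[id], tab$dci[id] + 0.75,
                        fr[id, , drop = FALSE], terms,
                        "DCI decrease-size model")
  dci_change_params(occurrence, direction, inc, dec)
}
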