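#' Covariate categorizer for the comorbidity-change models
#'
#' The CCI- and DCI-change models use categorized age, CCI and DCI rather
#' than the QCS basis of the death model. A categorizer holds the bin
#' definitions and produces consistent factors and design matrices for both
#' fitting and prediction.
#'
#' Default bins: CCI in \{0, 1, 2, >=3\}; DCI in \{<=0, (0,1], (1,3], >3\};
#' age in \{65-74, 75-84, >=85\}. All bins are configuration: supply your own
#' edges to match a different analysis plan.
#'
#' @param cci_breaks interior right-open break points for CCI (default
#'   `c(1, 2, 3)`, giving bins \{0\}, \{1\}, \{2\}, \{>=3\}).
#' @param dci_breaks interior right-closed break points for DCI (default
#'   `c(0, 1, 3)`).
#' @param age_breaks interior right-open break points for age in years
#'   (default `c(75, 85)`).
#' @return an object of class `covariate_categorizer`.
#' @export
covariate_categorizer <- function(cci_breaks = c(1, 2, 3),
                                  dci_breaks = c(0, 1, 3),
                                  age_breaks = c(75, 85)) {
  check_edges <- function(x, what) {
    if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
        any(diff(x) <= 0)) {
      stop("covariate_categorizer: ", what,
           " must be strictly increasing numeric edges", call. = FALSE)
    }
  }
  check_edges(cci_breaks, "cci_breaks")
  check_edges(dci_breaks, "dci_breaks")
  check_edges(age_breaks, "age_breaks")
  structure(
    list(cci_breaks = cci_breaks, dci_breaks = dci_breaks,
         age_breaks = age_breaks),
    class = "covariate_categorizer"
  )
}

#' @export
print.covariate_categorizer <- function(x, ...) {
  cat("Covariate categorizer\n")
  cat("  CCI bins:", paste(categorizer_levels(x, "cci"), collapse = ", "), "\n")
  cat("  DCI bins:", paste(categorizer_levels(x, "dci"), collapse = ", "), "\n")
  cat("  age bins:", paste(categorizer_levels(x, "age"), collapse = ", "), "\n")
  invisible(x)
}

#' Factor levels of a categorized covariate
#'
#' Interval labels (as produced by [base::cut()]) for one covariate under a
#' categorizer, e.g. `"[1,2)"` for the CCI = 1 bin.
#'
#' @param cat a [covariate_categorizer()].
#' @param which one of `"cci"`, `"dci"`, `"age"`.
#' @return character vector of level labels.
#' @export
categorizer_levels <- function(cat, which) {
  br <- switch(which,
               cci = cat$cci_breaks, dci = cat$dci_breaks,
               age = cat$age_breaks)
  right <- which == "dci"  # DCI bins are right-closed, CCI/age right-open
  full <- c(-Inf, br, Inf)
  levels(cut(numeric(0), breaks = full, right = right))
}

#' Categorize covariates
#'
#' Maps age, CCI and DCI values to their factor bins under a categorizer.
#'
#' @param cat a [covariate_categorizer()].
#' @param age,cci,dci numeric vectors of equal length (or length 1).
#' @return a data.frame with factor columns `age_cat`, `cci_cat`, `dci_cat`.
#' @export
categorize <- function(cat, age, cci, dci) {
  stopifnot(inherits(cat, "covariate_categorizer"))
  n <- max(length(age), length(cci), length(dci))
  age <- rep_len(age, n); cci <- rep_len(cci, n); dci <- rep_len(dci, n)
  if (anyNA(age) || anyNA(cci) || anyNA(dci)) {
    stop("categorize: covariates must not contain missing values",
         call. = FALSE)
  }
  data.frame(
    age_cat = cut(age, c(-Inf, cat$age_breaks, Inf), right = FALSE),
    cci_cat = cut(cci, c(-Inf, cat$cci_breaks, Inf), right = FALSE),
    dci_cat = cut(dci, c(-Inf, cat$dci_breaks, Inf), right = TRUE)
  )
}
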