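#' Quadratic-constant spline (QCS) basis
#'
#' Covariate transform used by the annual mortality model: a half-parabola
#' with its extremum at a cut point, joined continuously (with continuous
#' first derivative) to the constant zero above it,
#' \deqn{g(x; c) = (\min(x, c) - c)^2.}
#' The basis is strictly decreasing below the cut point and identically zero
#' at and above it, so a one-unit change in a comorbidity index moves the
#' linear predictor more strongly at low index values than near the cut
#' point, and not at all beyond it.
#'
#' Because \eqn{g} decreases in \eqn{x}, a covariate whose higher values
#' raise mortality carries a *negative* fitted weight on its QCS term.
#'
#' @param x numeric vector of covariate values (must be finite).
#' @param cut_point positive finite cut point, in the covariate's own units.
#'   The mortality model uses 7 for CCI, 14 for DCI and 100 years for the
#'   age interaction.
#' @return numeric vector of basis values, `(pmin(x, cut_point) - cut_point)^2`.
#' @examples
#' qcs_value(0:9, 7)
#' qcs_value(90, 100)
#' @export
qcs_value <- function(x, cut_point) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("qcs_value: 'x' must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(cut_point) || length(cut_point) != 1L ||
      !is.finite(cut_point) || cut_point <= 0) {
    stop("qcs_value: 'cut_point' must be a single positive finite number",
         call. = FALSE)
  }
  (pmin(x, cut_point) - cut_point)^2
}
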