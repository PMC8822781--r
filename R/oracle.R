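#' Exact survival by forward propagation of a finite Markov chain
#'
#' For transition model sets whose size distributions are degenerate (a
#' fixed CCI increment via `size_fixed` and a fixed DCI step via
#' `step_fixed`), the annual process is a finite Markov chain over
#' (age, CCI, DCI). This oracle propagates the state-probability
#' distribution exactly — no sampling — and is the reference against which
#' the Monte-Carlo simulator is validated.
#'
#' @param models a [transition_model_set()] with `cci$size_fixed` and
#'   `dci$step_fixed` set; non-degenerate size models are rejected.
#' @param start list with `age`, `cci`, `dci`.
#' @param horizon number of years to propagate (default: to the age cap).
#' @param max_age simulation age cap.
#' @return a [survival_curve()] with attributes `cci_mean` and `dci_mean`,
#'   the exact mean CCI and DCI among survivors at each anniversary.
#' @export
exact_survival_oracle <- function(models, start, horizon = NULL,
                                  max_age = 105L) {
  stopifnot(inherits(models, "transition_model_set"))
  kc <- models$cci$size_fixed
  kd <- models$dci$step_fixed
  if (is.null(kc) || is.null(kd)) {
    stop("exact_survival_oracle: requires degenerate size models ",
         "(cci$size_fixed and dci$step_fixed set)", call. = FALSE)
  }
  if (is.null(horizon)) horizon <- max_age - start$age + 1L
  cat <- models$categorizer

  cvals <- start$cci + kc * (0:horizon)
  dvals <- seq(-0.75, max(start$dci, start$dci + kd * horizon), by = 0.25)
  kdi <- as.integer(round(kd / 0.25))
  nr <- length(cvals); nc <- length(dvals)
  j0 <- which(abs(dvals - start$dci) < 1e-9)

  M <- matrix(0, nr, nc)
  M[1L, j0] <- 1
  grid_cci <- rep(cvals, times = nc)
  grid_dci <- rep(dvals, each = nr)

  surv <- 1
  cci_mean <- start$cci
  dci_mean <- start$dci

  # mass M*W moved by one CCI row and `cshift` DCI columns (clamped at the
  # -0.75 floor for decreases)
  move <- function(M, W, rshift, cshift) {
    A <- M * W
    out <- matrix(0, nr, nc)
    rsrc <- seq_len(nr - rshift)
    for (j in seq_len(nc)) {
      jdst <- if (cshift < 0) max(j + cshift, 1L) else j + cshift
      if (jdst > nc) {
        # the grid is sized so reachable mass never leaves it; columns
        # beyond the frontier are exactly empty
        if (any(A[rsrc, j] != 0)) {
          stop("exact_survival_oracle: internal grid overflow",
               call. = FALSE)
        }
        next
      }
      out[rsrc + rshift, jdst] <- out[rsrc + rshift, jdst] + A[rsrc, j]
    }
    out
  }

  for (t in seq_len(horizon)) {
    a <- start$age + t - 1L
    if (a >= max_age || sum(M) <= 0) {
      surv[t + 1L] <- 0
      cci_mean[t + 1L] <- NA_real_
      dci_mean[t + 1L] <- NA_real_
      M[] <- 0
      next
    }
    pd <- matrix(death_probability(a, grid_cci, grid_dci, models$death),
                 nr, nc)
    M <- M * (1 - pd)
    pc <- matrix(cci_change_probability(a, grid_cci, grid_dci, models$cci,
                                        cat), nr, nc)
    pr <- dci_transition_probabilities(a, grid_cci, grid_dci, models$dci,
                                       cat)
    pch <- matrix(pr$p_change, nr, nc)
    pup <- matrix(pr$p_increase, nr, nc)

    Mnew <- matrix(0, nr, nc)
    for (cmove in c(0L, 1L)) {
      wc <- if (cmove == 1L) pc else 1 - pc
      Mnew <- Mnew +
        move(M, wc * (1 - pch), cmove, 0L) +
        move(M, wc * pch * pup, cmove, kdi) +
        move(M, wc * pch * (1 - pup), cmove, -kdi)
    }
    M <- Mnew
    s <- sum(M)
    surv[t + 1L] <- s
    cci_mean[t + 1L] <- if (s > 0) sum(M * grid_cci) / s else NA_real_
    dci_mean[t + 1L] <- if (s > 0) sum(M * grid_dci) / s else NA_real_
    if (s <= 0) break
  }
  tmax <- length(surv) - 1L
  curve <- survival_curve(0:tmax, surv)
  attr(curve, "cci_mean") <- cci_mean
  attr(curve, "dci_mean") <- dci_mean
  curve
}
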