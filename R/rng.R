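# Named independent RNG sub-streams.
#
# The annual update consumes randomness from three named streams
# (mortality, cci, dci), each an independent Mersenne-Twister state. Every
# block of the yearly update draws a fixed number of variates from its own
# stream, computed from start-of-year covariates only, so reordering the
# CCI and DCI blocks leaves every stream's consumption — and hence the
# simulated trajectories — bit-identical.

# deterministic integer (< 2^31) derived from a seed and extra keys
stream_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (k in c(...)) {
    h <- (h * 69069 + (as.numeric(k) * 4 + 2147483587)) %% 2147483629
  }
  as.integer(h %% 2147483629) + 1L
}

#' Create named independent RNG sub-streams
#'
#' @param seed integer master seed.
#' @param names stream names (default `mortality`, `cci`, `dci`).
#' @return an environment holding one saved RNG state per stream.
#' @keywords internal
#' @export
rng_streams <- function(seed, names = c("mortality", "cci", "dci")) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  e <- new.env(parent = emptyenv())
  e$states <- lapply(seq_along(names), function(i) {
    set.seed(stream_seed(seed, 104729 * i))
    get(".Random.seed", envir = globalenv())
  })
  names(e$states) <- names
  class(e) <- "rng_streams"
  e
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run `fun()` under the named stream, saving its advanced state back
with_stream <- function(streams, name, fun) {
  stopifnot(inherits(streams, "rng_streams"),
            name %in% names(streams$states))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", streams$states[[name]], envir = globalenv())
  res <- fun()
  streams$states[[name]] <- get(".Random.seed", envir = globalenv())
  restore_rng(old)
  res
}
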