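# Physical constants used throughout (CODATA 2018).
# .hc_over_k is h*c/k_B in cm*K, the conversion between wavenumber and
# thermal energy; .c_cm_s is the speed of light in cm/s.
.hc_over_k <- 1.4387769
.c_cm_s <- 2.99792458e10
.c_cm_fs <- 2.99792458e-5 # speed of light in cm per femtosecond
.h_J_s <- 6.62607015e-34
.amu_kg <- 1.66053906660e-27

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators never disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# fast finite check for numeric vectors/matrices
all_finite <- function(x) all(is.finite(x))
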