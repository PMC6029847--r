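## Internal utilities: condition classes, seeded RNG scope, small numerics.

## All package errors inherit "collagenmech_error" plus a specific subclass so
## callers can condition on failure mode (e.g. "cm_no_contact", "cm_no_period").
cm_stop <- function(subclass, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(subclass, "collagenmech_error"),
                      call = call))
}

cm_check <- function(ok, subclass, message) {
  if (!isTRUE(ok)) cm_stop(subclass, message, call = sys.call(-2))
  invisible(TRUE)
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
## Guarantees byte-identical generator output for a fixed seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Force unit factor: F[nN] = HERTZ_UNIT * (E[kPa]/(1-nu^2)) * f(geometry[nm]).
## Derivation: kPa * nm^2 = 1e3 Pa * 1e-18 m^2 = 1e-15 N = 1e-6 nN.
.F_UNIT_NM_KPA <- 1e-6

## Sample standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

## Adjusted Fisher-Pearson standardised third moment (sample skewness g1
## rescaled by sqrt(n(n-1))/(n-2)); requires n >= 3.
skewness_g1 <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

## Parabolic (three-point) refinement of a discrete peak location.
## Returns fractional offset in [-0.5, 0.5] relative to the centre sample.
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
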