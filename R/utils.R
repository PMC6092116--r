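# Small shared helpers: axial (orientation) angle arithmetic and
# locally-scoped RNG seeding.

#' Axial difference between orientations
#'
#' Smallest absolute difference between two orientations in degrees,
#' treating angles as axial (modulo 180). The result lies in `[0, 90]`.
#'
#' @param a,b orientations in degrees (vectors recycle).
#' @return absolute axial differences in degrees.
#' @export
axial_difference <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

#' Wrap an orientation into `[0, 180)`
#' @param x degrees.
#' @export
wrap_orientation <- function(x) x %% 180

# Run `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
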