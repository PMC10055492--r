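# Internal numeric and RNG helpers.

#' Cumulative trapezoidal integral
#'
#' @param x grid (strictly increasing)
#' @param y values on the grid
#' @return vector of the same length as `x`; first element 0
#' @keywords internal
#' @noRd
cumTrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

#' @noRd
trapzInt <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Derive a named random stream seed from a root seed
#'
#' A single root seed spawns independent named sub-streams (simulation, mcmc,
#' training, inference, ...) so that changing one stage's stream does not
#' perturb the others. Purely arithmetic; result is always a valid 32-bit
#' integer seed.
#'
#' @param root integer root seed
#' @param stream character stream name
#' @return integer seed
#' @export
seedStream <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(stream))
  h <- 0
  for (c in utf8ToInt(stream)) h <- (h * 131 + c) %% 1048573
  v <- ((abs(root) %% 2147483647) * 1048573 + h * 31 + 17) %% 2147483629
  as.integer(v) + 1L
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
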