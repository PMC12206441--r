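#' Evaluate code with a locally seeded RNG
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so simulators are reproducible without disturbing the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

stopifnot_frac <- function(x, name) {
  stopifnot_scalar(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stopifnot_pos <- function(x, name, strict = TRUE) {
  stopifnot_scalar(x, name)
  if ((strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("'%s' must be %s", name,
                 if (strict) "> 0" else ">= 0"), call. = FALSE)
  invisible(x)
}

#' Standardised normal draws with exact sample moments
#'
#' Draws `n` standard-normal values and rescales them to have sample mean
#' exactly `mean` and sample SD exactly `sd` (n >= 2). Used to calibrate
#' synthetic groups whose true group statistics must equal stated values.
#'
#' @keywords internal
rnorm_exact <- function(n, mean = 0, sd = 1) {
  if (n == 1L) return(mean)
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
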