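#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so generators are deterministic without disturbing
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust noise scale of a signal
#'
#' Median absolute deviation from the median, scaled by 1/0.6745 so the
#' estimate is consistent for the standard deviation of Gaussian noise.
#' This is the conventional estimator for extracellular recordings, where
#' the sample SD is inflated by the spikes themselves.
#'
#' @param x Numeric vector.
#' @return Estimated noise standard deviation.
#' @export
robust_sigma <- function(x) {
  stats::median(abs(x - stats::median(x))) / 0.6745
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_fmt("'%s' must be a fraction in [0, 1]", name)
  invisible(x)
}
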