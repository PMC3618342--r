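#' Validate a frequency grid
#'
#' A frequency grid is an ordered vector of measurement frequencies in Hz.
#' All model equations are defined for angular frequency \eqn{\omega = 2\pi f}
#' with \eqn{\omega > 0}; a frequency of exactly zero is rejected here, and
#' callers wanting the DC behaviour should use [dc_limit()].
#'
#' @param f numeric vector of frequencies in Hz; finite, strictly positive,
#'   strictly increasing.
#' @return the validated frequency vector, invisibly classed as used
#'   throughout the package (a plain numeric vector).
#' @examples
#' f <- frequency_grid(c(0.1, 1, 10))
#' @export
frequency_grid <- function(f) {
  if (!is.numeric(f) || length(f) < 1L) {
    stop_fracz("invalid grid: frequencies must be a non-empty numeric vector")
  }
  if (any(!is.finite(f))) {
    stop_fracz("invalid grid: non-finite frequency at position ",
               which(!is.finite(f))[1L])
  }
  if (any(f <= 0)) {
    stop_fracz("invalid grid: non-positive frequency at position ",
               which(f <= 0)[1L], " (models are defined for omega > 0)")
  }
  if (length(f) > 1L && any(diff(f) <= 0)) {
    stop_fracz("invalid grid: frequencies must be strictly increasing ",
               "(violation after position ", which(diff(f) <= 0)[1L], ")")
  }
  as.numeric(f)
}

# angular frequency; the only place omega is derived from f
omega_of <- function(f) 2 * pi * frequency_grid(f)
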