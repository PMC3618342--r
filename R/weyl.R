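#' Truncated Fourier series (trigonometric polynomial)
#'
#' Represents \eqn{f(x) = \sum_{k=-K}^{K} c_k e^{jkx}} on the period
#' \eqn{2\pi}.  The fractional operators act coefficient-wise, so finite
#' trigonometric polynomials are the natural numeric carrier for every
#' operator statement exercised here.
#'
#' @param coeffs complex vector of length `2K + 1` holding \eqn{c_k} for
#'   `k = -K, ..., K` in increasing order of `k`.
#' @return an object of class `"fourier_poly"` with fields `k` and `c`.
#' @examples
#' harmonic(1)                      # e^{jx}
#' fourier_poly(c(0.5, 0, 0.5))     # cos(x)
#' @export
fourier_poly <- function(coeffs) {
  coeffs <- as.complex(coeffs)
  n <- length(coeffs)
  if (n < 3L || n %% 2L == 0L) {
    stop_fracz("invalid polynomial: need an odd number of coefficients ",
               ">= 3 (k = -K..K)")
  }
  if (any(!is.finite(Re(coeffs))) || any(!is.finite(Im(coeffs)))) {
    stop_fracz("invalid polynomial: non-finite coefficient")
  }
  K <- (n - 1L) %/% 2L
  structure(list(k = -K:K, c = coeffs, K = K), class = "fourier_poly")
}

#' @rdname fourier_poly
#' @param k harmonic index (nonzero integer); returns the single harmonic
#'   \eqn{e^{jkx}} embedded at truncation `K = |k|`.
#' @export
harmonic <- function(k) {
  stopifnot(is_number(k), k == round(k), k != 0)
  K <- abs(as.integer(k))
  coeffs <- rep(0 + 0i, 2L * K + 1L)
  coeffs[K + 1L + as.integer(k)] <- 1 + 0i
  fourier_poly(coeffs)
}

#' Evaluate a Fourier polynomial at points x
#' @param poly a [fourier_poly()].
#' @param x numeric vector of evaluation points.
#' @return complex values of the polynomial at `x`.
#' @export
fourier_eval <- function(poly, x) {
  stopifnot(inherits(poly, "fourier_poly"))
  vapply(x, function(xi) sum(poly$c * exp(1i * poly$k * xi)), 0i)
}

zero_mean <- function(poly) poly$c[poly$K + 1L] == 0 + 0i

assert_zero_mean <- function(poly) {
  stopifnot(inherits(poly, "fourier_poly"))
  if (!zero_mean(poly)) {
    stop_fracz("domain error: the mean term c_0 must be excluded ",
               "(exactly zero) for fractional operators of Weyl type")
  }
  invisible(poly)
}

#' Weyl fractional derivative / integral on a Fourier polynomial
#'
#' The Weyl operator of order `alpha` multiplies each coefficient by
#' \eqn{(jk)^{\alpha}} (derivative) or \eqn{(jk)^{-\alpha}} (integral),
#' principal branch, with the mean term `k = 0` excluded structurally: a
#' nonzero `c_0` is a domain error, not a numerical tolerance.  `alpha = 0`
#' is the unit operator and returns the input unchanged.
#'
#' @param poly a zero-mean [fourier_poly()].
#' @param alpha real operator order.
#' @param mode `"derivative"` or `"integral"`.
#' @return the transformed [fourier_poly()].
#' @examples
#' d <- weyl_apply(harmonic(1), 1)     # classical derivative: j e^{jx}
#' d$c
#' @export
weyl_apply <- function(poly, alpha, mode = c("derivative", "integral")) {
  mode <- match.arg(mode)
  assert_zero_mean(poly)
  if (!is_number(alpha)) stop_fracz("invalid parameter: `alpha` must be finite")
  if (alpha == 0) return(poly)
  s <- if (mode == "derivative") alpha else -alpha
  fac <- rep(0 + 0i, length(poly$k))
  nz <- poly$k != 0L
  fac[nz] <- exp(s * log(1i * poly$k[nz]))
  out <- poly
  out$c <- poly$c * fac
  out
}

#' Composition discrepancy of Weyl operators
#'
#' Returns \eqn{\max_k |(W^\alpha W^\beta - W^{\alpha+\beta})\,c_k|}.  The
#' operator family composes additively in the order; the discrepancy is
#' numerically below 1e-10 for \eqn{|\alpha|, |\beta| \le 2} on any
#' zero-mean polynomial.
#'
#' @param poly a zero-mean [fourier_poly()].
#' @param alpha,beta real operator orders.
#' @return maximum absolute coefficient discrepancy.
#' @export
weyl_compose_check <- function(poly, alpha, beta) {
  two_step <- weyl_apply(weyl_apply(poly, beta), alpha)
  one_step <- weyl_apply(poly, alpha + beta)
  max(Mod(two_step$c - one_step$c))
}

#' Generalized Weyl operator on a Fourier polynomial
#'
#' Coefficient-wise multiplication by the generalized symbol
#' \deqn{g_k = (jk\tau)^{\alpha + \beta\,\mathrm{Log}(jk\tau)}}
#' (principal branch), the operator counterpart of the generalized CPE
#' scaling.  For `beta = 0` and `tau = 1` the symbol is \eqn{(jk)^\alpha}
#' and the operator coincides with [weyl_apply()], the fractional derivative
#' of Weyl type.  The operator is linear and, like the classic one, excludes
#' the mean term.
#'
#' @param poly a zero-mean [fourier_poly()].
#' @param alpha fractional order.
#' @param beta remnant-memory coefficient.
#' @param tau non-negative relaxation-time parameter; `tau = 0` makes the
#'   symbol's logarithm undefined and is a domain error.
#' @return the transformed [fourier_poly()].
#' @export
gen_weyl_apply <- function(poly, alpha, beta = 0, tau = 1) {
  assert_zero_mean(poly)
  if (!is_number(alpha) || !is_number(beta)) {
    stop_fracz("invalid parameter: `alpha` and `beta` must be finite")
  }
  if (!is_number(tau) || tau < 0) {
    stop_fracz("invalid parameter: `tau` must be finite and >= 0")
  }
  if (tau == 0) {
    stop_fracz("domain error: generalized symbol undefined at tau = 0 ",
               "(log of zero)")
  }
  fac <- rep(0 + 0i, length(poly$k))
  nz <- poly$k != 0L
  L <- log(1i * poly$k[nz] * tau)       # principal branch, negative k allowed
  fac[nz] <- exp((alpha + beta * L) * L)
  out <- poly
  out$c <- poly$c * fac
  out
}

#' Impedance from the fractional circuit relation
#'
#' Drives the fractional constitutive relation of the (generalized) Cole
#' circuit with a unit sinusoidal current and returns the voltage/current
#' phasor ratio.  In dimensionless time \eqn{x = \omega t} the relation
#' reads, coefficient-wise on zero-mean polynomials,
#' \deqn{(1 + g_k)\, V_k = (R_0 + R_\infty\, g_k)\, I_k}
#' with \eqn{g_k} the (generalized) Weyl symbol at effective relaxation
#' scale \eqn{\omega\tau}.  The returned ratio reproduces [eval_cole()]
#' (`beta = 0`) and [eval_gc1()] (`p = 1`) at that frequency; the agreement
#' is the package's circuit-consistency check between the operator route
#' and the closed forms.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @param r0,r_inf,alpha,tau,beta model parameters as in [eval_gc1()].
#' @return complex impedance per `omega`, ohm.
#' @export
circuit_impedance <- function(omega, r0, r_inf, alpha, tau, beta = 0) {
  vapply(omega, function(om) {
    i_poly <- harmonic(1)
    di <- gen_weyl_apply(i_poly, alpha, beta = beta, tau = om * tau)
    # numerator polynomial r0*i + r_inf * D i, then divide per-k by (1 + g_k)
    num <- r0 * i_poly$c + r_inf * di$c
    g <- rep(0 + 0i, length(i_poly$k))
    nz <- i_poly$c != 0
    g[nz] <- di$c[nz] / i_poly$c[nz]
    v <- num
    v[nz] <- num[nz] / (1 + g[nz])
    idx <- which(i_poly$k == 1L)
    v[idx] / i_poly$c[idx]
  }, 0i)
}

#' Operator property suite for the Weyl module
#'
#' Runs the algebraic property checks on random zero-mean trigonometric
#' polynomials and the circuit-consistency comparison against the closed
#' forms, returning the maximum discrepancy of each property.  Used by the
#' `weyl-check` CLI subcommand.
#'
#' @param seed integer RNG seed for the random polynomial draws.
#' @param n_draws number of random polynomials per property.
#' @param K_max maximal truncation order of the random polynomials.
#' @return named numeric vector of maximum discrepancies.
#' @export
weyl_check <- function(seed = 1L, n_draws = 25L, K_max = 8L) {
  with_seed(seed, {
    rand_poly <- function() {
      K <- sample(2:K_max, 1L)
      coeffs <- complex(real = stats::rnorm(2 * K + 1),
                        imaginary = stats::rnorm(2 * K + 1))
      coeffs[K + 1L] <- 0 + 0i
      fourier_poly(coeffs)
    }
    compose <- identity_err <- linear <- reduce <- 0
    for (i in seq_len(n_draws)) {
      po <- rand_poly()
      a <- stats::runif(1, -2, 2)
      b <- stats::runif(1, -2, 2)
      compose <- max(compose, weyl_compose_check(po, a, b))
      inv <- weyl_apply(weyl_apply(po, a), a, mode = "integral")
      identity_err <- max(identity_err, max(Mod(inv$c - po$c)))
      qo <- rand_poly()
      # linearity on the common truncation
      Kc <- max(po$K, qo$K)
      pad <- function(pp) {
        cc <- rep(0 + 0i, 2 * Kc + 1)
        cc[Kc + 1 + pp$k] <- pp$c
        fourier_poly(cc)
      }
      po2 <- pad(po); qo2 <- pad(qo)
      lhs <- gen_weyl_apply(fourier_poly(2 * po2$c - 3i * qo2$c),
                            alpha = abs(a), beta = 0.05, tau = 2)
      rhs <- 2 * gen_weyl_apply(po2, abs(a), 0.05, 2)$c -
        3i * gen_weyl_apply(qo2, abs(a), 0.05, 2)$c
      linear <- max(linear, max(Mod(lhs$c - rhs)))
      red <- gen_weyl_apply(po, abs(a), beta = 0, tau = 1)
      reduce <- max(reduce, max(Mod(red$c - weyl_apply(po, abs(a))$c)))
    }
    # circuit consistency on a coarse sweep
    f <- exp(seq(log(0.1), log(1e5), length.out = 13))
    om <- 2 * pi * f
    zc <- circuit_impedance(om, 1.12e6, 1911, 0.743, 0.266)
    cole_err <- max(Mod(zc - eval_cole(1.12e6, 1911, 0.743, 0.266, f)) /
                      Mod(eval_cole(1.12e6, 1911, 0.743, 0.266, f)))
    zg <- circuit_impedance(om, 1.461e6, 2530, 0.707, 0.604, beta = 0.010132)
    gc1_err <- max(Mod(zg - eval_gc1(1.461e6, 2530, 0.707, 0.604,
                                     beta = 0.010132, f = f)) /
                     Mod(eval_gc1(1.461e6, 2530, 0.707, 0.604,
                                  beta = 0.010132, f = f)))
    c(composition = compose, inverse_pair = identity_err,
      linearity = linear, weyl_reduction = reduce,
      circuit_cole = cole_err, circuit_gc1 = gc1_err)
  })
}
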