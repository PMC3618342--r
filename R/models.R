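#' Generalized nonlinear frequency scaling of the GCPE
#'
#' The Cole dispersion scales frequency linearly through the factor
#' \eqn{(j\omega\tau)^\alpha}.  The generalized constant phase element
#' replaces the constant exponent by a partial Maclaurin series in the
#' principal complex logarithm of the dimensionless frequency,
#' \deqn{s(\omega) = (j\omega\tau)^{E(\omega)}, \qquad
#'       E(\omega) = \alpha + \sum_{m=1}^{5} c_m \, \mathrm{Log}(p\, j\omega\tau)^m,}
#' with \eqn{c = (\beta, \gamma, \delta, \epsilon, \zeta)}.  The scaling is
#' therefore non-linear and non-constant in frequency; \eqn{\beta} encodes
#' the remnant memory of the medium and `p` sets the reference scale of the
#' logarithmic correction.  For a vanishing coefficient family the factor
#' reduces exactly to \eqn{(j\omega\tau)^\alpha} for every `p`.
#'
#' All complex powers and logarithms use the principal branch, consistent
#' with the Weyl operator symbol for positive frequencies (see
#' [gen_weyl_apply()]).
#'
#' @param omega angular frequency in rad/s, > 0 (vectorized).
#' @param alpha fractional order in (0, 1].
#' @param beta remnant-memory coefficient.
#' @param tau relaxation time in seconds, > 0.
#' @param p non-negative scaling constant; `p = 0` with a nonzero
#'   coefficient family is a domain error (logarithm of zero).
#' @param gamma,delta,epsilon,zeta higher Maclaurin coefficients.
#' @return complex scaling factor, one value per `omega`.
#' @examples
#' gcpe_scaling(2 * pi, alpha = 0.8, beta = 0.074, tau = 2.883, p = 0.655)
#' # beta = 0 reduces to the Cole factor for any p:
#' gcpe_scaling(1, alpha = 0.7, beta = 0, tau = 1, p = 0.3)
#' @export
gcpe_scaling <- function(omega, alpha, beta = 0, tau = 1, p = 1,
                         gamma = 0, delta = 0, epsilon = 0, zeta = 0) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega <= 0)) {
    stop_fracz("domain error: omega must be finite and > 0")
  }
  assert_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  assert_number(p, "p", lower = 0)
  coeffs <- c(beta, gamma, delta, epsilon, zeta)
  if (any(!is.finite(coeffs))) {
    stop_fracz("domain error: memory coefficients must be finite")
  }
  L <- log(1i * omega * tau)            # principal branch: log(omega*tau) + i*pi/2
  if (all(coeffs == 0)) {
    return(exp(alpha * L))
  }
  if (p == 0) {
    stop_fracz("domain error: log of zero reference scale (p = 0) in the ",
               "generalized scaling")
  }
  z <- L + log(p)                       # Log(p * j * omega * tau)
  E <- alpha + coeffs[1] * z + coeffs[2] * z^2 + coeffs[3] * z^3 +
    coeffs[4] * z^4 + coeffs[5] * z^5
  exp(E * L)
}

# element impedance dr / (1 + s(omega)); omega vectorized
z_element <- function(el, omega) {
  if (is.null(el$dr)) {
    stop_fracz("invalid spec: element has no resistance increment; build the ",
               "model with `r0` or set `dr`")
  }
  s <- gcpe_scaling(omega, el$alpha, beta = el$beta, tau = el$tau, p = el$p,
                    gamma = el$gamma, delta = el$delta,
                    epsilon = el$epsilon, zeta = el$zeta)
  el$dr / (1 + s)
}

#' Impedance of a (generalized) constant phase element
#'
#' The classic CPE has \eqn{Z(\omega) = 1/(C_\alpha (j\omega)^\alpha)} with
#' constant phase \eqn{-\alpha\pi/2}; `alpha = 0` degenerates to a pure
#' resistance \eqn{1/C_\alpha} and `alpha = 1` to an ideal capacitor.  When
#' the parameter set carries a nonzero `beta` the generalized scaling of
#' [gcpe_scaling()] replaces the Cole factor:
#' \eqn{Z(\omega) = \tau^\alpha / (C_\alpha\, s(\omega))}, which reduces to
#' the classic expression for `beta = 0` and any `tau`.
#'
#' @param params a [cpe_params()] object.
#' @param f frequencies in Hz (validated by [frequency_grid()]).
#' @return complex impedance per frequency, ohm.
#' @examples
#' eval_cpe(cpe_params(2, 0), 1:10)          # 0.5 ohm resistor
#' eval_cpe(cpe_params(1, 1), 1 / (2 * pi))  # -1i at omega = 1
#' @export
eval_cpe <- function(params, f) {
  stopifnot(inherits(params, "fracz_cpe"))
  omega <- omega_of(f)
  if (params$beta == 0) {
    return(1 / (params$c_alpha * exp(params$alpha * log(1i * omega))))
  }
  s <- gcpe_scaling(omega, params$alpha, beta = params$beta,
                    tau = params$tau, p = params$p)
  params$tau^params$alpha / (params$c_alpha * s)
}

#' Impedance of the Cole model
#'
#' \deqn{Z(\omega) = R_\infty + (R_0 - R_\infty) / (1 + (j\omega\tau)^\alpha)}
#' The locus in the complex plane is a depressed circular arc;
#' `alpha = 1` gives the exact single-dispersion (Debye) semicircle.
#'
#' @param r0 zero-frequency resistance in ohm, > `r_inf`.
#' @param r_inf high-frequency resistance in ohm, >= 0.
#' @param alpha fractional order in (0, 1].
#' @param tau relaxation time in seconds, > 0.
#' @param f frequencies in Hz.
#' @return complex impedance per frequency, ohm.
#' @examples
#' eval_cole(1.12e6, 1911, 0.743, 0.266, c(0.1, 1, 10, 100))
#' @export
eval_cole <- function(r0, r_inf, alpha, tau, f) {
  assert_number(r_inf, "r_inf", lower = 0)
  assert_number(r0, "r0", lower = r_inf, strict_lower = TRUE)
  assert_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  omega <- omega_of(f)
  r_inf + (r0 - r_inf) / (1 + exp(alpha * log(1i * omega * tau)))
}

#' Impedance of the generalized Cole model (GC1)
#'
#' One generalized reduced Cole element (resistance increment
#' \eqn{\Delta R = p (R_0 - R_\infty)} in parallel with a generalized CPE)
#' in series with `r_inf`:
#' \deqn{Z(\omega) = R_\infty + \Delta R /
#'   (1 + (j\omega\tau)^{\alpha + \beta \mathrm{Log}(p\, j\omega\tau)}).}
#' For `beta = 0` and `p = 1` this is exactly [eval_cole()]; for nonzero
#' `beta` the impedance locus departs from the circular arc.
#'
#' @inheritParams eval_cole
#' @param beta remnant-memory coefficient.
#' @param p non-negative scaling constant (dispersion weight and log
#'   reference), default 1.
#' @return complex impedance per frequency, ohm.
#' @export
eval_gc1 <- function(r0, r_inf, alpha, tau, beta, f, p = 1) {
  assert_number(r_inf, "r_inf", lower = 0)
  assert_number(r0, "r0", lower = r_inf, strict_lower = TRUE)
  el <- gen_element(alpha = alpha, tau = tau, p = p, beta = beta,
                    dr = p * (r0 - r_inf))
  r_inf + z_element(el, omega_of(f))
}

#' Impedance of the Maclaurin-extended generalized Cole model (GGC1)
#'
#' Replaces the single \eqn{\beta} term of [eval_gc1()] by the five-term
#' partial Maclaurin sum with coefficients
#' \eqn{(\beta, \gamma, \delta, \epsilon, \zeta)} (see [gcpe_scaling()]).
#' Setting \eqn{\gamma = \delta = \epsilon = \zeta = 0} reduces exactly to
#' [eval_gc1()] with `p = 1`; all five coefficients zero reduce exactly to
#' [eval_cole()].
#'
#' @inheritParams eval_gc1
#' @param gamma,delta,epsilon,zeta higher Maclaurin coefficients.
#' @return complex impedance per frequency, ohm.
#' @export
eval_ggc1 <- function(r0, r_inf, alpha, tau, beta, gamma, delta, epsilon,
                      zeta, f) {
  assert_number(r_inf, "r_inf", lower = 0)
  assert_number(r0, "r0", lower = r_inf, strict_lower = TRUE)
  el <- ggc_element(alpha = alpha, tau = tau, beta = beta, gamma = gamma,
                    delta = delta, epsilon = epsilon, zeta = zeta,
                    dr = r0 - r_inf)
  r_inf + z_element(el, omega_of(f))
}

#' Impedance of a serial circuit of reduced (generalized) Cole elements
#'
#' \deqn{Z(\omega) = R_\infty + \sum_k \Delta R_k /
#'   (1 + s_k(\omega))}
#' where each summand is a reduced Cole element (classic constant exponent)
#' or a reduced generalized Cole element.  Element order affects only the
#' circuit label, never the sum.
#'
#' @param spec a [model_spec()].
#' @param f frequencies in Hz.
#' @return complex impedance per frequency, ohm.
#' @examples
#' m <- table_fixture("C2-d025")
#' head(eval_serial(m, c(0.1, 1, 10)))
#' @export
eval_serial <- function(spec, f) {
  if (!inherits(spec, "fracz_model")) {
    stop_fracz("invalid spec: expected a fracz_model object")
  }
  omega <- omega_of(f)
  z <- rep(complex(real = spec$r_inf, imaginary = 0), length(omega))
  for (el in spec$elements) z <- z + z_element(el, omega)
  z
}

#' @rdname eval_serial
#' @export
eval_model <- eval_serial

#' Self-consistent scaling constant p
#'
#' Diagnostic solver for the scaling constant of a generalized element.  The
#' implemented self-consistency condition requires the generalized scaling
#' factor, with log-reference `p`, to have modulus `p` at the fixed
#' dimensionless frequency \eqn{\omega\tau = e}:
#' \deqn{p = \left| (j e)^{\alpha + \beta \mathrm{Log}(p\, j e)} \right|,}
#' equivalently \eqn{\ln p = \alpha + \beta(1 + \ln p) - \beta \pi^2/4}.
#' For `beta = 0` the relation loses its logarithmic correction and
#' degenerates to the linear-scaling case \eqn{p = e^\alpha}.  The relation
#' is imposed at a fixed value of \eqn{\omega\tau}, so `tau` cancels; it is
#' kept in the signature for interface stability.
#'
#' This is a consistency diagnostic only: model evaluation and fitting treat
#' `p` as a free parameter, matching how the fitted tables report it.
#'
#' @param alpha fractional order in (0, 1].
#' @param beta remnant-memory coefficient (finite).
#' @param tau relaxation time in seconds, > 0 (does not affect the result).
#' @param bracket search interval for the non-negative root.
#' @return the non-negative root `p`; the fixed-point residual of the
#'   returned value is below 1e-10 (attribute `"residual"`).
#' @examples
#' solve_p(0.8, 0.05, 1)
#' solve_p(0.7, 0, 1)  # exp(0.7): no log correction
#' @export
solve_p <- function(alpha, beta, tau = 1, bracket = c(1e-8, 10)) {
  assert_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  if (!is_number(beta)) stop_fracz("invalid parameter: `beta` must be finite")

  fixed_point <- function(p) {
    # modulus of (j e)^(alpha + beta * Log(p * j * e)) minus p
    Le <- log(complex(real = 0, imaginary = exp(1)))   # 1 + i*pi/2
    E <- alpha + beta * (Le + log(p))
    Mod(exp(E * Le)) - p
  }

  if (beta == 0) {
    p <- exp(alpha)
  } else {
    lo <- bracket[1]
    hi <- bracket[2]
    flo <- fixed_point(lo)
    fhi <- fixed_point(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      stop_fracz("no-solution error: no sign change of the self-consistent ",
                 "relation on [", format(lo), ", ", format(hi), "] ",
                 "(residuals ", format(flo), ", ", format(fhi), ")")
    }
    p <- stats::uniroot(fixed_point, lower = lo, upper = hi,
                        tol = 1e-14)$root
  }
  resid <- fixed_point(p)
  if (!is.finite(resid) || abs(resid) > 1e-10) {
    stop_fracz("no-solution error: final residual ", format(resid),
               " exceeds 1e-10 on bracket [", format(bracket[1]), ", ",
               format(bracket[2]), "]")
  }
  structure(p, residual = resid)
}
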