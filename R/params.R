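#' Circuit elements of the reduced (generalized) Cole family
#'
#' A reduced Cole element is the parallel combination of a resistance
#' increment `dr` and a constant phase element, contributing
#' \deqn{Z_k(\omega) = \Delta R_k / (1 + (j\omega\tau_k)^{\alpha_k})}
#' to a series circuit.  Its generalized counterpart replaces the constant
#' exponent by a frequency-dependent one carrying the remnant-memory
#' coefficient \eqn{\beta} (kind `"gencole"`), and the Maclaurin-extended
#' element (kind `"ggc"`) carries the full five-coefficient partial sum
#' \eqn{\beta, \gamma, \delta, \epsilon, \zeta} (see [gcpe_scaling()]).
#'
#' The scaling constant `p` plays two roles: it is the dispersion weight
#' tying the element's resistance increment to the model-level dispersion
#' \eqn{\Delta R_k = p_k (R_0 - R_\infty)}, and for generalized elements it
#' sets the reference scale of the logarithmic exponent correction.  For
#' Maclaurin-extended elements `p` is fixed at 1.
#'
#' @param alpha fractional order, dimensionless, in (0, 1].
#' @param tau relaxation time in seconds, > 0.
#' @param p non-negative dimensionless scaling constant (dispersion weight).
#' @param beta remnant-memory coefficient, any sign.
#' @param gamma,delta,epsilon,zeta higher Maclaurin coefficients, any sign
#'   (`ggc_element` only).
#' @param dr resistance increment in ohm, >= 0, or `NULL` when the element
#'   is to receive its increment from the model-level `r0` via
#'   [model_spec()].
#' @return an object of class `"fracz_element"`.
#' @seealso [model_spec()], [eval_serial()]
#' @examples
#' cole_element(alpha = 0.75, tau = 0.3, dr = 1e6)
#' gen_element(alpha = 0.8, tau = 1.5, p = 0.65, beta = 0.074, dr = 5e5)
#' @export
cole_element <- function(alpha, tau, p = 1, dr = NULL) {
  new_element("cole", alpha = alpha, tau = tau, p = p, dr = dr)
}

#' @rdname cole_element
#' @export
gen_element <- function(alpha, tau, p = 1, beta = 0, dr = NULL) {
  new_element("gencole", alpha = alpha, tau = tau, p = p, beta = beta, dr = dr)
}

#' @rdname cole_element
#' @export
ggc_element <- function(alpha, tau, beta = 0, gamma = 0, delta = 0,
                        epsilon = 0, zeta = 0, dr = NULL) {
  new_element("ggc", alpha = alpha, tau = tau, p = 1, beta = beta,
              gamma = gamma, delta = delta, epsilon = epsilon, zeta = zeta,
              dr = dr)
}

new_element <- function(kind, alpha, tau, p = 1, beta = 0, gamma = 0,
                        delta = 0, epsilon = 0, zeta = 0, dr = NULL) {
  kind <- match.arg(kind, c("cole", "gencole", "ggc"))
  assert_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  assert_number(p, "p", lower = 0)
  for (nm in c("beta", "gamma", "delta", "epsilon", "zeta")) {
    if (!is_number(get(nm))) {
      stop_fracz("invalid parameter: `", nm, "` must be a finite numeric scalar")
    }
  }
  if (kind == "cole" && beta != 0) {
    stop_fracz("invalid parameter: a classic Cole element has beta = 0; ",
               "use gen_element() for beta != 0")
  }
  if (kind != "ggc" && any(c(gamma, delta, epsilon, zeta) != 0)) {
    stop_fracz("invalid parameter: Maclaurin coefficients require a ",
               "Maclaurin-extended element (ggc_element)")
  }
  if (kind == "ggc" && p != 1) {
    stop_fracz("invalid parameter: Maclaurin-extended elements fix p = 1")
  }
  if (!is.null(dr)) assert_number(dr, "dr", lower = 0)
  structure(
    list(kind = kind, dr = if (is.null(dr)) NULL else unname(dr),
         alpha = unname(alpha), tau = unname(tau), p = unname(p),
         beta = unname(beta), gamma = unname(gamma), delta = unname(delta),
         epsilon = unname(epsilon), zeta = unname(zeta)),
    class = "fracz_element"
  )
}

element_is_generalized <- function(el) {
  any(c(el$beta, el$gamma, el$delta, el$epsilon, el$zeta) != 0) ||
    el$kind != "cole"
}

#' Constant phase element parameters
#'
#' Parameters of a (generalized) constant phase element.  The classic CPE has
#' impedance \eqn{Z(\omega) = 1/(C_\alpha (j\omega)^\alpha)}; its phase is
#' frequency independent and equals \eqn{-\alpha\pi/2}.  The generalized CPE
#' additionally carries `beta`, `tau` and `p`, which feed the nonlinear
#' frequency scaling of [gcpe_scaling()].
#'
#' @param c_alpha capacitance of order `alpha` (unit: F s^(alpha-1)
#'   equivalent), > 0.
#' @param alpha fractional order in \[0, 1\]; `alpha = 0` gives a pure
#'   resistance `1/c_alpha`, `alpha = 1` an ideal capacitor.
#' @param beta remnant-memory coefficient (generalized CPE only).
#' @param tau time constant in seconds (generalized CPE only), > 0.
#' @param p non-negative scaling constant (generalized CPE only).
#' @return an object of class `"fracz_cpe"`.
#' @examples
#' cpe_params(c_alpha = 1e-6, alpha = 0.8)
#' @export
cpe_params <- function(c_alpha, alpha, beta = 0, tau = 1, p = 1) {
  assert_number(c_alpha, "c_alpha", lower = 0, strict_lower = TRUE)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  assert_number(tau, "tau", lower = 0, strict_lower = TRUE)
  assert_number(p, "p", lower = 0)
  if (!is_number(beta)) stop_fracz("invalid parameter: `beta` must be finite")
  structure(list(c_alpha = c_alpha, alpha = alpha, beta = beta,
                 tau = tau, p = p),
            class = "fracz_cpe")
}

canonical_labels <- c("C1", "C2", "C3", "GC1", "GC2", "GC1C1", "C1GC1", "GGC1")

# Infer the canonical circuit label from the element kinds.  Naming follows
# the permutation convention used for the serial models: C1GC1 is one
# generalized element followed by one classic element, GC1C1 the reverse.
infer_label <- function(elements) {
  kinds <- vapply(elements, `[[`, "", "kind")
  n <- length(kinds)
  if (all(kinds == "cole")) return(paste0("C", n))
  if (all(kinds == "gencole")) return(paste0("GC", n))
  if (identical(kinds, "ggc")) return("GGC1")
  if (identical(kinds, c("gencole", "cole"))) return("C1GC1")
  if (identical(kinds, c("cole", "gencole"))) return("GC1C1")
  NA_character_
}

#' Declarative description of a serial impedance circuit
#'
#' A model is a high-frequency series resistance `r_inf` followed by one or
#' more reduced (generalized) Cole elements in series.  Element resistance
#' increments may be given directly (`dr` set on each element) or derived
#' from the model-level zero-frequency resistance `r0` through the
#' dispersion weights: \eqn{\Delta R_k = p_k (R_0 - R_\infty)}.  For classic
#' models with weights summing to one the DC resistance then equals `r0`;
#' generalized models have different low-frequency asymptotics and their DC
#' behaviour is reported numerically by [dc_limit()].
#'
#' @param r_inf high-frequency series resistance in ohm, >= 0.
#' @param elements list of elements from [cole_element()] and friends.
#' @param r0 optional zero-frequency scale resistance in ohm (> `r_inf`).
#'   Required when any element lacks an explicit `dr`.
#' @param label optional canonical label; inferred from the element kinds
#'   when possible and checked for consistency when supplied.
#' @return an object of class `"fracz_model"`.
#' @examples
#' m <- model_spec(r_inf = 1911, r0 = 1.12e6,
#'                 elements = list(cole_element(0.743, 0.266, p = 0.267),
#'                                 cole_element(0.851, 1.414, p = 0.733)))
#' m$label
#' @export
model_spec <- function(r_inf, elements, r0 = NULL, label = NULL) {
  assert_number(r_inf, "r_inf", lower = 0)
  if (!is.list(elements) || length(elements) == 0L) {
    stop_fracz("invalid spec: `elements` must be a non-empty list of elements")
  }
  if (!all(vapply(elements, inherits, TRUE, "fracz_element"))) {
    stop_fracz("invalid spec: all elements must be fracz_element objects")
  }
  if (!is.null(r0)) {
    assert_number(r0, "r0", lower = r_inf, strict_lower = TRUE)
    elements <- lapply(elements, function(el) {
      dr_implied <- el$p * (r0 - r_inf)
      if (!is.null(el$dr) &&
          abs(el$dr - dr_implied) > 1e-8 * max(1, abs(dr_implied))) {
        stop_fracz("invalid spec: element dr = ", format(el$dr),
                   " conflicts with p * (r0 - r_inf) = ", format(dr_implied))
      }
      el$dr <- dr_implied
      el
    })
  } else {
    if (any(vapply(elements, function(el) is.null(el$dr), TRUE))) {
      stop_fracz("invalid spec: supply `r0` or an explicit `dr` per element")
    }
    # back out a shared dispersion scale when the weights allow it
    scales <- vapply(elements, function(el) {
      if (el$p > 0) el$dr / el$p else NA_real_
    }, 0)
    if (all(is.finite(scales)) &&
        diff(range(scales)) <= 1e-8 * max(1, max(scales))) {
      r0 <- r_inf + mean(scales)
    }
  }
  inferred <- infer_label(elements)
  if (is.null(label)) {
    label <- inferred
  } else if (!is.na(inferred) && !identical(label, inferred)) {
    stop_fracz("invalid spec: label \"", label,
               "\" is inconsistent with the element kinds (expected \"",
               inferred, "\")")
  }
  structure(list(r_inf = r_inf, r0 = r0, elements = elements, label = label),
            class = "fracz_model")
}

#' @export
print.fracz_model <- function(x, ...) {
  cat("<fracz_model> ", x$label %||% "custom",
      "  r_inf = ", format(x$r_inf), " ohm",
      if (!is.null(x$r0)) paste0("  r0 = ", format(x$r0), " ohm"), "\n", sep = "")
  for (i in seq_along(x$elements)) {
    el <- x$elements[[i]]
    extra <- switch(el$kind,
      cole    = "",
      gencole = sprintf("  beta = %g", el$beta),
      ggc     = sprintf("  beta = %g gamma = %g delta = %g epsilon = %g zeta = %g",
                        el$beta, el$gamma, el$delta, el$epsilon, el$zeta))
    cat(sprintf("  [%d] %-7s dr = %s ohm  alpha = %g  tau = %g s  p = %g%s\n",
                i, el$kind, format(el$dr), el$alpha, el$tau, el$p, extra))
  }
  invisible(x)
}

#' Total DC resistance of a classic serial model
#'
#' For models built purely from classic Cole elements the zero-frequency
#' resistance is `r_inf + sum(dr)`.  Generalized models have different
#' low-frequency asymptotics; use [dc_limit()] for those.
#' @param spec a [model_spec()].
#' @return DC resistance in ohm.
#' @export
dc_resistance <- function(spec) {
  stopifnot(inherits(spec, "fracz_model"))
  if (!all(vapply(spec$elements, `[[`, "", "kind") == "cole")) {
    stop_fracz("dc_resistance is defined for classic models only; ",
               "use dc_limit() for generalized models")
  }
  spec$r_inf + sum(vapply(spec$elements, `[[`, 0, "dr"))
}

#' Numeric DC limit of any model
#'
#' Evaluates the model at a small positive frequency (default 1e-6 Hz).  The
#' generalized models are reported numerically rather than asserted equal to
#' `r0` because their leading terms have different asymptotic behaviour for
#' nonzero memory coefficients.
#' @param spec a [model_spec()].
#' @param f_dc evaluation frequency in Hz.
#' @return complex impedance at `f_dc`.
#' @export
dc_limit <- function(spec, f_dc = 1e-6) {
  eval_serial(spec, f_dc)
}
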