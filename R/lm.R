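# Deterministic Levenberg-Marquardt least squares on a real residual vector.
#
# Damped normal equations with Nielsen's adaptive damping update and a
# central-difference Jacobian.  Everything is deterministic for fixed inputs,
# which the fitting module relies on for its bit-reproducibility contract.
# Non-finite residuals at a trial point reject the step (damping increases);
# non-finite residuals at the start return converged = FALSE rather than
# raising, per the fitting contract.

fracz_lm <- function(par, resid_fn,
                     ftol = 1e-12, ptol = 1e-12, gtol = 1e-12,
                     maxit = 5000L) {
  p <- as.numeric(par)
  n <- length(p)

  safe_resid <- function(x) {
    r <- tryCatch(resid_fn(x), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(NULL)
    r
  }

  jacobian <- function(x, r0_len) {
    J <- matrix(NA_real_, nrow = r0_len, ncol = n)
    for (i in seq_len(n)) {
      h <- 1e-6 * max(abs(x[i]), 1e-2)
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      rp <- safe_resid(xp)
      rm_ <- safe_resid(xm)
      if (is.null(rp) || is.null(rm_)) return(NULL)
      J[, i] <- (rp - rm_) / (2 * h)
    }
    J
  }

  r <- safe_resid(p)
  if (is.null(r)) {
    return(list(par = p, residuals = NA_real_, ss = Inf, n_iter = 0L,
                converged = FALSE,
                message = "non-finite residuals at the initial point"))
  }
  ss <- sum(r * r)
  lambda <- NA_real_
  nu <- 2
  msg <- "maximum iterations reached"
  converged <- FALSE
  it <- 0L
  n_tiny <- 0L  # consecutive accepted steps with negligible improvement

  while (it < maxit) {
    it <- it + 1L
    J <- jacobian(p, length(r))
    if (is.null(J)) { msg <- "non-finite Jacobian"; break }
    A <- crossprod(J)
    g <- crossprod(J, r)
    if (max(abs(g)) < gtol) { converged <- TRUE; msg <- "gradient tolerance"; break }
    if (is.na(lambda)) lambda <- 1e-3

    dA <- pmax(diag(A), 1e-12 * max(diag(A), 1e-300))
    accepted <- FALSE
    while (!accepted) {
      # Marquardt scaling: damping proportional to the curvature of each
      # direction keeps the step sensible when parameter sensitivities span
      # many orders of magnitude (the Maclaurin coefficients do)
      H <- A + lambda * diag(dA, n)
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- lambda * nu; nu <- 2 * nu
        if (lambda > 1e15) break
        next
      }
      delta <- as.numeric(delta)
      if (max(abs(delta) / (abs(p) + ptol)) < ptol) {
        converged <- TRUE; msg <- "step tolerance"; accepted <- TRUE
        break
      }
      p_try <- p + delta
      r_try <- safe_resid(p_try)
      ss_try <- if (is.null(r_try)) Inf else sum(r_try * r_try)
      predicted <- sum(delta * (lambda * dA * delta - g))  # > 0 when A psd
      rho <- if (predicted > 0) (ss - ss_try) / predicted else -1
      if (is.finite(ss_try) && ss_try < ss) {
        improve <- ss - ss_try
        p <- p_try; r <- r_try
        lambda <- lambda * max(1 / 3, 1 - (2 * rho - 1)^3)
        nu <- 2
        accepted <- TRUE
        n_tiny <- if (improve < ftol * max(ss, 1e-300)) n_tiny + 1L else 0L
        ss <- ss_try
        if (n_tiny >= 3L || ss < 1e-28) {
          converged <- TRUE; msg <- "cost tolerance"
        }
      } else {
        lambda <- lambda * nu
        nu <- 2 * nu
        if (lambda > 1e15) { msg <- "damping overflow (divergence)"; accepted <- TRUE }
      }
    }
    if (converged || msg == "damping overflow (divergence)" || lambda > 1e15) break
  }

  list(par = p, residuals = r, ss = ss, n_iter = it,
       converged = converged, message = msg)
}
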