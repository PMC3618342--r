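# Independent oracles: straight-line re-implementations of the model
# equations in plain real (polar) arithmetic, kept deliberately separate
# from the package's complex-log evaluation path.

# generalized scaling factor by explicit polar arithmetic, scalar omega
naive_scaling <- function(omega, alpha, tau, p = 1, beta = 0, gamma = 0,
                          delta = 0, epsilon = 0, zeta = 0) {
  lmod <- log(omega * tau)          # Log(j w tau) = lmod + i pi/2
  larg <- pi / 2
  zr <- lmod + log(p)               # Log(p j w tau)
  zi <- larg
  cs <- c(beta, gamma, delta, epsilon, zeta)
  e_re <- alpha
  e_im <- 0
  zm_r <- 1; zm_i <- 0
  for (m in 1:5) {
    tmp <- zm_r * zr - zm_i * zi
    zm_i <- zm_r * zi + zm_i * zr
    zm_r <- tmp
    e_re <- e_re + cs[m] * zm_r
    e_im <- e_im + cs[m] * zm_i
  }
  re <- e_re * lmod - e_im * larg
  im <- e_re * larg + e_im * lmod
  exp(re) * complex(real = cos(im), imaginary = sin(im))
}

naive_element <- function(omega, dr, alpha, tau, p = 1, beta = 0, gamma = 0,
                          delta = 0, epsilon = 0, zeta = 0) {
  dr / (1 + naive_scaling(omega, alpha, tau, p, beta, gamma, delta,
                          epsilon, zeta))
}

naive_cole <- function(omega, r0, r_inf, alpha, tau) {
  m <- (omega * tau)^alpha
  a <- alpha * pi / 2
  den <- complex(real = 1 + m * cos(a), imaginary = m * sin(a))
  r_inf + (r0 - r_inf) / den
}

naive_serial <- function(spec, omega) {
  z <- complex(real = spec$r_inf, imaginary = 0)
  for (el in spec$elements) {
    z <- z + naive_element(omega, el$dr, el$alpha, el$tau, el$p, el$beta,
                           el$gamma, el$delta, el$epsilon, el$zeta)
  }
  z
}

# dense bracketed bisection for the self-consistent p relation, independent
# of the production uniroot path
bisect_p <- function(alpha, beta, lo = 1e-8, hi = 10, iter = 200) {
  fp <- function(p) {
    le_r <- 1; le_i <- pi / 2                  # Log(j e)
    er <- alpha + beta * (le_r + log(p))
    ei <- beta * le_i
    Mod(exp(complex(real = er, imaginary = ei) *
              complex(real = le_r, imaginary = le_i))) - p
  }
  flo <- fp(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- fp(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# random valid parameter draws (seeded by the caller)
rand_cole_params <- function() {
  r_inf <- exp(runif(1, log(1e2), log(1e4)))
  list(r0 = r_inf + exp(runif(1, log(1e4), log(1e7))), r_inf = r_inf,
       alpha = runif(1, 0.3, 0.99), tau = exp(runif(1, log(1e-3), log(1e2))))
}

rand_mac <- function(scale = 0.02) {
  stats::rnorm(5, sd = scale * c(1, 0.5, 0.2, 0.05, 0.01))
}

acq_noiseless <- function(n_replicates = 1L) {
  acquisition_spec(noise_rel = 0, n_replicates = n_replicates)
}

grid61 <- function() default_grid(acquisition_spec())

# gauge-invariant (identifiable) summaries of a generalized model; see the
# methods vignette on the alpha/p/R0 ridge of single-beta elements
identifiable_params <- function(spec) {
  v <- c(r_inf = spec$r_inf)
  for (i in seq_along(spec$elements)) {
    el <- spec$elements[[i]]
    vi <- c(tau = el$tau, dr = el$dr,
            alpha_eff = el$alpha + el$beta * log(el$p),
            beta = el$beta)
    names(vi) <- paste0(names(vi), i)
    v <- c(v, vi)
  }
  v
}
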