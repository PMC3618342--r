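# closed-form model evaluation: CPE, Cole, generalized scaling, serial sums

test_that("CPE limits, frozen value and constant phase", {
  f <- grid61()
  # alpha = 0: pure resistance 1/c_alpha
  expect_equal(eval_cpe(cpe_params(2, 0), f), rep(0.5 + 0i, length(f)))
  # alpha = 1 at omega = 1: ideal capacitor
  expect_equal(eval_cpe(cpe_params(1, 1), 1 / (2 * pi)), 0 - 1i,
               tolerance = 1e-12)
  # alpha = 0.5 at omega = 1: frozen high-precision value (mpmath, 50 digits)
  expect_equal(eval_cpe(cpe_params(1, 0.5), 1 / (2 * pi)),
               complex(real = 0.7071067811865475244,
                       imaginary = -0.7071067811865475244),
               tolerance = 1e-12)
  # phase constancy across the whole grid
  ph <- Arg(eval_cpe(cpe_params(3.2e-6, 0.73), f))
  expect_lt(diff(range(ph)), 1e-12)
  expect_equal(ph[1], -0.73 * pi / 2, tolerance = 1e-12)
  # parameter guards
  expect_error(cpe_params(-1, 0.5), "c_alpha")
  expect_error(cpe_params(1, 1.2), "alpha")
})

test_that("Cole model: limits, alpha = 1 closed form, Debye semicircle", {
  f <- grid61()
  # DC limit
  z0 <- eval_cole(1.12e6, 1911, 0.743, 0.266, 1e-12)
  expect_equal(Re(z0), 1.12e6, tolerance = 1e-6)
  # alpha = 1, omega*tau = 1: r_inf + (r0 - r_inf) (1 - 1i)/2
  tau <- 0.5
  z1 <- eval_cole(2e6, 1e3, 1, tau, 1 / (2 * pi * tau))
  expect_equal(z1, 1e3 + (2e6 - 1e3) * (1 - 1i) / 2, tolerance = 1e-12)
  # alpha = 1 locus is the exact semicircle centred on (r_inf + r0)/2
  z <- eval_cole(2e6, 1e3, 1, tau, f)
  centre <- (2e6 + 1e3) / 2
  rad <- sqrt((Re(z) - centre)^2 + Im(z)^2)
  expect_equal(rad, rep((2e6 - 1e3) / 2, length(f)), tolerance = 1e-9)
  expect_error(eval_cole(1e3, 2e3, 0.8, 1, f), "r0")
  expect_error(eval_cole(1e6, 1e3, 0.8, 1, c(0, 1)), "grid")
})

test_that("gcpe_scaling: beta = 0 reductions hold exactly for any p", {
  f <- grid61()
  omega <- 2 * pi * f
  expect_equal(gcpe_scaling(1, alpha = 0.7, beta = 0, tau = 1, p = 0.3),
               exp(0.7 * log(1i)), tolerance = 1e-15)
  for (p in c(0.1, 1, 4.7)) {
    s <- gcpe_scaling(omega, alpha = 0.62, beta = 0, tau = 0.8, p = p)
    expect_equal(Mod(s), (omega * 0.8)^0.62, tolerance = 1e-13)
  }
})

test_that("gcpe_scaling matches frozen high-precision value and polar oracle", {
  # generalized element 2 of the GC2 d = 0.25 cm column at f = 1 Hz
  s <- gcpe_scaling(2 * pi, alpha = 0.805, beta = 0.074, tau = 2.883,
                    p = 0.655)
  expect_equal(s, complex(real = -4.557031337559839,
                          imaginary = 13.847111303192221),
               tolerance = 1e-10)
  set.seed(41)
  for (i in 1:50) {
    omega <- exp(runif(1, log(1e-2), log(1e5)))
    alpha <- runif(1, 0.2, 1)
    tau <- exp(runif(1, -3, 3))
    p <- exp(runif(1, -1, 1))
    beta <- rnorm(1, sd = 0.05)
    got <- gcpe_scaling(omega, alpha, beta = beta, tau = tau, p = p)
    expect_equal(got, naive_scaling(omega, alpha, tau, p, beta),
                 tolerance = 1e-10)
  }
})

test_that("gcpe_scaling domain errors", {
  expect_error(gcpe_scaling(0, 0.8), "omega")
  expect_error(gcpe_scaling(-1, 0.8), "omega")
  expect_error(gcpe_scaling(1, 0.8, beta = 0.1, tau = 1, p = 0),
               "log of zero")
  expect_error(gcpe_scaling(1, 0.8, tau = 0), "tau")
})

test_that("solve_p: fixed point, beta = 0 case, bisection oracle", {
  # residual contract
  for (cfg in list(c(0.743, 0), c(0.819, -0.015), c(0.805, 0.074),
                   c(0.532, 0.024), c(0.707, 0.010132))) {
    p <- solve_p(cfg[1], cfg[2], tau = 1)
    expect_lt(abs(attr(p, "residual")), 1e-10)
    expect_gte(as.numeric(p), 0)
  }
  # beta = 0 degenerates to the no-log-correction case
  expect_equal(as.numeric(solve_p(0.7, 0, 1)), exp(0.7), tolerance = 1e-12)
  # independent dense bisection oracle
  expect_equal(as.numeric(solve_p(0.8, 0.05, 1)), bisect_p(0.8, 0.05),
               tolerance = 1e-8)
  # frozen closed-form value
  expect_equal(as.numeric(solve_p(0.8, 0.05, 1)), 2.1487228154472765,
               tolerance = 1e-10)
  # tau cancels
  expect_equal(as.numeric(solve_p(0.8, 0.05, 1)),
               as.numeric(solve_p(0.8, 0.05, 37)), tolerance = 1e-12)
  expect_error(solve_p(0.8, 0.05, 1, bracket = c(5, 10)), "no-solution")
})

test_that("eval_gc1: Cole reduction, non-circular locus, frozen value", {
  f <- grid61()
  zc <- eval_cole(1.12e6, 1911, 0.743, 0.266, f)
  zg <- eval_gc1(1.12e6, 1911, 0.743, 0.266, beta = 0, f = f)
  expect_equal(zg, zc, tolerance = 1e-12)
  # beta != 0 departs from the circular arc: compare against the circle
  # through the beta = 0 locus (max orthogonal deviation nonzero)
  zb <- eval_gc1(1.12e6, 1911, 0.743, 0.266, beta = 0.05, f = f)
  expect_gt(max(Mod(zb - zc) / Mod(zc)), 1e-3)
  # GGC1 d = 2.0 cm base parameters, Maclaurin coefficients removed, f = 1 Hz
  expect_equal(eval_gc1(1.461e6, 2530, 0.707, 0.604, beta = 0.010132, f = 1),
               complex(real = 312601.024890575,
                       imaginary = -355158.177375797),
               tolerance = 1e-10)
})

test_that("eval_serial: single-term, commutativity, frozen two-term value", {
  f <- grid61()
  one <- model_spec(1500, list(cole_element(0.8, 0.4)), r0 = 1500 + 5e5)
  expect_equal(eval_serial(one, f), eval_cole(1500 + 5e5, 1500, 0.8, 0.4, f),
               tolerance = 1e-14)
  # element order affects labels only, never the sum
  e1 <- gen_element(0.7, 0.3, p = 0.6, beta = 0.03, dr = 3e5)
  e2 <- cole_element(0.9, 2, p = 0.4, dr = 2e5)
  m12 <- model_spec(1000, list(e1, e2))
  m21 <- model_spec(1000, list(e2, e1))
  expect_identical(m12$label, "C1GC1")
  expect_identical(m21$label, "GC1C1")
  expect_equal(eval_serial(m12, f), eval_serial(m21, f))
  # C2 d = 0.25 cm column at 1 Hz, frozen independent two-term value
  expect_equal(eval_serial(table_fixture("C2-d025"), 1),
               complex(real = 156552.645471355,
                       imaginary = -206905.373947926),
               tolerance = 1e-10)
  expect_error(model_spec(1000, list()), "non-empty")
})

test_that("eval_ggc1: truncation chain and frozen Table-2 value", {
  f <- grid61()
  # gamma..zeta = 0 reduces exactly to eval_gc1 (p = 1)
  z1 <- eval_ggc1(1.2e6, 2e3, 0.8, 0.5, beta = 0.02, gamma = 0, delta = 0,
                  epsilon = 0, zeta = 0, f = f)
  z2 <- eval_gc1(1.2e6, 2e3, 0.8, 0.5, beta = 0.02, f = f)
  expect_equal(z1, z2, tolerance = 1e-12)
  # all five zero reduces exactly to the Cole model
  z3 <- eval_ggc1(1.2e6, 2e3, 0.8, 0.5, 0, 0, 0, 0, 0, f = f)
  expect_equal(z3, eval_cole(1.2e6, 2e3, 0.8, 0.5, f), tolerance = 1e-12)
  # GGC1 d = 2.0 cm coefficients at 10 Hz, frozen high-precision value
  expect_equal(eval_ggc1(1.461e6, 2530, 0.707, 0.604, 0.010132, -0.004308,
                         -0.007025, -0.002536, -0.000206, f = 10),
               complex(real = -14271.1520711476,
                       imaginary = -5763.13484952431),
               tolerance = 1e-10)
})

test_that("reduction chain GGC1 -> GC1 -> Cole over random draws", {
  set.seed(7)
  f <- grid61()
  for (i in 1:100) {
    pp <- rand_cole_params()
    beta <- rnorm(1, sd = 0.03)
    zg <- eval_ggc1(pp$r0, pp$r_inf, pp$alpha, pp$tau, beta, 0, 0, 0, 0, f)
    z1 <- eval_gc1(pp$r0, pp$r_inf, pp$alpha, pp$tau, beta, f)
    zc <- eval_cole(pp$r0, pp$r_inf, pp$alpha, pp$tau, f)
    expect_lt(max(Mod(zg - z1) / Mod(z1)), 1e-12)
    z0 <- eval_gc1(pp$r0, pp$r_inf, pp$alpha, pp$tau, beta = 0, f)
    expect_lt(max(Mod(z0 - zc) / Mod(zc)), 1e-12)
  }
})

test_that("classic models: Re Z non-increasing, -Im Z >= 0, series additivity", {
  set.seed(11)
  f <- grid61()
  omega <- 2 * pi * f
  for (i in 1:25) {
    pp <- rand_cole_params()
    z <- eval_cole(pp$r0, pp$r_inf, pp$alpha, pp$tau, f)
    expect_true(all(diff(Re(z)) <= 1e-9 * Re(z)[-length(z)]))
    expect_true(all(-Im(z) >= -1e-12))
  }
  # additivity: serial sum equals element sums plus r_inf, exactly
  els <- list(cole_element(0.7, 0.2, dr = 2e5),
              gen_element(0.8, 1.5, p = 0.5, beta = 0.04, dr = 3e5),
              ggc_element(0.9, 0.8, beta = 0.01, gamma = -0.005, dr = 1e5))
  m <- model_spec(777, els)
  by_hand <- Reduce(function(acc, el) acc + fracz:::z_element(el, omega),
                    els, init = rep(777 + 0i, length(omega)))
  expect_identical(eval_serial(m, f), by_hand)
})

test_that("oracle equivalence on 1000 random (parameter, frequency) pairs", {
  set.seed(99)
  for (i in 1:1000) {
    omega <- exp(runif(1, log(1e-2), log(1e6)))
    pp <- rand_cole_params()
    kind <- sample(c("cole", "gencole", "ggc"), 1)
    if (kind == "cole") {
      got <- eval_cole(pp$r0, pp$r_inf, pp$alpha, pp$tau, omega / (2 * pi))
      expec <- naive_cole(omega, pp$r0, pp$r_inf, pp$alpha, pp$tau)
    } else if (kind == "gencole") {
      beta <- rnorm(1, sd = 0.04)
      p <- exp(runif(1, -0.7, 0.7))
      got <- eval_gc1(pp$r0, pp$r_inf, pp$alpha, pp$tau, beta,
                      omega / (2 * pi), p = p)
      expec <- pp$r_inf + naive_element(omega, p * (pp$r0 - pp$r_inf),
                                        pp$alpha, pp$tau, p, beta)
    } else {
      mac <- rand_mac()
      got <- eval_ggc1(pp$r0, pp$r_inf, pp$alpha, pp$tau, mac[1], mac[2],
                       mac[3], mac[4], mac[5], omega / (2 * pi))
      expec <- pp$r_inf + naive_element(omega, pp$r0 - pp$r_inf, pp$alpha,
                                        pp$tau, 1, mac[1], mac[2], mac[3],
                                        mac[4], mac[5])
    }
    expect_equal(got, expec, tolerance = 1e-10)
  }
})

test_that("model_spec invariants: labels, dr/r0 consistency, DC resistance", {
  m <- table_fixture("C2-d025")
  expect_identical(m$label, "C2")
  expect_equal(dc_resistance(m), 1.12e6, tolerance = 1e-12)
  expect_equal(Re(dc_limit(m)), 1.12e6, tolerance = 1e-4)
  # dr implied by r0 and weights
  expect_equal(m$elements[[1]]$dr, 0.267 * (1.12e6 - 1911))
  # conflicting label rejected
  expect_error(model_spec(1000, list(cole_element(0.8, 1, dr = 1e5)),
                          label = "GC1"), "label")
  # dr conflicting with p * (r0 - r_inf) rejected
  expect_error(model_spec(1000, list(cole_element(0.8, 1, p = 0.5, dr = 1e5)),
                          r0 = 2e5), "conflicts")
  expect_error(dc_resistance(table_fixture("GGC1-d20")), "classic")
})
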