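# Weyl fractional operators on truncated Fourier series

test_that("weyl_apply: classical derivative, unit operator, mean-term guard", {
  h <- harmonic(1)
  d <- weyl_apply(h, 1)
  expect_equal(d$c[d$k == 1], 1i + 0i, tolerance = 1e-15)
  # alpha = 0 is the unit operator, returned unchanged
  set.seed(5)
  coeffs <- complex(real = rnorm(7), imaginary = rnorm(7))
  coeffs[4] <- 0 + 0i
  po <- fourier_poly(coeffs)
  expect_identical(weyl_apply(po, 0), po)
  # the k = 0 exclusion is structural, not a tolerance
  coeffs[4] <- 1e-300 + 0i
  expect_error(weyl_apply(fourier_poly(coeffs), 0.5), "mean term")
  # integral inverts derivative
  back <- weyl_apply(weyl_apply(po, 0.62), 0.62, mode = "integral")
  expect_equal(back$c, po$c, tolerance = 1e-13)
})

test_that("composition W^a W^b = W^(a+b) and half-order special cases", {
  expect_lt(weyl_compose_check(harmonic(1), 0.5, 0.5), 1e-12)
  expect_lt(weyl_compose_check(harmonic(1), 0.3, -0.3), 1e-12)
  set.seed(17)
  for (i in 1:20) {
    K <- 8
    coeffs <- complex(real = rnorm(2 * K + 1), imaginary = rnorm(2 * K + 1))
    coeffs[K + 1] <- 0 + 0i
    po <- fourier_poly(coeffs)
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    expect_lt(weyl_compose_check(po, a, b), 1e-10)
  }
})

test_that("generalized operator: reduction, linearity, frozen symbol", {
  set.seed(23)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    coeffs <- complex(real = rnorm(2 * K + 1), imaginary = rnorm(2 * K + 1))
    coeffs[K + 1] <- 0 + 0i
    po <- fourier_poly(coeffs)
    # beta = 0, tau = 1 coincides with the Weyl derivative
    a <- runif(1, 0.1, 1.8)
    expect_equal(gen_weyl_apply(po, a, beta = 0, tau = 1)$c,
                 weyl_apply(po, a)$c, tolerance = 1e-12)
    # linearity
    qo <- fourier_poly(rev(coeffs))
    lhs <- gen_weyl_apply(fourier_poly(2 * po$c - 3i * qo$c), a, 0.05, 2)$c
    rhs <- 2 * gen_weyl_apply(po, a, 0.05, 2)$c -
      3i * gen_weyl_apply(qo, a, 0.05, 2)$c
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # frozen high-precision symbol for e^{jx}, alpha 0.8, beta 0.05, tau 2
  g <- gen_weyl_apply(harmonic(1), 0.8, 0.05, 2)
  expect_equal(g$c[g$k == 1],
               complex(real = 0.3213438867570784,
                       imaginary = 1.5433428470893604),
               tolerance = 1e-12)
  expect_error(gen_weyl_apply(harmonic(1), 0.8, 0.05, 0), "log of zero")
})

test_that("circuit relation reproduces the closed-form impedances", {
  f <- exp(seq(log(0.1), log(1e5), length.out = 31))
  omega <- 2 * pi * f
  zc <- circuit_impedance(omega, 1.12e6, 1911, 0.743, 0.266)
  ze <- eval_cole(1.12e6, 1911, 0.743, 0.266, f)
  expect_lt(max(Mod(zc - ze) / Mod(ze)), 1e-8)
  zg <- circuit_impedance(omega, 1.461e6, 2530, 0.707, 0.604,
                          beta = 0.010132)
  zge <- eval_gc1(1.461e6, 2530, 0.707, 0.604, beta = 0.010132, f = f)
  expect_lt(max(Mod(zg - zge) / Mod(zge)), 1e-8)
})

test_that("weyl_check property suite is within contract tolerances", {
  disc <- weyl_check(seed = 1)
  expect_lt(disc[["composition"]], 1e-10)
  expect_lt(disc[["inverse_pair"]], 1e-10)
  expect_lt(disc[["linearity"]], 1e-10)
  expect_lt(disc[["weyl_reduction"]], 1e-10)
  expect_lt(disc[["circuit_cole"]], 1e-8)
  expect_lt(disc[["circuit_gc1"]], 1e-8)
})

test_that("fourier_poly validation and evaluation", {
  expect_error(fourier_poly(c(1, 2)), "odd")
  expect_error(fourier_poly(c(1, NaN, 2)), "non-finite")
  po <- fourier_poly(c(0.5, 0, 0.5))      # cos(x)
  x <- seq(0, 2 * pi, length.out = 11)
  expect_equal(Re(fourier_eval(po, x)), cos(x), tolerance = 1e-14)
})
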