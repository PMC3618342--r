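# complex nonlinear least squares: residual stacking, LM fit, staged
# protocol, model comparison

test_that("stack_residuals: self-consistency, r_inf linearity, identity", {
  m <- table_fixture("C2-d025")
  sp <- mean_spectrum(simulate_spectrum(m, acq_noiseless()))
  expect_equal(stack_residuals(m, sp), rep(0, 2 * nrow(sp)))
  # shifting r_inf by +delta shifts every real residual by +delta, no
  # imaginary residual moves
  m2 <- m
  m2$r_inf <- m$r_inf + 123
  r <- stack_residuals(m2, sp)
  n <- nrow(sp)
  expect_equal(r[seq_len(n)], rep(123, n), tolerance = 1e-9)
  expect_equal(r[n + seq_len(n)], rep(0, n))
  # sum of squares identity vs direct complex norm
  set.seed(3)
  m3 <- perturb_spec(m, 1.4)
  r3 <- stack_residuals(m3, sp)
  dz <- eval_serial(m3, sp$frequency_hz) -
    complex(real = sp$z_real_ohm, imaginary = sp$z_imag_ohm)
  expect_equal(sum(r3^2), sum(Mod(dz)^2), tolerance = 1e-12)
  sp_bad <- sp
  sp_bad$z_real_ohm[3] <- NaN
  expect_error(stack_residuals(m, sp_bad), "data error")
})

test_that("fit is deterministic and a fixed point at the optimum", {
  truth <- table_fixture("C2-d025")
  sp <- simulate_spectrum(truth, acq_noiseless())
  # data at the optimum: returned estimates stay at the init, mse ~ 0
  at_opt <- fit_impedance(truth, sp)
  expect_lt(at_opt$mse, 1e-12)
  expect_equal(at_opt$spec$r0, truth$r0, tolerance = 1e-9)
  # bit-identical reruns
  f1 <- fit_impedance(perturb_spec(truth), sp)
  f2 <- fit_impedance(perturb_spec(truth), sp)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$mse, f2$mse)
})

test_that("C2 noiseless recovery from x1.2 init reaches 0.1%", {
  truth <- table_fixture("C2-d025")
  sp <- simulate_spectrum(truth, acq_noiseless())
  fit <- fit_impedance(perturb_spec(truth), sp)
  expect_true(fit$converged)
  cmp <- compare_spec_params(truth, fit$spec)
  expect_lt(max(cmp$rel_err), 1e-3)
})

test_that("mse conventions agree and more than ten parameters warns", {
  truth <- table_fixture("C2-d025")
  sp <- simulate_spectrum(truth, acquisition_spec(noise_rel = 1e-3,
                                                  n_replicates = 5,
                                                  seed = 4))
  fit <- fit_impedance(truth, sp)
  expect_gte(fit$mse, 0)
  expect_equal(fit$mse_scaled, fit$mse_mohm2 * 1e7)
  expect_equal(fit$mse, fit$mse_mohm2 * 1e12)
  expect_equal(fit$mse,
               sum(Mod(fit$residuals)^2) / length(fit$residuals))
  # an 11-free-parameter structure triggers the precondition warning
  els <- list(gen_element(0.7, 0.2, p = 0.5, beta = 0.01),
              gen_element(0.8, 1, p = 0.5, beta = 0.01),
              cole_element(0.9, 5, p = 0.2))
  wide <- model_spec(1000, els, r0 = 1e6)
  expect_warning(fit_impedance(wide, sp, max_iter = 2L), "free parameters")
})

test_that("non-convergence yields a flagged result, never an exception", {
  truth <- table_fixture("C2-d025")
  sp <- simulate_spectrum(truth, acq_noiseless())
  res <- fit_impedance(perturb_spec(truth, 3), sp, max_iter = 2L)
  expect_s3_class(res, "fracz_fit")
  expect_false(res$converged)
})

test_that("staged GC1 on Cole data drives beta to zero without worsening mse", {
  cole <- model_spec(2000, list(cole_element(0.8, 0.5)), r0 = 1e6)
  sp <- simulate_spectrum(cole, acq_noiseless())
  g <- staged_fit("GC1", sp)
  expect_true(g$converged)
  expect_lt(abs(g$spec$elements[[1]]$beta), 1e-6)
  expect_lte(g$mse, g$stage1$mse + 1e-12)
  expect_s3_class(g$stage1, "fracz_fit")
  expect_error(staged_fit("Z9", sp), "unknown model label")
})

test_that("staged GC2 recovers the memory coefficients within 1e-3", {
  truth <- table_fixture("GC2-d025")
  sp <- simulate_spectrum(truth, acq_noiseless())
  g <- staged_fit("GC2", sp)
  expect_true(g$converged)
  expect_equal(g$spec$elements[[1]]$beta, -0.015, tolerance = 1e-3)
  expect_equal(g$spec$elements[[2]]$beta, 0.074, tolerance = 1e-3)
  # gauge-invariant combinations recover to 0.1% (see methods vignette on
  # the alpha/p/R0 ridge of generalized elements)
  it <- identifiable_params(truth)
  ig <- identifiable_params(g$spec)
  expect_equal(ig, it, tolerance = 1e-3)
})

test_that("nesting monotonicity on noiseless nested data", {
  spg <- simulate_spectrum(table_fixture("GGC1-d20"), acq_noiseless())
  mse <- vapply(c("C1", "GC1", "GGC1"),
                function(lb) staged_fit(lb, spg)$mse, 0)
  expect_true(all(diff(mse) <= 1e-9 * pmax(mse[-3], 1)))
  spc <- simulate_spectrum(table_fixture("C2-d20"), acq_noiseless())
  mse2 <- vapply(c("C2", "GC2"), function(lb) staged_fit(lb, spc)$mse, 0)
  expect_lte(mse2[["GC2"]], mse2[["C2"]] + 1e-12)
})

test_that("compare_models ranks by ascending mse with tie-breaks", {
  sp <- simulate_spectrum(table_fixture("C2-d20"), acq_noiseless())
  tab <- compare_models(sp, c("GC2", "C2"))
  expect_identical(tab$rank, 1:2)
  expect_true(all(diff(tab$mse[tab$converged]) >= -1e-12))
  # C2 generated the data: GC2 cannot fit worse, and the improvement
  # percentage vs the classic baseline is finite and >= 0
  imp <- attr(tab, "improvement_pct_vs_classic")
  expect_true(is.finite(imp))
  expect_gte(imp, 0)
  expect_error(compare_models(sp, "C2"), "at least two")
})

test_that("fixture round trip: simulate noiselessly then staged_fit recovers", {
  truth <- table_fixture("C1GC1-d20")
  sp <- simulate_spectrum(truth, acq_noiseless())
  g <- staged_fit("C1GC1", sp)
  expect_true(g$converged)
  expect_lt(g$mse, 1e-10)
  it <- identifiable_params(truth)
  ig <- identifiable_params(g$spec)
  expect_equal(ig, it, tolerance = 1e-3)
})
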