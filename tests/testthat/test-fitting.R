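test_that("high-b log-linear step recovers a pure mono-exponential exactly", {
  sch <- liver_scheme()
  sig <- decay_signal(sch, 1000 * exp(-sch$b * 1e-3))
  res <- fit_monoexp_highb(sig, b_start = 0)
  expect_equal(res$d_slow, 1e-3, tolerance = 1e-10)
  expect_equal(res$pf_i, 0, tolerance = 1e-10)
  expect_identical(res$n_highb, 7L)
  # too few high-b points
  small <- decay_signal(acquisition_scheme(c(0, 30, 60, 100)),
                        exp(-c(0, 30, 60, 100) * 1e-3))
  expect_error(fit_monoexp_highb(small, 0), "at least 3")
})

test_that("high-b step on noiseless biex carries a small contamination bias", {
  # the residual fast signal at b = 60-100 (about 1% of the slow pool at the
  # canonical parameters) biases pf_i low by about 0.005; the bias is the
  # same scale at every starting b-value
  sig <- noiseless_biex_decay()
  p <- canonical_biex()
  r0 <- fit_monoexp_highb(sig, b_start = 0)
  expect_lt(abs(r0$pf_i - 0.2), 0.01)
  r20 <- fit_monoexp_highb(sig, b_start = 20)
  expect_lt(abs(r20$pf_i - shifted_pf(p, 20)), 0.01)
})

test_that("constrained one-parameter d_fast fit", {
  sig <- noiseless_biex_decay()
  # exact inputs recover d_fast to high precision
  res <- fit_dfast_constrained(sig, 0, d_slow = 1e-3, pf_i = 0.2)
  expect_equal(res$d_fast, 50e-3, tolerance = 1e-6)
  expect_true(res$converged)
  # a perturbed pf_i biases the estimate but keeps it finite and in bounds
  res2 <- fit_dfast_constrained(sig, 0, d_slow = 1e-3, pf_i = 0.21)
  expect_true(is.finite(res2$d_fast))
  bd <- ivim_bounds()$d_fast
  expect_gte(res2$d_fast, bd[1])
  expect_lte(res2$d_fast, bd[2])
  # degenerate constant signal: minimizer pinned at the lower bound
  const <- decay_signal(liver_scheme(), rep(500, 16))
  res3 <- fit_dfast_constrained(const, 0, d_slow = 1e-3, pf_i = 0.5)
  expect_false(res3$converged)
  expect_lt(res3$d_fast - bd[1], 1e-5)
})

test_that("segmented fit composes the two stages and validates b_start", {
  sig <- noiseless_biex_decay()
  fit <- segmented_fit(sig)
  expect_s3_class(fit, "ivim_fit")
  expect_lt(abs(fit$pf_i - 0.2), 0.02)
  expect_lt(abs(fit$d_slow - 1e-3) / 1e-3, 0.02)
  expect_lt(abs(fit$d_fast - 50e-3) / 50e-3, 0.1)
  expect_error(segmented_fit(sig, b_start = 5), "not a sampled")
  # tidy/glance interface
  td <- tidy(fit)
  expect_identical(td$term, c("pf_i", "d_slow", "d_fast"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("segmented pf_i tracks the closed-form shifted fraction", {
  p <- canonical_biex()
  sig <- noiseless_biex_decay(p)
  pfs <- vapply(c(0, 2, 4, 7, 10, 15, 20), function(bi) {
    segmented_fit(sig, b_start = bi)$pf_i
  }, numeric(1))
  expect_true(all(abs(pfs - shifted_pf(p, c(0, 2, 4, 7, 10, 15, 20))) < 0.01))
  # fitted pf_i strictly decreases with the starting b-value
  expect_true(all(diff(pfs) < 0))
})

test_that("full biex fit recovers noiseless truth and is deterministic", {
  sig <- noiseless_biex_decay()
  fit <- full_biex_fit(sig)
  expect_equal(fit$pf_i, 0.2, tolerance = 1e-4)
  expect_equal(fit$d_slow, 1e-3, tolerance = 1e-4)
  expect_equal(fit$d_fast, 50e-3, tolerance = 1e-4)
  fit2 <- full_biex_fit(sig)
  expect_identical(tidy(fit), tidy(fit2))
  # recovery from a later start too
  fit20 <- full_biex_fit(sig, b_start = 20)
  expect_equal(fit20$pf_i, shifted_pf(canonical_biex(), 20),
               tolerance = 1e-4)
  expect_lt(abs(fit20$d_fast - 50e-3) / 50e-3, 1e-4)
})

test_that("full biex on a triex curve absorbs both perfusion pools", {
  sig <- noiseless_triex_decay()
  fit <- full_biex_fit(sig)
  # pf_i approximates f_fast + f_vfast = 0.29
  expect_lt(abs(fit$pf_i - 0.29), 0.03)
})

test_that("segmented and full biex pf_i agree up to the high-b bias", {
  sig <- noiseless_biex_decay()
  gap <- abs(segmented_fit(sig)$pf_i - full_biex_fit(sig)$pf_i)
  expect_lt(gap, 0.01)
})

test_that("full triex fit recovers noiseless truth", {
  sig <- noiseless_triex_decay()
  fit <- full_triex_fit(sig)
  expect_true(fit$converged)
  expect_identical(fit$n_free, 6L)
  p <- fit$params
  expect_equal(p$f_slow, 0.71, tolerance = 0.02)
  expect_equal(p$f_fast, 0.15, tolerance = 0.02)
  expect_equal(p$f_vfast, 0.14, tolerance = 0.02)
  expect_lt(abs(p$d_slow - 1e-3) / 1e-3, 0.1)
  expect_lt(abs(p$d_fast - 50e-3) / 50e-3, 0.1)
  expect_lt(abs(p$d_vfast - 0.5) / 0.5, 0.1)
  expect_equal(p$f_slow + p$f_fast + p$f_vfast, 1, tolerance = 1e-9)
  # deterministic
  expect_identical(tidy(fit), tidy(full_triex_fit(sig)))
  # constrained 5-parameter variant agrees on a noiseless curve
  fit5 <- full_triex_fit(sig, constrain_fractions = TRUE)
  expect_identical(fit5$n_free, 5L)
  expect_equal(fit5$params$f_fast, 0.15, tolerance = 0.02)
})

test_that("full triex fit with a vanishing very fast pool", {
  tp <- triex_params(0.8, 0.2, 0, 1e-3, 50e-3, 0.5)
  sig <- noiseless_triex_decay(tp)
  fit <- full_triex_fit(sig)
  expect_lt(fit$params$f_vfast, 0.02)
  expect_error(full_triex_fit(sig[-1, ]), "b = 0")
})

test_that("all fitted parameters are invariant to global signal scaling", {
  sig <- noiseless_triex_decay()
  sigk <- sig
  sigk$signal <- sig$signal * 3.7
  f1 <- segmented_fit(sig); f2 <- segmented_fit(sigk)
  expect_equal(c(f1$pf_i, f1$d_slow, f1$d_fast),
               c(f2$pf_i, f2$d_slow, f2$d_fast), tolerance = 1e-6)
  b1 <- full_biex_fit(sig); b2 <- full_biex_fit(sigk)
  expect_equal(c(b1$pf_i, b1$d_slow, b1$d_fast),
               c(b2$pf_i, b2$d_slow, b2$d_fast), tolerance = 1e-6)
  t1 <- full_triex_fit(sig); t2 <- full_triex_fit(sigk)
  expect_equal(tidy(t1)$estimate, tidy(t2)$estimate, tolerance = 1e-6)
})

test_that("fitting QC flags implausible perfusion fractions", {
  sig <- noiseless_biex_decay()
  good <- fit_qc(list(segmented_fit(sig)))
  expect_true(good$pass)
  fake <- segmented_fit(sig)
  fake$pf_i <- 0.7
  bad <- fit_qc(list(fake))
  expect_false(bad$pass)
  expect_match(bad$reasons, "outside", all = FALSE)
})
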