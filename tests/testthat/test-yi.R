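test_that("log-odds series on noiseless biex tracks the theoretical line", {
  p <- canonical_biex()
  sig <- noiseless_biex_decay(p)
  ser <- compute_yi_series(sig)
  expect_s3_class(ser, "yi_series")
  expect_identical(ser$b_i, c(0, 2, 4, 7, 10, 15, 20))
  expect_identical(ser$in_fit, c(FALSE, rep(TRUE, 6)))
  # series lies near the analytic line; the high-b contamination bias of the
  # segmented step shifts each point up by < 0.1 in Y
  line <- theoretical_yi_line(p, ser$b_i)
  expect_lt(max(abs(ser$y_i - line$y)), 0.1)
  expect_gt(cor(ser$y_i, line$y), 0.999)
  # frozen point check at b_i = 20 (closed form 0.08578 -> Y 2.366)
  expect_equal(ser$pf_i[ser$b_i == 20], 0.0857793, tolerance = 0.01 / 0.0858)
  expect_equal(ser$y_i[ser$b_i == 20], 2.3662, tolerance = 0.1)
  expect_error(compute_yi_series(sig, b_grid = c(2, 5, 20)), "not in the")
  expect_error(compute_yi_series(sig, b_grid = c(4, 2)), "ascending")
})

test_that("line fit is exact on exact input and reports extrapolated residuals", {
  ser <- tibble::tibble(b_i = c(2, 4, 7, 10, 15, 20),
                        pf_i = inverse_yi(0.049 * c(2, 4, 7, 10, 15, 20) +
                                            log(4)),
                        y_i = 0.049 * c(2, 4, 7, 10, 15, 20) + log(4),
                        in_fit = TRUE, in_window = TRUE, valid = TRUE)
  attr(ser, "d_slow") <- 1e-3
  class(ser) <- c("yi_series", class(ser))
  reg <- fit_yi_line(ser)
  expect_equal(reg$slope, 0.049, tolerance = 1e-12)
  expect_equal(reg$intercept, log(4), tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(reg$points$residual)), 0, tolerance = 1e-12)
  # OLS residuals of fitted points sum to zero
  expect_equal(sum(reg$points$residual[reg$points$used_in_fit]), 0,
               tolerance = 1e-10)
  # fewer than 3 valid points is an error
  expect_error(fit_yi_line(ser[1:2, ]), "at least 3")
})

test_that("triex decay puts the b = 0 point far below the fitted line", {
  sig <- noiseless_triex_decay()
  ser <- compute_yi_series(sig)
  reg <- fit_yi_line(ser)
  res0 <- reg$points$residual[reg$points$b_i == 0]
  expect_lt(res0, 0)
  expect_identical(which.max(abs(reg$points$residual)),
                   which(reg$points$b_i == 0))
  # the b = 2 residual is negative and the largest among the fitted points
  fitted <- reg$points[reg$points$used_in_fit, ]
  expect_lt(fitted$residual[fitted$b_i == 2], 0)
  expect_identical(which.max(abs(fitted$residual)), which(fitted$b_i == 2))
  # including b = 0 in the fit degrades linearity
  ser0 <- compute_yi_series(sig, b_grid = c(0, 2, 4, 7, 10, 15, 20))
  expect_lt(fit_yi_line(ser0)$r_squared, reg$r_squared)
})

test_that("derived parameters follow the slope/intercept identities", {
  reg <- structure(list(slope = 0.049, intercept = log(4), r_squared = 1,
                        d_slow = 1e-3, points = NULL, n_fit = 6),
                   class = "yi_regression")
  out <- derive_params(reg, d_slow = 1e-3, f_tot = 0.34)
  expect_equal(out$d_fast_yi, 0.050)
  expect_equal(out$f_fast, 0.2, tolerance = 1e-12)
  expect_equal(out$f_vfast, 0.14, tolerance = 1e-12)
  expect_true(out$slope_positive)
  reg$intercept <- 0
  expect_equal(derive_params(reg, f_tot = 0.6)$f_fast, 0.5)
  # negative raw f_vfast is clipped and flagged
  reg$intercept <- log(4)
  clipped <- derive_params(reg, f_tot = 0.1)
  expect_identical(clipped$f_vfast, 0)
  expect_true(clipped$f_vfast_clipped)
  expect_equal(clipped$f_vfast_raw, -0.1, tolerance = 1e-12)
})

test_that("pipeline on noiseless biex approaches the recovery limit", {
  p <- canonical_biex()
  sig <- noiseless_biex_decay(p)
  fit <- yi_pipeline(sig)
  expect_true(fit$qc$pass)
  expect_gt(fit$regression$r_squared, 0.9999)
  # accuracy limited by the segmented step's contamination bias
  expect_lt(abs(fit$params$d_fast_yi - 50e-3) / 50e-3, 0.05)
  expect_lt(abs(fit$params$f_fast - 0.2), 0.005)
  expect_lte(fit$params$f_vfast, 1e-3)
  # deterministic
  expect_identical(glance(fit), glance(yi_pipeline(sig)))
})

test_that("pipeline on noiseless triex separates the perfusion pools", {
  sig <- noiseless_triex_decay()
  fit <- yi_pipeline(sig)
  expect_true(fit$qc$pass)
  # f_tot from the b=0 segmented fit matches F_fast + F_vfast
  expect_equal(fit$params$f_tot, 0.29, tolerance = 0.03)
  # the intercept excludes most of the very fast pool but, at d_vfast = 0.5,
  # the pool has not fully decayed by b = 2 and f_fast lands between
  # F_fast and F_tot
  expect_gt(fit$params$f_fast, 0.15)
  expect_lt(fit$params$f_fast, fit$params$f_tot)
  # decomposition identity is exact pre-clipping
  expect_equal(fit$params$f_vfast_raw,
               fit$params$f_tot - fit$params$f_fast, tolerance = 1e-12)
  # the slope stays positive; residual very fast signal at b_i = 2-4
  # inflates d_fast_yi above the fast-pool rate
  expect_true(fit$params$slope_positive)
  expect_gt(fit$params$d_fast_yi, 50e-3)
  expect_lt(fit$params$d_fast_yi, 75e-3)
})

test_that("intercept approaches the surviving-pool fraction as the very fast pool speeds up", {
  # once the very fast pool decays before b = 2 (d_vfast >= 2), the
  # intercept estimates f_fast / (1 - f_vfast); it always underestimates
  # f_tot
  for (dv in c(0.5, 1, 2, 5)) {
    tp <- triex_params(0.71, 0.15, 0.14, 1e-3, 50e-3, dv)
    fit <- yi_pipeline(noiseless_triex_decay(tp))
    expect_lt(fit$params$f_fast, fit$params$f_tot)
    if (dv >= 2) {
      expect_lt(abs(fit$params$f_fast - 0.15 / 0.86), 0.01)
      expect_lt(abs(fit$params$f_fast - 0.15), 0.03)
    }
  }
})

test_that("estimate is robust to dropping any single interior grid point", {
  sig <- noiseless_biex_decay()
  base <- yi_pipeline(sig)$params$d_fast_yi
  g <- c(2, 4, 7, 10, 15, 20)
  for (i in 2:5) {
    alt <- yi_pipeline(sig, b_grid = g[-i])$params$d_fast_yi
    expect_lt(abs(alt - base) / base, 0.05)
  }
})

test_that("degenerate input fails QC without crashing", {
  const <- decay_signal(liver_scheme(), rep(800, 16))
  fit <- yi_pipeline(const)
  expect_false(fit$qc$pass)
  expect_s3_class(fit, "yi_fit")
})
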