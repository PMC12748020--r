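test_that("coefficient of variation: values, errors, scale invariance", {
  expect_identical(cv(c(2, 2, 2)), 0)
  expect_equal(cv(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-1, 1)), "mean is zero")
  withr::with_seed(61, {
    for (i in 1:1000) {
      x <- rlnorm(sample(2:20, 1))
      k <- runif(1, 0.1, 100)
      expect_equal(cv(k * x), cv(x), tolerance = 1e-10)
    }
  })
})

test_that("within-subject SD: hand-computed cases and translation invariance", {
  expect_identical(wsd(data.frame(scan1 = c(1, 2), scan2 = c(1, 2))), 0)
  expect_equal(wsd(data.frame(scan1 = 0, scan2 = 2)), sqrt(2),
               tolerance = 1e-12)
  expect_equal(wsd(data.frame(scan1 = c(0, 0), scan2 = c(2, -2))), sqrt(2),
               tolerance = 1e-12)
  withr::with_seed(62, {
    for (i in 1:200) {
      p <- data.frame(scan1 = rnorm(5), scan2 = rnorm(5))
      shift <- runif(1, -10, 10)
      ps <- data.frame(scan1 = p$scan1 + shift, scan2 = p$scan2 + shift)
      expect_equal(wsd(ps), wsd(p), tolerance = 1e-10)
      expect_equal(bland_altman(ps), bland_altman(p), tolerance = 1e-10)
    }
  })
})

test_that("Bland-Altman difference and limits", {
  ident <- data.frame(scan1 = c(1, 2, 3), scan2 = c(1, 2, 3))
  ba0 <- bland_altman(ident)
  expect_identical(c(ba0$mean_diff, ba0$lower, ba0$upper), c(0, 0, 0))
  # d = {1, 3}: mean 2, limits 2 +/- 1.96 * sqrt(2)
  p <- data.frame(scan1 = c(0, 0), scan2 = c(1, 3))
  ba <- bland_altman(p)
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$lower, 2 - 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$upper, 2 + 1.96 * sqrt(2), tolerance = 1e-12)
  # swapping the scans negates the mean difference
  flip <- bland_altman(data.frame(scan1 = p$scan2, scan2 = p$scan1))
  expect_equal(flip$mean_diff, -ba$mean_diff)
  expect_error(bland_altman(data.frame(scan1 = 1, scan2 = 2)), "at least 2")
})

test_that("ICC: perfect agreement, shuffled pairs, and the ANOVA oracle", {
  perfect <- data.frame(scan1 = c(1, 2, 3, 5, 8), scan2 = c(1, 2, 3, 5, 8))
  expect_equal(icc(perfect)$icc, 1, tolerance = 1e-12)
  # independent reshuffling destroys agreement
  shuffled <- withr::with_seed(63, {
    v <- rnorm(100)
    data.frame(scan1 = v, scan2 = sample(v))
  })
  expect_lt(abs(icc(shuffled)$icc), 0.2)
  # 5-pair fixture against the aov-based mean-squares oracle
  fix <- data.frame(scan1 = c(10, 12, 15, 20, 11),
                    scan2 = c(11, 13, 14, 22, 10))
  expect_equal(icc(fix)$icc, icc_oracle_aov(fix), tolerance = 1e-10)
  expect_equal(icc(fix, "icc3_1")$icc, icc_oracle_aov(fix, "icc3_1"),
               tolerance = 1e-10)
  # property: agreement with the oracle on random fixtures up to n = 20
  withr::with_seed(64, {
    for (i in 1:50) {
      n <- sample(3:20, 1)
      p <- data.frame(scan1 = rnorm(n, 10, 3),
                      scan2 = rnorm(n, 10, 3))
      expect_equal(icc(p)$icc, icc_oracle_aov(p), tolerance = 1e-10)
    }
  })
  # degenerate all-equal input is defined as 1 with a flag
  flat <- data.frame(scan1 = rep(4, 5), scan2 = rep(4, 5))
  expect_true(icc(flat)$degenerate)
  expect_identical(icc(flat)$icc, 1)
})

test_that("reproducibility report bundles the statistics coherently", {
  p <- data.frame(scan1 = c(10, 12, 15, 20, 11),
                  scan2 = c(11, 13, 14, 22, 10))
  rep <- repro_report(p)
  expect_identical(rep$n_pairs, 5L)
  expect_identical(rep$n_scans, 10L)
  expect_equal(rep$mean, mean(c(p$scan1, p$scan2)))
  expect_true(rep$ba_lower <= rep$ba_difference &&
                rep$ba_difference <= rep$ba_upper)
  expect_gte(rep$cov, 0)
  expect_gte(rep$wsd, 0)
})

test_that("method comparison table and its degenerate cases", {
  base <- tidyr::crossing(subject_id = sprintf("S%02d", 1:5),
                          session = 1:2)
  vals <- withr::with_seed(65, rnorm(10, 50, 5))
  res <- dplyr::bind_rows(
    dplyr::mutate(base, method = "a", parameter = "d_fast", value = vals),
    dplyr::mutate(base, method = "b", parameter = "d_fast", value = vals))
  mc <- method_comparison(res)
  # identical estimator tables give identical rows
  expect_equal(mc$cov[mc$method == "a"], mc$cov[mc$method == "b"])
  expect_equal(mc$wsd[mc$method == "a"], mc$wsd[mc$method == "b"])
  # no noise and no jitter: wsd 0, degenerate ICC 1
  same <- dplyr::mutate(base, method = "a", parameter = "pf",
                        value = rep(c(1, 2, 3, 4, 5), each = 2))
  mc2 <- method_comparison(same)
  expect_identical(mc2$wsd, 0)
  expect_equal(mc2$icc, 1, tolerance = 1e-12)
  # mismatched scan sets error out
  expect_error(method_comparison(res[-1, ]), "different scan sets")
  # truth table adds bias and rmse
  truth <- dplyr::mutate(base, parameter = "d_fast", value = 50)
  mct <- method_comparison(res, truth = truth)
  expect_true(all(c("bias", "rmse") %in% names(mct)))
  expect_equal(mct$bias[1], mean(vals) - 50, tolerance = 1e-12)
})
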