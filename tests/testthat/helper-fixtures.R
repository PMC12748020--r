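# Canonical truth parameters used across the suite.
canonical_biex <- function() biex_params(pf = 0.2, d_slow = 1e-3,
                                         d_fast = 50e-3)
canonical_triex <- function() triex_params(f_slow = 0.71, f_fast = 0.15,
                                           f_vfast = 0.14, d_slow = 1e-3,
                                           d_fast = 50e-3, d_vfast = 0.5)

noiseless_biex_decay <- function(params = canonical_biex(), s0 = 1000,
                                 scheme = liver_scheme()) {
  decay_signal(scheme, biex_signal(params, s0, scheme$b))
}

noiseless_triex_decay <- function(params = canonical_triex(), s0 = 1000,
                                  scheme = liver_scheme()) {
  decay_signal(scheme, triex_signal(params, s0, scheme$b))
}

# Liver-realistic random biex draws (truncated around healthy-liver means).
random_biex_draws <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rt <- function(mean, sd, lo, hi) {
        qnorm(runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
      }
      biex_params(pf = rt(0.286, 0.057, 0.05, 0.5),
                  d_slow = rt(1e-3, 2e-4, 4e-4, 2.5e-3),
                  d_fast = rt(55e-3, 11e-3, 20e-3, 0.15))
    })
  })
}

# Independent ICC oracle: mean squares from stats::aov on the long table,
# assembled into the agreement and consistency forms.
icc_oracle_aov <- function(pairs, type = "icc2_1") {
  long <- data.frame(
    subject = factor(rep(seq_len(nrow(pairs)), 2)),
    session = factor(rep(1:2, each = nrow(pairs))),
    value = c(pairs$scan1, pairs$scan2))
  tab <- summary(stats::aov(value ~ subject + session, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["session", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(pairs); k <- 2
  if (type == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}
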