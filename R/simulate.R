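#' Noise model for simulated decay signals
#'
#' Describes the per-excitation noise applied to simulated signals. For
#' `kind = "rician"` each excitation's magnitude is
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` and
#' `sigma = s0 / snr`, matching magnitude reconstruction of MR images;
#' `"gaussian"` adds `N(0, sigma)` directly (useful for analytic checks);
#' `"none"` returns the exact model values. SNR is defined per excitation
#' at b = 0.
#'
#' @param snr Signal-to-noise ratio S(0)/sigma per excitation (default
#'   100); ignored for `kind = "none"`.
#' @param kind One of `"rician"`, `"gaussian"`, `"none"`.
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(snr = 100, kind = c("rician", "gaussian", "none")) {
  kind <- match.arg(kind)
  if (kind != "none" && (!is.finite(snr) || snr <= 0)) {
    stop("noise_model: snr must be > 0", call. = FALSE)
  }
  structure(list(snr = snr, kind = kind), class = "noise_model")
}

# Run code with a private RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one noisy decay signal
#'
#' Forward-simulates a tri-exponential decay on an acquisition scheme:
#' the exact model value at each b is corrupted per excitation according to
#' the noise model, and the `nsa` excitations are averaged — the same
#' magnitude-averaging a scanner performs. With `kind = "none"` the output
#' equals [triex_signal()] exactly. Fully reproducible given `seed`.
#'
#' @param params A [triex_params()] truth object.
#' @param scheme An acquisition-scheme tibble (default [liver_scheme()]).
#' @param noise A [noise_model()] (default Rician at SNR 100).
#' @param s0 True signal at b = 0 (default 1000).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#'
#' @return A decay-signal tibble (columns `b`, `signal`, `nsa`).
#' @examples
#' p <- triex_params(0.714, 0.150, 0.136, 1e-3, 55e-3, 0.5)
#' generate_decay(p, seed = 1)
#' @export
generate_decay <- function(params, scheme = liver_scheme(),
                           noise = noise_model(), s0 = 1000, seed = NULL) {
  stopifnot(inherits(params, "triex_params"), inherits(noise, "noise_model"))
  check_scheme(scheme)
  clean <- triex_signal(params, s0, scheme$b)
  if (noise$kind == "none") {
    return(decay_signal(scheme, clean))
  }
  draw <- function() {
    sigma <- s0 / noise$snr
    vapply(seq_len(nrow(scheme)), function(i) {
      n <- scheme$nsa[i]
      if (noise$kind == "rician") {
        mean(sqrt((clean[i] + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2))
      } else {
        mean(clean[i] + stats::rnorm(n, 0, sigma))
      }
    }, numeric(1))
  }
  sig <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  decay_signal(scheme, pmax(sig, .Machine$double.eps))
}

#' Mean of the Rician distribution
#'
#' Closed-form expectation of `sqrt((nu + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, sigma)`:
#' \deqn{E = \sigma \sqrt{\pi/2}\; L_{1/2}(-\nu^2 / 2\sigma^2)}
#' where \eqn{L_{1/2}} is the Laguerre function, expressed through modified
#' Bessel functions. Quantifies the upward noise-floor bias of magnitude
#' images at low SNR.
#'
#' @param nu Underlying noise-free magnitude (>= 0).
#' @param sigma Gaussian channel standard deviation (> 0).
#'
#' @return The expected observed magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  stopifnot(all(nu >= 0), sigma > 0)
  x <- nu^2 / (2 * sigma^2)
  # L_{1/2}(-x) = exp(-x/2) [(1 + x) I0(x/2) + x I1(x/2)]; the scaled Bessel
  # form cancels the exponentials so large nu/sigma cannot overflow
  lag <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
    x * besselI(x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * lag
}

#' Specification of a simulated scan-rescan cohort
#'
#' Per-subject truth parameters are drawn from truncated normal
#' distributions around the supplied means; the second scan of each pair
#' re-uses the subject's parameters perturbed multiplicatively by the
#' rescan jitter (emulating physiological variation between sessions) with
#' independent noise. Defaults reflect healthy-liver values: fractions
#' f_fast = 0.150, f_vfast = 0.136 (f_slow as the complement), rates
#' d_slow = 1.0e-3, d_fast = 55e-3 mm^2/s, and d_vfast = 0.5 mm^2/s (a
#' literature-scale value for the very fast pool; not estimated by this
#' package's methods).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param means Named list of truth means: `f_fast`, `f_vfast`, `d_slow`,
#'   `d_fast`, `d_vfast`.
#' @param rel_sd Relative between-subject dispersion applied to every
#'   parameter (default 0.2), truncated so invariants always hold.
#' @param rescan_jitter Relative multiplicative perturbation between the
#'   two scans of a pair (default 0.05).
#' @param seed Base integer seed. A stream of per-subject seeds is drawn
#'   from it, so subject `k` is reproducible independently of `n_subjects`.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 17,
                        means = list(f_fast = 0.150, f_vfast = 0.136,
                                     d_slow = 1.0e-3, d_fast = 55e-3,
                                     d_vfast = 0.5),
                        rel_sd = 0.2, rescan_jitter = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 1, rel_sd >= 0, rescan_jitter >= 0)
  need <- c("f_fast", "f_vfast", "d_slow", "d_fast", "d_vfast")
  if (!all(need %in% names(means))) {
    stop("cohort_spec: means must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), means = means,
                 rel_sd = rel_sd, rescan_jitter = rescan_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draw by inverse-CDF (no rejection, deterministic count
# of RNG consumption).
rtrunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

draw_triex <- function(means, rel_sd, bounds = ivim_bounds()) {
  ff <- rtrunc(1, means$f_fast, rel_sd * means$f_fast, 1e-3, 0.5)
  fv <- rtrunc(1, means$f_vfast, rel_sd * means$f_vfast, 1e-3, 0.5)
  ds <- rtrunc(1, means$d_slow, rel_sd * means$d_slow,
               bounds$d_slow[1], bounds$d_slow[2])
  df <- rtrunc(1, means$d_fast, rel_sd * means$d_fast,
               bounds$d_fast[1], bounds$d_fast[2])
  dv <- rtrunc(1, means$d_vfast, rel_sd * means$d_vfast,
               bounds$d_vfast[1], bounds$d_vfast[2])
  triex_params(f_slow = 1 - ff - fv, f_fast = ff, f_vfast = fv,
               d_slow = ds, d_fast = df, d_vfast = dv)
}

jitter_triex <- function(p, jitter, bounds = ivim_bounds()) {
  if (jitter == 0) return(p)
  mult <- function(x, lo, hi) min(max(x * (1 + jitter * stats::rnorm(1)),
                                      lo), hi)
  ff <- mult(p$f_fast, 1e-3, 0.5)
  fv <- mult(p$f_vfast, 1e-3, 0.5)
  triex_params(f_slow = 1 - ff - fv, f_fast = ff, f_vfast = fv,
               d_slow = mult(p$d_slow, bounds$d_slow[1], bounds$d_slow[2]),
               d_fast = mult(p$d_fast, bounds$d_fast[1], bounds$d_fast[2]),
               d_vfast = mult(p$d_vfast, bounds$d_vfast[1],
                              bounds$d_vfast[2]))
}

#' Simulate a paired scan-rescan cohort
#'
#' Generates two scans per subject under a [cohort_spec()]: subject-level
#' truth parameters, a jittered second-scan truth, and independent noise
#' for every scan. The result is a nested tibble with one row per scan —
#' ids, session index, the true parameters as columns, and the decay table
#' in the `decay` list-column.
#'
#' @param spec A [cohort_spec()].
#' @param scheme Acquisition scheme (default [liver_scheme()]).
#' @param noise A [noise_model()] (default Rician, SNR 100).
#' @param s0 True S(0) (default 1000).
#'
#' @return A tibble with columns `subject_id`, `scan_id`, `session`,
#'   `f_slow`, `f_fast`, `f_vfast`, `d_slow`, `d_fast`, `d_vfast` (truth)
#'   and `decay` (list-column of decay tibbles).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 7))
#' coh
#' @export
generate_cohort <- function(spec, scheme = liver_scheme(),
                            noise = noise_model(), s0 = 1000) {
  stopifnot(inherits(spec, "cohort_spec"))
  # one stream of per-subject seeds, drawn with replacement so subject k
  # depends only on the base seed and k, never on n_subjects
  subject_seeds <- with_local_seed(spec$seed,
    sample.int(2147483646L, spec$n_subjects, replace = TRUE))
  purrr::map_dfr(seq_len(spec$n_subjects), function(k) {
    with_local_seed(subject_seeds[k], {
      truth1 <- draw_triex(spec$means, spec$rel_sd)
      truth2 <- jitter_triex(truth1, spec$rescan_jitter)
      truths <- list(truth1, truth2)
      decays <- list(generate_decay(truth1, scheme, noise, s0, seed = NULL),
                     generate_decay(truth2, scheme, noise, s0, seed = NULL))
      purrr::map_dfr(1:2, function(sess) {
        tr <- truths[[sess]]
        tibble::tibble(
          subject_id = sprintf("S%03d", k),
          scan_id = sprintf("S%03d_s%d", k, sess),
          session = sess,
          f_slow = tr$f_slow, f_fast = tr$f_fast, f_vfast = tr$f_vfast,
          d_slow = tr$d_slow, d_fast = tr$d_fast, d_vfast = tr$d_vfast,
          decay = list(decays[[sess]]))
      })
    })
  })
}
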