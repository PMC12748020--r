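#' Default parameter bounds for IVIM fitting
#'
#' Bounds used by all nonlinear least-squares steps. Disjoint rate ranges
#' enforce the compartment ordering `d_slow < d_fast < d_vfast` and cover
#' reported healthy-liver values.
#'
#' @return A named list: `d_slow` = c(1e-4, 3e-3), `d_fast` = c(3e-3, 0.5),
#'   `d_vfast` = c(0.1, 10) (all mm^2/s), `pf` = c(0, 1).
#' @export
ivim_bounds <- function() {
  list(d_slow = c(1e-4, 3e-3),
       d_fast = c(3e-3, 0.5),
       d_vfast = c(0.1, 10),
       pf = c(0, 1))
}

# Restrict a decay table to b >= b_start; b_start must be a sampled b-value.
restrict_decay <- function(decay, b_start) {
  check_decay(decay)
  if (!any(abs(decay$b - b_start) < 1e-9)) {
    stop(sprintf("b_start = %g is not a sampled b-value", b_start),
         call. = FALSE)
  }
  decay[decay$b >= b_start - 1e-9, , drop = FALSE]
}

#' High-b mono-exponential (log-linear) fitting step
#'
#' First stage of segmented IVIM fitting: above the threshold b-value the
#' perfusion compartments are assumed fully decayed, so
#' `log(S(b))` is linear in `(b - b_start)` with slope `-d_slow` and
#' intercept `log((1 - pf_i) * S(b_start))`. Ordinary least squares on the
#' high-b points therefore yields `d_slow` and the apparent perfusion
#' fraction `pf_i` at the fit-starting b-value.
#'
#' @param decay A decay-signal tibble (columns `b`, `signal`).
#' @param b_start Fit-starting b-value; must be one of the sampled b-values.
#' @param threshold High-b threshold, s/mm^2; points with `b >= threshold`
#'   enter the log-linear fit (default 60, inclusive).
#'
#' @return A list with elements `d_slow`, `pf_i`, `s_start` (the
#'   normalization signal S(b_start)) and `n_highb`.
#' @export
fit_monoexp_highb <- function(decay, b_start = 0, threshold = 60) {
  dat <- restrict_decay(decay, b_start)
  s_start <- dat$signal[which.min(abs(dat$b - b_start))]
  hi <- dat[dat$b >= threshold, , drop = FALSE]
  if (nrow(hi) < 3) {
    stop("fit_monoexp_highb: need at least 3 points at or above the threshold",
         call. = FALSE)
  }
  fit <- stats::lm(log(signal) ~ I(b - b_start), data = hi)
  co <- stats::coef(fit)
  d_slow <- -unname(co[2])
  pf_i <- 1 - exp(unname(co[1])) / s_start
  list(d_slow = d_slow, pf_i = pf_i, s_start = s_start, n_highb = nrow(hi))
}

#' Constrained one-parameter fit of the fast pseudo-diffusion coefficient
#'
#' Second stage of segmented fitting: with `d_slow` and `pf_i` held fixed,
#' the fast coefficient is the single free parameter of the shifted
#' bi-exponential model
#' `S(b) = S(b_start) * (pf_i exp(-(b - b_start) d_fast) +
#' (1 - pf_i) exp(-(b - b_start) d_slow))`, minimized in least squares over
#' all points with `b >= b_start` within the `d_fast` bounds.
#'
#' @inheritParams fit_monoexp_highb
#' @param d_slow,pf_i Values fixed from the high-b step.
#' @param bounds Bounds list as from [ivim_bounds()].
#'
#' @return A list with `d_fast`, `sse` and `converged` (`FALSE` when the
#'   minimizer is pinned at a bound).
#' @export
fit_dfast_constrained <- function(decay, b_start = 0, d_slow, pf_i,
                                  bounds = ivim_bounds()) {
  stopifnot(d_slow > 0, pf_i > 0, pf_i < 1)
  dat <- restrict_decay(decay, b_start)
  s_start <- dat$signal[which.min(abs(dat$b - b_start))]
  db <- dat$b - b_start
  slow_part <- (1 - pf_i) * exp(-db * d_slow)
  sse_fun <- function(d_fast) {
    pred <- s_start * (pf_i * exp(-db * d_fast) + slow_part)
    sum((dat$signal - pred)^2)
  }
  lo <- bounds$d_fast[1]
  hi <- bounds$d_fast[2]
  opt <- stats::optimize(sse_fun, lower = lo, upper = hi, tol = 1e-10)
  at_bound <- (opt$minimum - lo) < 1e-6 || (hi - opt$minimum) < 1e-6
  list(d_fast = opt$minimum, sse = opt$objective, converged = !at_bound)
}

new_ivim_fit <- function(b_start, pf_i, d_slow, d_fast, method, sse,
                         converged, n, decay) {
  structure(list(b_start = b_start, pf_i = pf_i, d_slow = d_slow,
                 d_fast = d_fast, method = method, sse = sse,
                 converged = converged, n = n, decay = decay),
            class = "ivim_fit")
}

#' Segmented bi-exponential IVIM fit
#'
#' The conventional two-stage estimator, runnable from any sampled
#' fit-starting b-value: a log-linear mono-exponential fit over
#' `b >= threshold` gives `d_slow` and `pf_i` ([fit_monoexp_highb()]), then
#' a constrained one-parameter least-squares fit gives `d_fast`
#' ([fit_dfast_constrained()]). Data are restricted to `b >= b_start` and
#' normalized by S(b_start).
#'
#' @inheritParams fit_monoexp_highb
#' @param bounds Bounds list as from [ivim_bounds()].
#'
#' @return An object of class `ivim_fit` with fields `b_start`, `pf_i`,
#'   `d_slow`, `d_fast`, `method = "segmented"`, `sse`, `converged`, `n`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' p <- biex_params(0.2, 1e-3, 50e-3)
#' sig <- decay_signal(liver_scheme(), biex_signal(p, 1000, liver_scheme()$b))
#' segmented_fit(sig)
#' @export
segmented_fit <- function(decay, b_start = 0, threshold = 60,
                          bounds = ivim_bounds()) {
  step1 <- fit_monoexp_highb(decay, b_start, threshold)
  pf_use <- min(max(step1$pf_i, 1e-6), 1 - 1e-6)
  step2 <- fit_dfast_constrained(decay, b_start, step1$d_slow, pf_use, bounds)
  dat <- restrict_decay(decay, b_start)
  new_ivim_fit(b_start = b_start, pf_i = step1$pf_i, d_slow = step1$d_slow,
               d_fast = step2$d_fast, method = "segmented", sse = step2$sse,
               converged = step2$converged && step1$d_slow > 0,
               n = nrow(dat), decay = dat)
}

#' Full bi-exponential IVIM fit
#'
#' All three parameters (`pf_i`, `d_slow`, `d_fast`) in one bounded
#' nonlinear least-squares fit of the shifted bi-exponential model over
#' `b >= b_start`, normalized by S(b_start). Initialized from the segmented
#' fit, so the result is deterministic.
#'
#' @inheritParams segmented_fit
#'
#' @return An `ivim_fit` object with `method = "full"`.
#' @export
full_biex_fit <- function(decay, b_start = 0, threshold = 60,
                          bounds = ivim_bounds()) {
  seg <- segmented_fit(decay, b_start, threshold, bounds)
  dat <- seg$decay
  s_start <- dat$signal[which.min(abs(dat$b - b_start))]
  db <- dat$b - b_start
  clamp <- function(x, rng, eps) min(max(x, rng[1] + eps), rng[2] - eps)
  start <- list(pf = clamp(seg$pf_i, bounds$pf, 1e-4),
                dslow = clamp(seg$d_slow, bounds$d_slow, 1e-6),
                dfast = clamp(seg$d_fast, bounds$d_fast, 1e-6))
  y <- dat$signal / s_start
  lo <- c(bounds$pf[1], bounds$d_slow[1], bounds$d_fast[1])
  hi <- c(bounds$pf[2], bounds$d_slow[2], bounds$d_fast[2])
  fit <- try(minpack.lm::nls.lm(
    par = unlist(start),
    fn = function(p) y - (p[1] * exp(-db * p[3]) +
                            (1 - p[1]) * exp(-db * p[2])),
    lower = lo, upper = hi,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-12)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    seg$method <- "full"
    seg$converged <- FALSE
    return(seg)
  }
  co <- unname(fit$par)
  sse <- fit$deviance * s_start^2
  at_bound <- any(abs(co - lo) < 1e-8) || any(abs(co - hi) < 1e-8)
  new_ivim_fit(b_start = b_start, pf_i = co[1],
               d_slow = co[2], d_fast = co[3],
               method = "full", sse = sse,
               converged = !at_bound && fit$info %in% 1:4,
               n = nrow(dat), decay = dat)
}

#' Full tri-exponential IVIM fit
#'
#' One bounded nonlinear least-squares fit of the three-compartment decay
#' with S(0) fixed as normalization. By default all six parameters (three
#' fractions, three rates) are free within bounds and the fitted fractions
#' are normalized to unit sum afterwards; `constrain_fractions = TRUE`
#' instead fits five parameters with `f_slow = 1 - f_fast - f_vfast`
#' eliminated. Rate ordering is enforced by the disjoint bounds.
#'
#' @param decay A decay-signal tibble whose scheme includes b = 0.
#' @param bounds Bounds list as from [ivim_bounds()].
#' @param constrain_fractions Fit with the unit-sum constraint built in.
#'
#' @return An object of class `triex_fit`: fields `params` (a
#'   [triex_params()] with normalized fractions), `raw_fractions`, `sse`,
#'   `converged`, `n_free`, `n`.
#' @export
full_triex_fit <- function(decay, bounds = ivim_bounds(),
                           constrain_fractions = FALSE) {
  check_decay(decay)
  if (abs(decay$b[1]) > 1e-9) {
    stop("full_triex_fit: scheme must include b = 0", call. = FALSE)
  }
  s0 <- decay$signal[1]
  y <- decay$signal / s0
  b <- decay$b
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                     ptol = 1e-12)
  if (constrain_fractions) {
    init <- c(0.15, 0.15, 1e-3, 50e-3, 0.5)
    fn <- function(p) {
      y - ((1 - p[1] - p[2]) * exp(-b * p[3]) + p[1] * exp(-b * p[4]) +
             p[2] * exp(-b * p[5]))
    }
    lo <- c(0, 0, bounds$d_slow[1], bounds$d_fast[1], bounds$d_vfast[1])
    hi <- c(1, 1, bounds$d_slow[2], bounds$d_fast[2], bounds$d_vfast[2])
    n_free <- 5L
  } else {
    init <- c(0.7, 0.15, 0.15, 1e-3, 50e-3, 0.5)
    fn <- function(p) {
      y - (p[1] * exp(-b * p[4]) + p[2] * exp(-b * p[5]) +
             p[3] * exp(-b * p[6]))
    }
    lo <- c(0, 0, 0, bounds$d_slow[1], bounds$d_fast[1], bounds$d_vfast[1])
    hi <- c(1, 1, 1, bounds$d_slow[2], bounds$d_fast[2], bounds$d_vfast[2])
    n_free <- 6L
  }
  fit <- try(minpack.lm::nls.lm(par = init, fn = fn, lower = lo, upper = hi,
                                control = ctrl), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(params = NULL, raw_fractions = NULL, sse = NA_real_,
                          converged = FALSE, n_free = n_free,
                          n = nrow(decay)),
                     class = "triex_fit"))
  }
  co <- if (constrain_fractions) {
    list(fs = 1 - fit$par[1] - fit$par[2], ff = fit$par[1], fv = fit$par[2],
         ds = fit$par[3], df = fit$par[4], dv = fit$par[5])
  } else {
    list(fs = fit$par[1], ff = fit$par[2], fv = fit$par[3],
         ds = fit$par[4], df = fit$par[5], dv = fit$par[6])
  }
  raw <- c(f_slow = co$fs, f_fast = co$ff, f_vfast = co$fv)
  tot <- sum(raw)
  frac <- if (tot > 0) raw / tot else c(f_slow = 1, f_fast = 0, f_vfast = 0)
  # disjoint rate bounds can still collide numerically at a shared edge
  rates <- sort(c(co$ds, co$df, co$dv))
  ordered <- rates[1] < rates[2] && rates[2] < rates[3]
  params <- if (ordered) {
    triex_params(f_slow = unname(frac["f_slow"]),
                 f_fast = unname(frac["f_fast"]),
                 f_vfast = unname(frac["f_vfast"]),
                 d_slow = co$ds, d_fast = co$df, d_vfast = co$dv)
  } else NULL
  structure(list(params = params, raw_fractions = raw,
                 sse = fit$deviance * s0^2,
                 converged = ordered && fit$info %in% 1:4,
                 n_free = n_free, n = nrow(decay)),
            class = "triex_fit")
}

#' Predicted signal from a fitted bi-exponential model
#'
#' @param object An `ivim_fit`.
#' @param b b-values at which to predict (default: the fitted points).
#' @param ... Unused.
#' @return Predicted intensities on the original signal scale.
#' @export
predict.ivim_fit <- function(object, b = NULL, ...) {
  if (is.null(b)) b <- object$decay$b
  s_start <- object$decay$signal[which.min(abs(object$decay$b -
                                                 object$b_start))]
  db <- b - object$b_start
  pf <- min(max(object$pf_i, 0), 1)
  s_start * (pf * exp(-db * object$d_fast) +
               (1 - pf) * exp(-db * object$d_slow))
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf(
    "<ivim_fit: %s> b_start = %g, pf_i = %.4f, d_slow = %.4g, d_fast = %.4g (sse %.3g, %s)\n",
    x$method, x$b_start, x$pf_i, x$d_slow, x$d_fast, x$sse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.triex_fit <- function(x, ...) {
  cat(sprintf("<triex_fit> %d free parameters, sse %.3g, %s\n", x$n_free,
              x$sse, if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Tidy an IVIM fit into a one-row-per-term tibble
#'
#' @param x An `ivim_fit` or `triex_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy ivim_fit
#' @export
tidy.ivim_fit <- function(x, ...) {
  tibble::tibble(term = c("pf_i", "d_slow", "d_fast"),
                 estimate = c(x$pf_i, x$d_slow, x$d_fast))
}

#' @rdname tidy.ivim_fit
#' @method tidy triex_fit
#' @export
tidy.triex_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  p <- x$params
  tibble::tibble(
    term = c("f_slow", "f_fast", "f_vfast", "d_slow", "d_fast", "d_vfast"),
    estimate = c(p$f_slow, p$f_fast, p$f_vfast, p$d_slow, p$d_fast,
                 p$d_vfast))
}

#' One-row fit summary
#'
#' @param x An `ivim_fit` or `triex_fit` object.
#' @param ... Unused.
#' @return A one-row tibble of fit-level statistics.
#' @method glance ivim_fit
#' @export
glance.ivim_fit <- function(x, ...) {
  tibble::tibble(method = x$method, b_start = x$b_start, sse = x$sse,
                 converged = x$converged, n = x$n)
}

#' @rdname glance.ivim_fit
#' @method glance triex_fit
#' @export
glance.triex_fit <- function(x, ...) {
  tibble::tibble(method = "triex", sse = x$sse, converged = x$converged,
                 n_free = x$n_free, n = x$n)
}

#' Per-scan fitting quality control
#'
#' A scan fails fitting QC when any of its segmented apparent perfusion
#' fractions falls outside the plausible window or any fit failed to
#' converge. The window replaces subjective visual rejection of poor fits
#' with an explicit numeric rule.
#'
#' @param fits A list of `ivim_fit` objects for one scan.
#' @param pf_window Allowed open interval for `pf_i` (default (0.001, 0.6)).
#'
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing).
#' @export
fit_qc <- function(fits, pf_window = c(0.001, 0.6)) {
  reasons <- character()
  for (f in fits) {
    if (!f$converged) {
      reasons <- c(reasons,
                   sprintf("fit at b_start=%g did not converge", f$b_start))
    }
    if (f$pf_i <= pf_window[1] || f$pf_i >= pf_window[2]) {
      reasons <- c(reasons,
                   sprintf("pf_i=%.4f at b_start=%g outside (%g, %g)",
                           f$pf_i, f$b_start, pf_window[1], pf_window[2]))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}
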