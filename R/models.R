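#' Bi-exponential IVIM signal model
#'
#' Evaluates the standard two-compartment IVIM decay
#' \deqn{S(b) = S_0 [PF e^{-b D_{fast}} + (1 - PF) e^{-b D_{slow}}]}{
#'       S(b) = S0 (pf exp(-b d_fast) + (1 - pf) exp(-b d_slow))}
#' at the given b-values.
#'
#' @param params A [biex_params()] object.
#' @param s0 Signal at b = 0, arbitrary units, > 0.
#' @param b Numeric vector of b-values, s/mm^2, all >= 0.
#'
#' @return Numeric vector of signal intensities, same length as `b`.
#' @examples
#' p <- biex_params(0.2, 1e-3, 50e-3)
#' biex_signal(p, s0 = 1, b = c(0, 20, 600))
#' @export
biex_signal <- function(params, s0, b) {
  stopifnot(inherits(params, "biex_params"), is.numeric(s0), s0 > 0)
  if (any(b < 0)) stop("biex_signal: b must be >= 0", call. = FALSE)
  s0 * (params$pf * exp(-b * params$d_fast) +
          (1 - params$pf) * exp(-b * params$d_slow))
}

#' Tri-exponential IVIM signal model
#'
#' Evaluates the three-compartment decay
#' \deqn{S(b) = S_0 \sum_k F_k e^{-b D_k}}{S(b) = S0 sum_k F_k exp(-b D_k)}
#' over the slow, fast and very fast compartments.
#'
#' @param params A [triex_params()] object.
#' @inheritParams biex_signal
#'
#' @return Numeric vector of signal intensities, same length as `b`.
#' @export
triex_signal <- function(params, s0, b) {
  stopifnot(inherits(params, "triex_params"), is.numeric(s0), s0 > 0)
  if (any(b < 0)) stop("triex_signal: b must be >= 0", call. = FALSE)
  s0 * (params$f_slow * exp(-b * params$d_slow) +
          params$f_fast * exp(-b * params$d_fast) +
          params$f_vfast * exp(-b * params$d_vfast))
}

#' Apparent perfusion fraction at a shifted fit-starting b-value
#'
#' When the bi-exponential fit is started at `b_i` instead of 0 and
#' normalized by S(b_i), the curve is still bi-exponential with the same
#' rates but an apparent perfusion fraction
#' \deqn{PF_i = \frac{PF e^{-b_i D_{fast}}}
#'                   {PF e^{-b_i D_{fast}} + (1 - PF) e^{-b_i D_{slow}}}}
#' which decreases towards zero as `b_i` grows (whenever
#' `d_fast > d_slow`). At `b_i = 0` it equals `pf`.
#'
#' @param params A [biex_params()] object.
#' @param b_i Fit-starting b-value(s), s/mm^2, >= 0. Vectorized.
#'
#' @return Apparent perfusion fraction(s) in (0, 1).
#' @examples
#' p <- biex_params(0.2, 1e-3, 50e-3)
#' shifted_pf(p, b_i = c(0, 2, 20))
#' @export
shifted_pf <- function(params, b_i) {
  stopifnot(inherits(params, "biex_params"))
  if (any(b_i < 0)) stop("shifted_pf: b_i must be >= 0", call. = FALSE)
  fast <- params$pf * exp(-b_i * params$d_fast)
  slow <- (1 - params$pf) * exp(-b_i * params$d_slow)
  fast / (fast + slow)
}

#' Log-odds transform of a perfusion fraction
#'
#' Computes \eqn{Y = \ln[(1 - PF_i) / PF_i]}. Under the bi-exponential
#' model this quantity is linear in the fit-starting b-value, with slope
#' `d_fast - d_slow` and intercept `log((1 - pf) / pf)`.
#'
#' Fitted perfusion fractions from noisy data may fall outside (0, 1); with
#' `clip = TRUE` (the default for fitted values downstream) the input is
#' clipped into \[1e-6, 1 - 1e-6\] first. With `clip = FALSE` values outside
#' the open unit interval raise an error, which is the right behaviour for
#' analytic checks.
#'
#' @param pf_i Perfusion fraction(s).
#' @param clip Clip into \[1e-6, 1 - 1e-6\] before the log (default `FALSE`).
#'
#' @return Log-odds value(s), dimensionless.
#' @examples
#' yi_transform(0.2)   # log(4)
#' inverse_yi(log(4))  # 0.2
#' @export
yi_transform <- function(pf_i, clip = FALSE) {
  if (clip) {
    pf_i <- pmin(pmax(pf_i, 1e-6), 1 - 1e-6)
  } else if (any(pf_i <= 0 | pf_i >= 1)) {
    stop("yi_transform: pf_i must lie strictly inside (0, 1)", call. = FALSE)
  }
  log((1 - pf_i) / pf_i)
}

#' @rdname yi_transform
#' @param y Log-odds value(s); `inverse_yi` maps them back to fractions via
#'   \eqn{1 / (1 + e^y)}.
#' @export
inverse_yi <- function(y) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  1 / (1 + exp(y))
}

#' Theoretical log-odds line of the shifted perfusion fraction
#'
#' Closed form of the linear relationship followed by
#' `yi_transform(shifted_pf(params, b_i))`: slope `d_fast - d_slow`,
#' intercept `log((1 - pf) / pf)`.
#'
#' @param params A [biex_params()] object with `d_fast > d_slow`.
#' @param b_i Numeric vector of fit-starting b-values, s/mm^2, >= 0.
#'
#' @return A list with `slope` (mm^2/s), `intercept` (log-odds) and `y`
#'   (the line evaluated at `b_i`).
#' @examples
#' theoretical_yi_line(biex_params(0.2, 1e-3, 50e-3), b_i = c(0, 10, 20))
#' @export
theoretical_yi_line <- function(params, b_i) {
  stopifnot(inherits(params, "biex_params"))
  if (params$d_fast <= params$d_slow) {
    stop("theoretical_yi_line: requires d_fast > d_slow (non-zero slope)",
         call. = FALSE)
  }
  if (any(b_i < 0)) {
    stop("theoretical_yi_line: b_i must be >= 0", call. = FALSE)
  }
  slope <- params$d_fast - params$d_slow
  intercept <- log((1 - params$pf) / params$pf)
  list(slope = slope, intercept = intercept, y = slope * b_i + intercept)
}
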