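#' Bi-exponential IVIM parameter set
#'
#' Bundles the three parameters of the two-compartment IVIM signal model:
#' the perfusion fraction `pf`, the molecular diffusion coefficient `d_slow`
#' and the perfusion-related pseudo-diffusion coefficient `d_fast`. All
#' diffusion coefficients are in mm\eqn{^2}/s; b-values throughout the
#' package are in s/mm\eqn{^2} and internal values are never rescaled.
#'
#' @param pf Perfusion fraction, strictly inside (0, 1).
#' @param d_slow Slow (molecular) diffusion coefficient, mm^2/s, > 0.
#' @param d_fast Fast (pseudo-diffusion) coefficient, mm^2/s. Must satisfy
#'   `d_fast >= d_slow`; equality gives a mono-exponential collapse and is
#'   permitted for signal generation but rejected where the log-odds line
#'   needs a non-zero slope (set `strict = TRUE`).
#' @param strict Require `d_fast > d_slow` strictly (default `FALSE`).
#'
#' @return An object of class `biex_params` (a named list).
#' @examples
#' biex_params(pf = 0.2, d_slow = 1e-3, d_fast = 50e-3)
#' @export
biex_params <- function(pf, d_slow, d_fast, strict = FALSE) {
  stopifnot(is.numeric(pf), is.numeric(d_slow), is.numeric(d_fast))
  if (!all(is.finite(c(pf, d_slow, d_fast)))) {
    stop("biex_params: all parameters must be finite", call. = FALSE)
  }
  if (pf <= 0 || pf >= 1) {
    stop("biex_params: pf must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (d_slow <= 0) stop("biex_params: d_slow must be > 0", call. = FALSE)
  if (strict && d_fast <= d_slow) {
    stop("biex_params: d_fast must exceed d_slow", call. = FALSE)
  }
  if (d_fast < d_slow) {
    stop("biex_params: d_fast must be >= d_slow", call. = FALSE)
  }
  structure(list(pf = pf, d_slow = d_slow, d_fast = d_fast),
            class = "biex_params")
}

#' Tri-exponential IVIM parameter set
#'
#' Three-compartment model: slow molecular diffusion plus a fast and a very
#' fast perfusion-related compartment. Fractions must sum to one (within
#' 1e-9) and the rates must be strictly ordered
#' `d_slow < d_fast < d_vfast`.
#'
#' @param f_slow,f_fast,f_vfast Compartment fractions in \[0, 1\], summing
#'   to 1.
#' @param d_slow,d_fast,d_vfast Compartment diffusion coefficients, mm^2/s,
#'   strictly increasing.
#'
#' @return An object of class `triex_params` (a named list).
#' @examples
#' triex_params(f_slow = 0.71, f_fast = 0.15, f_vfast = 0.14,
#'              d_slow = 1e-3, d_fast = 50e-3, d_vfast = 0.5)
#' @export
triex_params <- function(f_slow, f_fast, f_vfast, d_slow, d_fast, d_vfast) {
  fr <- c(f_slow, f_fast, f_vfast)
  dd <- c(d_slow, d_fast, d_vfast)
  if (!all(is.finite(c(fr, dd)))) {
    stop("triex_params: all parameters must be finite", call. = FALSE)
  }
  if (any(fr < 0) || any(fr > 1)) {
    stop("triex_params: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("triex_params: fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!(d_slow < d_fast && d_fast < d_vfast)) {
    stop("triex_params: rates must satisfy d_slow < d_fast < d_vfast",
         call. = FALSE)
  }
  structure(list(f_slow = f_slow, f_fast = f_fast, f_vfast = f_vfast,
                 d_slow = d_slow, d_fast = d_fast, d_vfast = d_vfast),
            class = "triex_params")
}

#' @export
print.biex_params <- function(x, ...) {
  cat(sprintf(
    "<biex_params> pf = %.4g, d_slow = %.4g, d_fast = %.4g mm^2/s\n",
    x$pf, x$d_slow, x$d_fast))
  invisible(x)
}

#' @export
print.triex_params <- function(x, ...) {
  cat(sprintf(
    "<triex_params> f = (%.4g, %.4g, %.4g), d = (%.4g, %.4g, %.4g) mm^2/s\n",
    x$f_slow, x$f_fast, x$f_vfast, x$d_slow, x$d_fast, x$d_vfast))
  invisible(x)
}
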