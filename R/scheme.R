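#' Build an acquisition scheme
#'
#' An acquisition scheme is a tibble with one row per nominal b-value and
#' columns `b` (s/mm^2, unique, strictly increasing, >= 0) and `nsa`
#' (number of signal averages per b, positive integer).
#'
#' @param b Numeric vector of b-values.
#' @param nsa Integer vector of averaging counts, recycled if length 1.
#'
#' @return A tibble with columns `b` and `nsa`.
#' @examples
#' acquisition_scheme(c(0, 10, 100, 600), nsa = 2)
#' @export
acquisition_scheme <- function(b, nsa = 1L) {
  stopifnot(is.numeric(b), length(b) >= 1)
  if (length(nsa) == 1) nsa <- rep(nsa, length(b))
  if (length(nsa) != length(b)) {
    stop("acquisition_scheme: b and nsa must have the same length",
         call. = FALSE)
  }
  if (any(b < 0)) stop("acquisition_scheme: b must be >= 0", call. = FALSE)
  if (anyDuplicated(b) || is.unsorted(b, strictly = TRUE)) {
    stop("acquisition_scheme: b must be unique and strictly increasing",
         call. = FALSE)
  }
  if (any(nsa < 1) || any(nsa != round(nsa))) {
    stop("acquisition_scheme: nsa must be positive integers", call. = FALSE)
  }
  tibble::tibble(b = as.numeric(b), nsa = as.integer(nsa))
}

#' The 16-b-value liver IVIM acquisition scheme
#'
#' The b-value distribution used by the two healthy-liver scan-rescan
#' protocols this package targets: 0, 2, 4, 7, 10, 15, 20, 30, 46, 60, 72,
#' 100, 150, 200, 400, 600 s/mm^2. The 3.0 T protocol (`nsa_pattern =
#' "dataset1"`, the default) averaged 3 excitations at b = 0, 2, 60 and 2 at
#' b = 400, 600 with a single excitation elsewhere; the 1.5 T protocol
#' (`"dataset2"`) averaged 2 excitations at every b-value.
#'
#' @param nsa_pattern `"dataset1"` or `"dataset2"`.
#'
#' @return An acquisition-scheme tibble (columns `b`, `nsa`).
#' @examples
#' liver_scheme()
#' @export
liver_scheme <- function(nsa_pattern = c("dataset1", "dataset2")) {
  nsa_pattern <- match.arg(nsa_pattern)
  b <- c(0, 2, 4, 7, 10, 15, 20, 30, 46, 60, 72, 100, 150, 200, 400, 600)
  nsa <- if (nsa_pattern == "dataset1") {
    ifelse(b %in% c(0, 2, 60), 3L, ifelse(b %in% c(400, 600), 2L, 1L))
  } else {
    rep(2L, length(b))
  }
  acquisition_scheme(b, nsa)
}

#' Assemble a decay signal table
#'
#' A decay signal is a tibble with columns `b`, `signal` and `nsa`: one
#' scan's ROI-mean diffusion decay series on an acquisition scheme. All
#' signal values must be strictly positive.
#'
#' @param scheme An acquisition-scheme tibble (see [acquisition_scheme()]).
#' @param signal Numeric vector of intensities, same length as the scheme.
#'
#' @return A tibble with columns `b`, `signal`, `nsa`.
#' @export
decay_signal <- function(scheme, signal) {
  check_scheme(scheme)
  if (length(signal) != nrow(scheme)) {
    stop("decay_signal: signal length must match the scheme", call. = FALSE)
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("decay_signal: all signal values must be finite and > 0",
         call. = FALSE)
  }
  tibble::tibble(b = scheme$b, signal = as.numeric(signal), nsa = scheme$nsa)
}

check_scheme <- function(x) {
  if (!is.data.frame(x) || !all(c("b", "nsa") %in% names(x))) {
    stop("expected an acquisition scheme with columns b and nsa",
         call. = FALSE)
  }
  invisible(x)
}

check_decay <- function(x) {
  if (!is.data.frame(x) || !all(c("b", "signal") %in% names(x))) {
    stop("expected a decay signal with columns b and signal", call. = FALSE)
  }
  if (anyDuplicated(x$b) || is.unsorted(x$b, strictly = TRUE)) {
    stop("decay signal: b must be unique and sorted ascending", call. = FALSE)
  }
  if (any(!is.finite(x$signal)) || any(x$signal <= 0)) {
    stop("decay signal: all signal values must be finite and > 0",
         call. = FALSE)
  }
  invisible(x)
}
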