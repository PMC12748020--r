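#' Compute the log-odds perfusion-fraction series over fit-starting b-values
#'
#' Runs a segmented bi-exponential fit from each starting b-value in
#' `b_grid`, records the apparent perfusion fraction `pf_i` and its
#' log-odds `y_i = log((1 - pf_i) / pf_i)`, and returns the series as a
#' tibble. The slow diffusion coefficient is shared across starting points
#' (the high-b subset entering the log-linear step never changes) and is
#' carried in the `d_slow` attribute.
#'
#' Points whose fit did not converge or whose `pf_i` left (0, 1) are marked
#' invalid and excluded from the subsequent line fit. Points with `pf_i`
#' outside the quasi-linear window (0.05, 0.4) of the log-odds transform
#' are flagged via `in_window` but retained.
#'
#' @param decay A decay-signal tibble (columns `b`, `signal`).
#' @param b_grid Fit-starting b-values entering the line fit, sorted
#'   ascending; every value must be a sampled b-value. Default
#'   `c(2, 4, 7, 10, 15, 20)` — b = 0 is excluded because signal there
#'   exceeds the bi-exponential prediction.
#' @param extra_b Additional starting b-values evaluated for diagnostics
#'   but excluded from the line fit (default 0, so the residual at b = 0
#'   can be obtained by extrapolation). Values absent from the scheme are
#'   dropped silently.
#' @param threshold High-b threshold for the segmented fits (default 60).
#' @param bounds Bounds list as from [ivim_bounds()].
#'
#' @return A tibble of class `yi_series` with columns `b_i`, `pf_i`, `y_i`,
#'   `in_fit`, `in_window`, `valid`, and attributes `d_slow` and
#'   `threshold`.
#' @examples
#' p <- biex_params(0.2, 1e-3, 50e-3)
#' sig <- decay_signal(liver_scheme(), biex_signal(p, 1000, liver_scheme()$b))
#' compute_yi_series(sig)
#' @export
compute_yi_series <- function(decay, b_grid = c(2, 4, 7, 10, 15, 20),
                              extra_b = 0, threshold = 60,
                              bounds = ivim_bounds()) {
  check_decay(decay)
  if (is.unsorted(b_grid, strictly = TRUE)) {
    stop("compute_yi_series: b_grid must be strictly ascending", call. = FALSE)
  }
  missing_b <- setdiff(b_grid, decay$b)
  if (length(missing_b) > 0) {
    stop(sprintf("compute_yi_series: grid value(s) %s not in the scheme",
                 paste(missing_b, collapse = ", ")), call. = FALSE)
  }
  extra_b <- intersect(extra_b, decay$b)
  all_b <- sort(union(b_grid, extra_b))
  fits <- purrr::map(all_b, function(bi) {
    tryCatch(segmented_fit(decay, b_start = bi, threshold = threshold,
                           bounds = bounds),
             error = function(e) NULL)
  })
  rows <- purrr::map2_dfr(fits, all_b, function(f, bi) {
    if (is.null(f)) {
      return(tibble::tibble(b_i = bi, pf_i = NA_real_, y_i = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(b_i = bi, pf_i = f$pf_i,
                   y_i = yi_transform(f$pf_i, clip = TRUE),
                   converged = f$converged)
  })
  d_slow <- NA_real_
  for (f in fits) if (!is.null(f)) { d_slow <- f$d_slow; break }
  out <- rows |>
    dplyr::mutate(
      in_fit = .data$b_i %in% b_grid,
      in_window = !is.na(.data$pf_i) & .data$pf_i > 0.05 & .data$pf_i < 0.4,
      valid = .data$converged & is.finite(.data$y_i) &
        !is.na(.data$pf_i) & .data$pf_i > 0 & .data$pf_i < 1) |>
    dplyr::select(-"converged")
  attr(out, "d_slow") <- d_slow
  attr(out, "threshold") <- threshold
  class(out) <- c("yi_series", class(out))
  out
}

#' Fit the log-odds line over fit-starting b-values
#'
#' Unweighted ordinary least squares of `y_i` on `b_i` over the valid
#' series points marked `in_fit`. Under the bi-exponential model the slope
#' estimates `d_fast - d_slow` and the intercept the log-odds of the
#' perfusion fraction at b = 0. Residuals (actual minus predicted) are
#' reported for every series point; points excluded from the fit get their
#' residual by extrapolating the fitted line, which is how the departure of
#' the b = 0 point from bi-exponential behaviour is quantified.
#'
#' @param series A `yi_series` tibble from [compute_yi_series()].
#' @param strict Drop points outside the (0.05, 0.4) linearity window from
#'   the fit (default `FALSE`: they are retained).
#'
#' @return An object of class `yi_regression`: `slope` (mm^2/s),
#'   `intercept` (log-odds), `r_squared`, `d_slow`, and `points` — the
#'   series tibble with `predicted` and `residual` columns added.
#' @export
fit_yi_line <- function(series, strict = FALSE) {
  stopifnot(inherits(series, "yi_series") ||
              all(c("b_i", "y_i", "in_fit", "valid") %in% names(series)))
  use <- series$in_fit & series$valid
  if (strict) use <- use & series$in_window
  if (sum(use) < 3) {
    stop("fit_yi_line: need at least 3 valid points for the line fit",
         call. = FALSE)
  }
  dat <- series[use, , drop = FALSE]
  fit <- stats::lm(y_i ~ b_i, data = dat)
  co <- stats::coef(fit)
  # R^2 computed directly so an exactly collinear series stays well-defined
  sst <- sum((dat$y_i - mean(dat$y_i))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  points <- tibble::as_tibble(series) |>
    dplyr::mutate(predicted = unname(co[1]) + unname(co[2]) * .data$b_i,
                  residual = .data$y_i - .data$predicted,
                  used_in_fit = dplyr::row_number() %in% which(use))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2,
                 d_slow = attr(series, "d_slow"),
                 points = points, n_fit = sum(use)),
            class = "yi_regression")
}

#' @export
print.yi_regression <- function(x, ...) {
  cat(sprintf(
    "<yi_regression> slope = %.4g mm^2/s, intercept = %.4f, R^2 = %.4f (%d points)\n",
    x$slope, x$intercept, x$r_squared, x$n_fit))
  invisible(x)
}

#' Derive IVIM parameters from the fitted log-odds line
#'
#' Converts the line fit into physical parameters: the stabilized fast
#' pseudo-diffusion coefficient `d_fast_yi = slope + d_slow`; the fast
#' perfusion fraction `f_fast` from the inverse log-odds of the intercept
#' (the bi-exponential-model prediction of the perfusion fraction at b = 0,
#' free of very fast components); and the very fast fraction
#' `f_vfast = f_tot - f_fast`, where `f_tot` is the total perfusion
#' fraction from a conventional fit started at b = 0. A negative raw
#' `f_vfast` is clipped to zero and flagged, as is a non-positive slope
#' (which would imply `d_fast <= d_slow`).
#'
#' @param reg A `yi_regression` from [fit_yi_line()].
#' @param d_slow Slow diffusion coefficient, mm^2/s (defaults to the value
#'   carried by the regression).
#' @param f_tot Total perfusion fraction in (0, 1), conventionally the
#'   segmented-fit `pf_i` at `b_start = 0`.
#'
#' @return A one-row tibble: `d_fast_yi`, `f_fast`, `f_tot`, `f_vfast`,
#'   `f_vfast_raw`, `slope_positive`, `f_vfast_clipped`.
#' @export
derive_params <- function(reg, d_slow = reg$d_slow, f_tot) {
  stopifnot(inherits(reg, "yi_regression"), d_slow > 0,
            f_tot > 0, f_tot < 1)
  f_fast <- inverse_yi(reg$intercept)
  f_vfast_raw <- f_tot - f_fast
  tibble::tibble(
    d_fast_yi = reg$slope + d_slow,
    f_fast = f_fast,
    f_tot = f_tot,
    f_vfast = max(f_vfast_raw, 0),
    f_vfast_raw = f_vfast_raw,
    slope_positive = reg$slope > 0,
    f_vfast_clipped = f_vfast_raw < 0)
}

#' Full per-scan log-odds IVIM estimate
#'
#' Composes the whole estimator for one scan: segmented fits over the grid
#' of starting b-values ([compute_yi_series()]), the log-odds line fit
#' ([fit_yi_line()]), and the derived parameters ([derive_params()]), with
#' the total perfusion fraction taken by default from the segmented fit at
#' b = 0. Deterministic given the input and configuration.
#'
#' A scan fails QC when the line fit's R^2 falls below `r2_floor`, when the
#' slope is non-positive, or when the underlying segmented fits fail
#' [fit_qc()].
#'
#' @inheritParams compute_yi_series
#' @param r2_floor Minimum acceptable R^2 of the line fit (default 0.5).
#' @param f_tot_method Source of the total perfusion fraction:
#'   `"segmented"` (default), `"full"` (full bi-exponential fit at b = 0)
#'   or `"triex"` (f_fast + f_vfast of a full tri-exponential fit).
#' @param strict Passed to [fit_yi_line()].
#'
#' @return An object of class `yi_fit`: `series`, `regression`, `params`
#'   (one-row tibble), `qc` (list with `pass` and `reasons`). Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- biex_params(0.2, 1e-3, 50e-3)
#' sig <- decay_signal(liver_scheme(), biex_signal(p, 1000, liver_scheme()$b))
#' fit <- yi_pipeline(sig)
#' glance(fit)
#' @export
yi_pipeline <- function(decay, b_grid = c(2, 4, 7, 10, 15, 20),
                        threshold = 60, bounds = ivim_bounds(),
                        r2_floor = 0.5,
                        f_tot_method = c("segmented", "full", "triex"),
                        strict = FALSE) {
  f_tot_method <- match.arg(f_tot_method)
  check_decay(decay)
  series <- compute_yi_series(decay, b_grid = b_grid, threshold = threshold,
                              bounds = bounds)
  reasons <- character()
  reg <- tryCatch(fit_yi_line(series, strict = strict),
                  error = function(e) NULL)
  if (is.null(reg)) {
    return(structure(list(series = series, regression = NULL, params = NULL,
                          qc = list(pass = FALSE,
                                    reasons = "log-odds line fit failed")),
                     class = "yi_fit"))
  }
  b0_fit <- tryCatch(segmented_fit(decay, b_start = 0, threshold = threshold,
                                   bounds = bounds), error = function(e) NULL)
  f_tot <- switch(f_tot_method,
    segmented = if (!is.null(b0_fit)) b0_fit$pf_i else NA_real_,
    full = full_biex_fit(decay, 0, threshold, bounds)$pf_i,
    triex = {
      tf <- full_triex_fit(decay, bounds)
      if (!is.null(tf$params)) tf$params$f_fast + tf$params$f_vfast
      else NA_real_
    })
  params <- if (is.finite(f_tot) && f_tot > 0 && f_tot < 1) {
    derive_params(reg, f_tot = f_tot)
  } else {
    reasons <- c(reasons, "total perfusion fraction unavailable or degenerate")
    NULL
  }
  if (reg$r_squared < r2_floor) {
    reasons <- c(reasons, sprintf("R^2 = %.3f below floor %.3f",
                                  reg$r_squared, r2_floor))
  }
  if (reg$slope <= 0) {
    reasons <- c(reasons, "non-positive log-odds slope (d_fast <= d_slow)")
  }
  if (!is.null(b0_fit)) {
    q <- fit_qc(list(b0_fit))
    if (!q$pass) reasons <- c(reasons, q$reasons)
  }
  structure(list(series = series, regression = reg, params = params,
                 qc = list(pass = length(reasons) == 0, reasons = reasons)),
            class = "yi_fit")
}

#' @export
print.yi_fit <- function(x, ...) {
  cat("<yi_fit>\n")
  if (!is.null(x$regression)) print(x$regression)
  if (!is.null(x$params)) {
    cat(sprintf("  d_fast_yi = %.4g mm^2/s, f_fast = %.4f, f_tot = %.4f, f_vfast = %.4f\n",
                x$params$d_fast_yi, x$params$f_fast, x$params$f_tot,
                x$params$f_vfast))
  }
  cat(sprintf("  QC: %s\n", if (x$qc$pass) "pass"
              else paste(x$qc$reasons, collapse = "; ")))
  invisible(x)
}

#' @rdname tidy.ivim_fit
#' @method tidy yi_fit
#' @export
tidy.yi_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("d_slow", "d_fast_yi", "f_fast", "f_tot", "f_vfast"),
    estimate = c(x$regression$d_slow, x$params$d_fast_yi, x$params$f_fast,
                 x$params$f_tot, x$params$f_vfast))
}

#' @rdname glance.ivim_fit
#' @method glance yi_fit
#' @export
glance.yi_fit <- function(x, ...) {
  tibble::tibble(
    slope = if (is.null(x$regression)) NA_real_ else x$regression$slope,
    intercept = if (is.null(x$regression)) NA_real_
                else x$regression$intercept,
    r_squared = if (is.null(x$regression)) NA_real_
                else x$regression$r_squared,
    n_fit = if (is.null(x$regression)) NA_integer_ else x$regression$n_fit,
    qc_pass = x$qc$pass)
}
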