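#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Scale-invariant: `cv(k * x) == cv(x)` for k > 0.
#'
#' @param x Numeric vector, length >= 2, non-zero mean.
#' @return Dimensionless ratio.
#' @examples
#' cv(c(1, 3))  # sqrt(2) / 2
#' @export
cv <- function(x) {
  if (length(x) < 2) stop("cv: need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("cv: mean is zero", call. = FALSE)
  stats::sd(x) / m
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("scan1", "scan2") %in% names(pairs))) {
    stop("expected a paired-measurement data frame with columns scan1, scan2",
         call. = FALSE)
  }
  if (anyNA(pairs$scan1) || anyNA(pairs$scan2)) {
    stop("paired measurements must be complete (apply QC filtering first)",
         call. = FALSE)
  }
  invisible(pairs)
}

#' Within-subject standard deviation of paired scans
#'
#' `sqrt(sum(d_i^2) / (2 n))` with `d_i = scan2 - scan1`, the conventional
#' two-measurement repeatability SD. Translation-invariant.
#'
#' @param pairs Data frame with columns `scan1` and `scan2` (one row per
#'   subject).
#' @return Scalar in the units of the input.
#' @examples
#' wsd(data.frame(scan1 = c(0, 0), scan2 = c(2, -2)))  # sqrt(2)
#' @export
wsd <- function(pairs) {
  check_pairs(pairs)
  d <- pairs$scan2 - pairs$scan1
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Bland-Altman mean difference and 95% limits of agreement
#'
#' Mean of `scan2 - scan1` and limits at mean +/- 1.96 times the sample SD
#' of the differences.
#'
#' @inheritParams wsd
#' @return A one-row tibble: `mean_diff`, `lower`, `upper`.
#' @export
bland_altman <- function(pairs) {
  check_pairs(pairs)
  if (nrow(pairs) < 2) {
    stop("bland_altman: need at least 2 pairs", call. = FALSE)
  }
  d <- pairs$scan2 - pairs$scan1
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s)
}

#' Intraclass correlation coefficient for scan-rescan agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC(2,1)
#' by default, computed from the mean-squares decomposition of the subject
#' x session table; `type = "icc3_1"` gives the two-way mixed consistency
#' variant. When every value is identical the ratio is undefined and the
#' ICC is reported as 1 with `degenerate = TRUE`.
#'
#' @inheritParams wsd
#' @param type `"icc2_1"` (default) or `"icc3_1"`.
#' @return A one-row tibble: `icc`, `type`, `degenerate`, `n`.
#' @export
icc <- function(pairs, type = c("icc2_1", "icc3_1")) {
  type <- match.arg(type)
  check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3) stop("icc: need at least 3 pairs", call. = FALSE)
  x <- cbind(pairs$scan1, pairs$scan2)
  k <- 2
  grand <- mean(x)
  subj <- rowMeans(x)
  sess <- colMeans(x)
  msr <- k * sum((subj - grand)^2) / (n - 1)
  msc <- n * sum((sess - grand)^2) / (k - 1)
  mse <- sum((x - outer(subj, rep(1, k)) - outer(rep(1, n), sess) +
                grand)^2) / ((n - 1) * (k - 1))
  denom2 <- msr + (k - 1) * mse + k / n * (msc - mse)
  denom3 <- msr + (k - 1) * mse
  degenerate <- (type == "icc2_1" && denom2 == 0) ||
    (type == "icc3_1" && denom3 == 0)
  val <- if (degenerate) 1 else if (type == "icc2_1") {
    (msr - mse) / denom2
  } else {
    (msr - mse) / denom3
  }
  tibble::tibble(icc = val, type = type, degenerate = degenerate, n = n)
}

#' Full scan-rescan reproducibility report for one parameter
#'
#' Combines the dispersion and agreement statistics reported for
#' scan-rescan IVIM studies: mean and CoV over all scans, and wSD,
#' Bland-Altman difference with 95% limits, and ICC over complete pairs.
#'
#' @inheritParams icc
#' @return A one-row tibble: `mean`, `cov`, `wsd`, `ba_difference`,
#'   `ba_lower`, `ba_upper`, `icc`, `n_scans`, `n_pairs`.
#' @export
repro_report <- function(pairs, type = c("icc2_1", "icc3_1")) {
  type <- match.arg(type)
  check_pairs(pairs)
  allv <- c(pairs$scan1, pairs$scan2)
  ba <- bland_altman(pairs)
  ic <- icc(pairs, type)
  tibble::tibble(mean = mean(allv), cov = cv(allv), wsd = wsd(pairs),
                 ba_difference = ba$mean_diff, ba_lower = ba$lower,
                 ba_upper = ba$upper, icc = ic$icc,
                 n_scans = length(allv), n_pairs = nrow(pairs))
}

#' Compare estimators' stability over a cohort
#'
#' Takes a long per-scan results table — one row per (scan, method,
#' parameter) — and produces the scan-rescan comparison reported for
#' competing IVIM estimators: per parameter and method, the mean and CoV
#' over all scans and the wSD, Bland-Altman and ICC statistics over
#' complete scan pairs. When a truth table is supplied (simulation only),
#' bias and RMSE against the per-scan truth are appended.
#'
#' @param results Data frame with columns `subject_id`, `session` (1 or 2),
#'   `method`, `parameter`, `value`.
#' @param truth Optional data frame with columns `subject_id`, `session`,
#'   `parameter`, `value` holding the simulated truth.
#' @param type ICC variant, see [icc()].
#'
#' @return A tibble with one row per (parameter, method).
#' @export
method_comparison <- function(results, truth = NULL,
                              type = c("icc2_1", "icc3_1")) {
  type <- match.arg(type)
  need <- c("subject_id", "session", "method", "parameter", "value")
  if (!all(need %in% names(results))) {
    stop("method_comparison: results must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  scan_sets <- results |>
    dplyr::distinct(.data$method, .data$subject_id, .data$session) |>
    dplyr::count(.data$method, name = "n_scans")
  if (dplyr::n_distinct(scan_sets$n_scans) > 1) {
    stop("method_comparison: methods cover different scan sets",
         call. = FALSE)
  }
  out <- results |>
    dplyr::group_by(.data$parameter, .data$method) |>
    dplyr::group_modify(function(df, key) {
      pairs <- df |>
        tidyr::pivot_wider(id_cols = "subject_id",
                           names_from = "session",
                           names_prefix = "scan",
                           values_from = "value") |>
        dplyr::filter(!is.na(.data$scan1), !is.na(.data$scan2))
      rep <- repro_report(pairs, type)
      rep$n_scans <- nrow(df)
      rep
    }) |>
    dplyr::ungroup()
  if (!is.null(truth)) {
    err <- results |>
      dplyr::inner_join(truth, by = c("subject_id", "session", "parameter"),
                        suffix = c("", "_true")) |>
      dplyr::group_by(.data$parameter, .data$method) |>
      dplyr::summarise(
        bias = mean(.data$value - .data$value_true),
        rmse = sqrt(mean((.data$value - .data$value_true)^2)),
        .groups = "drop")
    out <- dplyr::left_join(out, err, by = c("parameter", "method"))
  }
  out
}
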