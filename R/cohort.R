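#' Fit every scan of a cohort with one or more estimators
#'
#' Applies the chosen estimators to each scan of a nested scan table (as
#' produced by [generate_cohort()] or [read_decay_csv()]) and returns a
#' long per-scan parameter table ready for [method_comparison()].
#'
#' Methods: `"segmented"` — conventional segmented bi-exponential fit from
#' `b_start` (parameters `d_slow`, `pf_i`, `d_fast`); `"yi"` — the
#' shifted-start log-odds estimator (parameters `d_slow`, `d_fast`,
#' `f_fast`, `f_tot`, `f_vfast`, plus `r_squared` as a diagnostic);
#' `"triex"` — full tri-exponential fit (`f_tot`, `f_fast`, `f_vfast` and
#' the three rates). A scan that fails an estimator's QC keeps its rows
#' with `qc_pass = FALSE` (or `NA` values when the estimate is undefined)
#' so exclusions stay auditable.
#'
#' @param scans Nested tibble with columns `subject_id`, `scan_id`,
#'   `session`, `decay`.
#' @param methods Subset of `c("segmented", "yi", "triex")`.
#' @param b_start Starting b-value of the conventional segmented fit
#'   (default 2; b = 0 is conventionally excluded for liver biex fitting).
#' @param b_grid,threshold,r2_floor Passed to [yi_pipeline()].
#'
#' @return A tibble with columns `subject_id`, `scan_id`, `session`,
#'   `method`, `parameter`, `value`, `qc_pass`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 2, seed = 1))
#' fit_scans(coh, methods = "segmented")
#' @export
fit_scans <- function(scans, methods = c("segmented", "yi"), b_start = 2,
                      b_grid = c(2, 4, 7, 10, 15, 20), threshold = 60,
                      r2_floor = 0.5) {
  methods <- match.arg(methods, c("segmented", "yi", "triex"),
                       several.ok = TRUE)
  stopifnot(all(c("subject_id", "scan_id", "session", "decay") %in%
                  names(scans)))
  purrr::map_dfr(seq_len(nrow(scans)), function(i) {
    d <- scans$decay[[i]]
    out <- list()
    if ("segmented" %in% methods) {
      fit <- tryCatch(segmented_fit(d, b_start = b_start,
                                    threshold = threshold),
                      error = function(e) NULL)
      out$segmented <- if (is.null(fit)) {
        tibble::tibble(method = "segmented",
                       parameter = c("d_slow", "pf_i", "d_fast"),
                       value = NA_real_, qc_pass = FALSE)
      } else {
        tibble::tibble(method = "segmented",
                       parameter = c("d_slow", "pf_i", "d_fast"),
                       value = c(fit$d_slow, fit$pf_i, fit$d_fast),
                       qc_pass = fit_qc(list(fit))$pass)
      }
    }
    if ("yi" %in% methods) {
      fit <- tryCatch(yi_pipeline(d, b_grid = b_grid, threshold = threshold,
                                  r2_floor = r2_floor),
                      error = function(e) NULL)
      out$yi <- if (is.null(fit) || is.null(fit$params)) {
        tibble::tibble(method = "yi",
                       parameter = c("d_slow", "d_fast", "f_fast", "f_tot",
                                     "f_vfast", "r_squared"),
                       value = NA_real_, qc_pass = FALSE)
      } else {
        tibble::tibble(method = "yi",
                       parameter = c("d_slow", "d_fast", "f_fast", "f_tot",
                                     "f_vfast", "r_squared"),
                       value = c(fit$regression$d_slow,
                                 fit$params$d_fast_yi, fit$params$f_fast,
                                 fit$params$f_tot, fit$params$f_vfast,
                                 fit$regression$r_squared),
                       qc_pass = fit$qc$pass)
      }
    }
    if ("triex" %in% methods) {
      fit <- tryCatch(full_triex_fit(d), error = function(e) NULL)
      out$triex <- if (is.null(fit) || is.null(fit$params)) {
        tibble::tibble(method = "triex",
                       parameter = c("f_tot", "f_fast", "f_vfast", "d_slow",
                                     "d_fast", "d_vfast"),
                       value = NA_real_, qc_pass = FALSE)
      } else {
        p <- fit$params
        tibble::tibble(method = "triex",
                       parameter = c("f_tot", "f_fast", "f_vfast", "d_slow",
                                     "d_fast", "d_vfast"),
                       value = c(p$f_fast + p$f_vfast, p$f_fast, p$f_vfast,
                                 p$d_slow, p$d_fast, p$d_vfast),
                       qc_pass = fit$converged)
      }
    }
    dplyr::bind_cols(
      tibble::tibble(subject_id = scans$subject_id[i],
                     scan_id = scans$scan_id[i],
                     session = scans$session[i]),
      dplyr::bind_rows(out))
  })
}

#' Exclude subjects with any QC-failing scan
#'
#' Mirrors the enrolment practice of scan-rescan studies: a subject whose
#' scans fail any estimator's QC is dropped from every method's statistics
#' so all methods are compared on the same scan set. Exclusions are
#' reported via a message and an attribute.
#'
#' @param results Long table from [fit_scans()].
#' @return The filtered table, with the excluded subject ids in the
#'   `excluded` attribute.
#' @export
apply_qc <- function(results) {
  stopifnot(all(c("subject_id", "qc_pass") %in% names(results)))
  bad <- sort(unique(results$subject_id[!results$qc_pass |
                                          is.na(results$value)]))
  if (length(bad) > 0) {
    message("QC excluded ", length(bad), " subject(s): ",
            paste(bad, collapse = ", "))
  }
  out <- results[!results$subject_id %in% bad, , drop = FALSE]
  attr(out, "excluded") <- bad
  out
}
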