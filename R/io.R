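#' Read a long-format decay-table CSV into scan records
#'
#' The on-disk format is one row per (scan, b-value) with columns
#' `subject_id`, `scan_id`, `session`, `b`, `signal` and optionally `nsa`
#' (assumed 1 when absent). Rows are sorted by b within each scan;
#' duplicate b-values within a scan and non-positive signals are parse
#' errors that name the offending row.
#'
#' @param path Path to the CSV file.
#' @return A nested tibble with one row per scan: `subject_id`, `scan_id`,
#'   `session`, and a `decay` list-column of decay tibbles.
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "scan_id", "session", "b", "signal")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_decay_csv: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"nsa" %in% names(raw)) raw$nsa <- 1L
  bad <- which(!is.finite(raw$signal) | raw$signal <= 0)
  if (length(bad) > 0) {
    stop(sprintf("read_decay_csv: non-positive signal at data row %d", bad[1]),
         call. = FALSE)
  }
  if (!all(raw$session %in% c(1, 2))) {
    stop("read_decay_csv: session must be 1 or 2", call. = FALSE)
  }
  raw |>
    dplyr::group_by(.data$subject_id, .data$scan_id, .data$session) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$b)
      if (anyDuplicated(df$b)) {
        stop(sprintf("read_decay_csv: duplicate b-value in scan %s",
                     key$scan_id), call. = FALSE)
      }
      tibble::tibble(decay = list(
        tibble::tibble(b = df$b, signal = df$signal,
                       nsa = as.integer(df$nsa))))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(session = as.integer(.data$session))
}

#' Write scan records as a long-format decay CSV
#'
#' Inverse of [read_decay_csv()]: unnests the `decay` list-column into one
#' row per (scan, b-value). Column order is fixed so repeated runs are
#' byte-stable.
#'
#' @param scans Nested tibble as produced by [read_decay_csv()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(scans, path) {
  stopifnot(all(c("subject_id", "scan_id", "session", "decay") %in%
                  names(scans)))
  long <- scans |>
    dplyr::select("subject_id", "scan_id", "session", "decay") |>
    tidyr::unnest("decay") |>
    dplyr::select("subject_id", "scan_id", "session", "b", "signal", "nsa")
  readr::write_csv(long, path)
  invisible(path)
}

#' Write a simulated cohort's decay tables and truth table
#'
#' Emits `decays.csv` (long-format decay tables, see [write_decay_csv()])
#' and `truth.csv` (one row per scan with the true tri-exponential
#' parameters) under `dir`.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  decay_path <- file.path(dir, "decays.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_decay_csv(cohort, decay_path)
  cohort |>
    dplyr::select("subject_id", "scan_id", "session", "f_slow", "f_fast",
                  "f_vfast", "d_slow", "d_fast", "d_vfast") |>
    readr::write_csv(truth_path)
  invisible(c(decay_path, truth_path))
}

#' Read one diffusion-weighted scan from NIfTI + bval files
#'
#' Loads a 4D diffusion-weighted volume, an FSL-style whitespace-separated
#' b-value text file (one value per volume) and a binary ROI mask
#' (included where mask > 0.5), and reduces the scan to a decay table of
#' ROI-mean signal per b-value. Repeated b-values (separate excitations
#' stored as volumes) are averaged per nominal b with the repeat count
#' recorded as `nsa`.
#'
#' @param volume_path Path to the 4D NIfTI volume.
#' @param bval_path Path to the b-value text file.
#' @param mask_path Path to the 3D mask NIfTI matching the spatial
#'   dimensions.
#' @param subject_id,scan_id,session Identifiers attached to the record.
#'
#' @return A one-row nested tibble (same shape as [read_decay_csv()]).
#' @export
read_nifti_scan <- function(volume_path, bval_path, mask_path,
                            subject_id = "subj", scan_id = "scan",
                            session = 1L) {
  vol <- RNifti::readNifti(volume_path)
  arr <- as.array(vol)
  if (length(dim(arr)) != 4) {
    stop("read_nifti_scan: volume must be 4D", call. = FALSE)
  }
  bvals <- scan(bval_path, quiet = TRUE)
  if (length(bvals) != dim(arr)[4]) {
    stop(sprintf("read_nifti_scan: %d b-values but %d volumes",
                 length(bvals), dim(arr)[4]), call. = FALSE)
  }
  mask <- as.array(RNifti::readNifti(mask_path)) > 0.5
  mask <- conform_mask(mask, dim(arr)[1:3])
  if (!all(dim(mask) == dim(arr)[1:3])) {
    stop("read_nifti_scan: mask does not match the spatial dimensions",
         call. = FALSE)
  }
  if (!any(mask)) stop("read_nifti_scan: empty mask", call. = FALSE)
  roi_mean <- vapply(seq_along(bvals), function(i) {
    v <- arr[, , , i, drop = FALSE]
    mean(v[array(mask, dim(arr)[1:3])])
  }, numeric(1))
  per_b <- tibble::tibble(b = bvals, signal = roi_mean) |>
    dplyr::group_by(.data$b) |>
    dplyr::summarise(signal = mean(.data$signal), nsa = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$b) |>
    dplyr::mutate(nsa = as.integer(.data$nsa))
  tibble::tibble(subject_id = subject_id, scan_id = scan_id,
                 session = as.integer(session), decay = list(per_b))
}
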