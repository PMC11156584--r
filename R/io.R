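#' Read and write photometry trace CSV files
#'
#' The trace dialect is comma-separated, '.' decimal, UTF-8, header
#' mandatory: columns `time_s`, `intensity_au` and optionally `state`
#' (wake/nrem/rem). Time must be strictly increasing.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_trace_csv <- function(path) {
  d <- read_checked_csv(path, c("time_s", "intensity_au"))
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    abort(sprintf("%s: time_s must be strictly increasing", path))
  }
  d
}

#' @param data Data frame to write.
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(data, path) {
  stopifnot(all(c("time_s", "intensity_au") %in% names(data)))
  write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a histology profile CSV (`ap_distance_um`, `mean_intensity_au`)
#' @inheritParams read_trace_csv
#' @return A tibble sorted by distance.
#' @export
read_histology_csv <- function(path) {
  d <- read_checked_csv(path, c("ap_distance_um", "mean_intensity_au"))
  dplyr::arrange(d, .data$ap_distance_um)
}

#' Read a calibration CSV (`concentration`, `intensity_au`)
#' @inheritParams read_trace_csv
#' @return A tibble.
#' @export
read_calibration_csv <- function(path) {
  read_checked_csv(path, c("concentration", "intensity_au"))
}

# internal: CSV reader with column and numeric checks; parse errors name
# the offending line
read_checked_csv <- function(path, numeric_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- tryCatch(
    read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed CSV %s: %s", path,
                                      conditionMessage(e))))
  missing <- setdiff(numeric_cols, names(d))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s) %s", path,
                  paste(missing, collapse = ", ")))
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(is.na(v) & !is.na(d[[cc]]))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value in column %s at data line %d",
                    path, cc, bad[1]))
    }
    d[[cc]] <- v
  }
  as_tibble(d)
}

#' Read a structured run configuration
#'
#' Configurations are JSON (YAML also accepted when the yaml package is
#' installed). Keys carry explicit units as suffixes (`*_um`, `*_s`,
#' `*_um2_per_s`, `*_hz`, `*_au`); unknown keys for a command are
#' rejected at run time by [run_command()].
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs need the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
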