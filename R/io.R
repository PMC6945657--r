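# Scan-file dialect, bundled benchmark tables and report writers.
#
# Scan files are plain text: '#'-prefixed header lines with 'key: value'
# pairs (linactune_scan, kind, depth_cm, normalization, spacing_cm), then a
# two-column CSV body 'position_cm,dose_percent'. Vendor water-tank formats
# are proprietary; this dialect carries exactly what the gamma engine needs.

#' Write a scan curve to a scan file
#'
#' @param curve A [scan_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(curve, path) {
  stopifnot(inherits(curve, "scan_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# linactune_scan: v1",
    sprintf("# kind: %s", curve$kind),
    sprintf("# depth_cm: %s",
            if (is.finite(curve$depth)) format(curve$depth, digits = 15) else "NA"),
    sprintf("# normalization: %s", curve$normalization),
    sprintf("# spacing_cm: %s", format(curve$spacing, digits = 15)),
    "position_cm,dose_percent",
    sprintf("%s,%s", format(curve$positions, digits = 15, trim = TRUE),
            format(curve$values, digits = 15, trim = TRUE))
  ), con)
  invisible(path)
}

#' Read a scan curve from a scan file
#'
#' Accepts LF or CRLF line endings; malformed files are rejected with
#' line-numbered messages. `write_scan()` then `read_scan()` reproduces
#' positions and values to within 1e-9.
#'
#' @param path Path to a scan file.
#' @return A [scan_curve()].
#' @export
read_scan <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1)
    stop("scan file must start with a contiguous '#' header block")
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  need <- c("linactune_scan", "kind", "depth_cm", "normalization", "spacing_cm")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("scan header is missing key(s): ", paste(missing, collapse = ", "))
  h <- stats::setNames(vals, keys)
  body <- lines[-hdr_idx]
  if (length(body) < 1L || body[1] != "position_cm,dose_percent")
    stop(sprintf("line %d: expected column header 'position_cm,dose_percent'",
                 length(hdr_idx) + 1L))
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  off <- length(hdr_idx) + 1L
  pos <- numeric(length(parts)); dose <- numeric(length(parts))
  for (i in seq_along(parts)) {
    ln <- off + i
    if (length(parts[[i]]) != 2L)
      stop(sprintf("line %d: expected two comma-separated fields", ln))
    p <- suppressWarnings(as.numeric(parts[[i]][1]))
    v <- suppressWarnings(as.numeric(parts[[i]][2]))
    if (!is.finite(p) || !is.finite(v))
      stop(sprintf("line %d: non-numeric or NaN value", ln))
    if (i > 1 && p <= pos[i - 1])
      stop(sprintf("line %d: positions must be strictly increasing", ln))
    pos[i] <- p; dose[i] <- v
  }
  depth <- suppressWarnings(as.numeric(h[["depth_cm"]]))
  scan_curve(kind = h[["kind"]], positions = pos, values = dose,
             depth = if (is.finite(depth)) depth else NA_real_,
             normalization = h[["normalization"]])
}

# Bundled benchmark tables: published gamma-index passing-rate tables from a
# linac-commissioning study of a Varian-type machine at 6 MV and 10 MV.
fixture_registry <- list(
  `1`  = list(kind = "history", label = "PDD history sweep, 6.26 MeV"),
  `2`  = list(kind = "history", label = "PDD history sweep, 5.40 MeV"),
  `3`  = list(kind = "history", label = "Profile history sweep, 6.26 MeV"),
  `4`  = list(kind = "history", label = "Profile history sweep, 5.40 MeV"),
  `5`  = list(kind = "energy_fwhm", label = "6 MV stage 1: energy FWHM"),
  `6`  = list(kind = "focal_spot", label = "6 MV stage 2: focal-spot FWHM"),
  `7`  = list(kind = "divergence", label = "6 MV stage 3: divergence"),
  `8`  = list(kind = "history", label = "PDD history sweep, 10.7 MeV"),
  `9`  = list(kind = "history", label = "PDD history sweep, 10.5 MeV"),
  `10` = list(kind = "history", label = "Profile history sweep, 10.7 MeV"),
  `11` = list(kind = "history", label = "Profile history sweep, 10.5 MeV"),
  `12` = list(kind = "energy_fwhm", label = "10 MV stage 1: energy FWHM"),
  `13` = list(kind = "cross_depth", label = "10 MV energy-FWHM depth comparison"),
  `14` = list(kind = "focal_spot", label = "10 MV stage 2: focal-spot FWHM"),
  `15` = list(kind = "divergence", label = "10 MV stage 3: divergence")
)

#' Load a bundled benchmark table
#'
#' The package ships, as plain-CSV fixtures, the printed passing-rate tables
#' of a published linac-commissioning study (history sweeps at two candidate
#' energies per nominal beam quality, the three serial tuning stages for each,
#' and one depth-by-depth comparison). Values are exactly as printed.
#'
#' @param table_id Integer 1-15.
#' @return A list with `table_id`, `kind`, `label` and `data` (a data frame).
#' @examples
#' load_paper_fixture(1)$data
#' @export
load_paper_fixture <- function(table_id) {
  key <- as.character(table_id)
  if (length(table_id) != 1L || !key %in% names(fixture_registry))
    stop("unknown table id: ", table_id, " (valid: 1-15)")
  path <- system.file("extdata", "tables",
                      sprintf("table%02d.csv", as.integer(table_id)),
                      package = "linactune", mustWork = TRUE)
  data <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  c(list(table_id = as.integer(table_id)), fixture_registry[[key]],
    list(data = data))
}

#' Trend record from a bundled history-sweep table
#'
#' Convenience wrapper: loads a history-sweep fixture and assembles the
#' corresponding [build_trend()] record (histories are stored in units of
#' 1e6 in the tables).
#'
#' @param table_id Id of a history-sweep table (1-4, 8-11).
#' @param energy Candidate energy in MeV (metadata).
#' @return A `trend_record`.
#' @export
trend_from_fixture <- function(table_id, energy = NA_real_) {
  fx <- load_paper_fixture(table_id)
  if (fx$kind != "history")
    stop("table ", table_id, " is not a history-sweep table")
  d <- fx$data
  build_trend(fx$label,
              data.frame(n_histories = d$n_histories_1e6 * 1e6,
                         avg_uncertainty = d$avg_uncertainty,
                         rate_3_3 = d$rate_3_3, rate_2_2 = d$rate_2_2,
                         rate_1_1 = d$rate_1_1),
              energy = energy)
}

#' Write a gamma report
#'
#' Serialises one or more `gamma_result`s to JSON (full detail, optionally
#' with per-point gamma values) or CSV (one row per criteria set).
#'
#' @param results A `gamma_result` or list of them.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @param include_gamma Include per-point gamma values in JSON output.
#' @return `path`, invisibly.
#' @export
write_gamma_report <- function(results, path, format = c("json", "csv"),
                               include_gamma = FALSE) {
  format <- match.arg(format)
  if (inherits(results, "gamma_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "gamma_result")))
  rows <- lapply(results, function(r) {
    out <- list(schema = "linactune_gamma_report_v1",
                dose_pct = r$criteria$dose_pct, dta_mm = r$criteria$dta_mm,
                search_cap_cm = r$criteria$search_cap_cm,
                resample_factor = r$criteria$resample_factor,
                n_points = r$n_points, n_pass = r$n_pass,
                n_uncovered = r$n_uncovered, passing_rate = r$passing_rate)
    if (include_gamma) out$gamma_values <- r$gamma_values
    out
  })
  if (format == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[c("dose_pct", "dta_mm", "n_points", "n_pass",
                        "n_uncovered", "passing_rate")])))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
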