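# Readers and writers for the package's plain-text interchange formats:
#   - clinical table CSV (one header row, empty cell = missing)
#   - spectrum matrix CSV/TSV (first column sample ID, remaining columns
#     integer m/z bin labels)
#   - long-format scan CSV (scan_index,time_s,mz,intensity)
#   - mzML (MS1 scans, via mzR, optional)
# Numeric fields are written with 17 significant digits so CSV round-trips
# are bit-exact for doubles.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write / read a clinical table CSV
#'
#' One header row; empty cells encode missing values.
#'
#' @param clinical Clinical table `data.frame`.
#' @param path File path.
#' @return `read_clinical_table` returns a `data.frame`.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  for (v in names(out)) {
    if (is.numeric(out[[v]])) out[[v]] <- fmt_num(out[[v]])
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write / read a spectrum matrix CSV
#'
#' First column `sample_id`, remaining columns labelled by integer m/z bin.
#'
#' @param mat Numeric matrix, samples x bins, with dimnames.
#' @param path File path.
#' @param sep Field separator, `","` (CSV, default) or `"\t"` (TSV).
#' @return `read_spectrum_matrix` returns a numeric matrix with dimnames.
#' @export
write_spectrum_matrix <- function(mat, path, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(mat)), collapse = sep), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' @rdname write_spectrum_matrix
#' @export
read_spectrum_matrix <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write / read a raw acquisition as long-format scan CSV
#'
#' Columns `scan_index,time_s,mz,intensity`, one row per peak, scans ordered
#' by index.
#'
#' @param raw A `raw_acquisition`.
#' @param path File path.
#' @return `read_scan_csv` returns a `raw_acquisition` (without ground-truth
#'   windows, which only simulated acquisitions carry).
#' @export
write_scan_csv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_acquisition"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("scan_index,time_s,mz,intensity", con)
  for (i in seq_along(raw$scans)) {
    s <- raw$scans[[i]]
    writeLines(sprintf("%d,%s,%s,%s", i, sprintf("%.17g", raw$times[i]),
                       fmt_num(s$mz), fmt_num(s$intensity)), con)
  }
  invisible(path)
}

#' @rdname write_scan_csv
#' @param sample_id Metadata label attached on read.
#' @export
read_scan_csv <- function(path, sample_id = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_index", "time_s", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop_bad_arg("scan CSV must have columns: ", paste(need, collapse = ", "))
  }
  idx <- sort(unique(df$scan_index))
  scans <- lapply(idx, function(i) {
    sub <- df[df$scan_index == i, ]
    list(mz = sub$mz, intensity = sub$intensity)
  })
  times <- vapply(idx, function(i) df$time_s[df$scan_index == i][1], numeric(1))
  if (any(diff(times) <= 0)) stop_bad_arg("scan times must be strictly increasing")
  structure(list(times = times, scans = scans,
                 metadata = list(sample_id = sample_id, instrument_mode = NA_character_),
                 truth = NULL),
            class = "raw_acquisition")
}

#' Read an mzML acquisition (MS1 scans)
#'
#' Uses the Bioconductor `mzR` parser; both profile and centroid data are
#' accepted (either way the peak list is binned downstream).
#'
#' @param path Path to an mzML file.
#' @param sample_id Metadata label.
#' @return A `raw_acquisition`.
#' @export
read_mzml_acquisition <- function(path, sample_id = basename(path)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_bad_arg("reading mzML requires the 'mzR' package")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  keep <- which(hdr$msLevel == 1L)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(keep, function(i) {
    list(mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
  })
  structure(list(times = hdr$retentionTime[keep], scans = scans,
                 metadata = list(sample_id = sample_id, instrument_mode = NA_character_),
                 truth = NULL),
            class = "raw_acquisition")
}
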