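# Raw-acquisition processing: TIC-based window segmentation, unit-mass
# binning, background subtraction, unit-area normalisation, and replicate
# averaging. The composition turns one raw scan stream into one processed
# spectrum per sample.

scan_tics <- function(raw) {
  vapply(raw$scans, function(s) sum(s$intensity), numeric(1))
}

#' Segment an acquisition into background and sample windows
#'
#' Identifies the leading background region and every sample-insertion window
#' from the rapid rise in the total ion count (TIC) when the loaded probe
#' enters the source. The background TIC level is estimated from the leading
#' scans; a scan is "high" when its TIC is at least `rise_factor` times that
#' level, and sample windows are maximal runs of at least `min_window_scans`
#' consecutive high scans (shorter runs are ignored as transients).
#'
#' @param raw A `raw_acquisition`.
#' @param rise_factor TIC ratio (> 1) defining a sample scan. Default 5.
#' @param min_window_scans Minimum run length for a sample window. Default 5.
#'
#' @return Object of class `window_segmentation`: list with `background` and
#'   `samples`, half-open 1-based scan-index intervals `c(start, end)`.
#' @export
segment_acquisition <- function(raw, rise_factor = 5, min_window_scans = 5L) {
  stopifnot(inherits(raw, "raw_acquisition"))
  check_number(rise_factor, "rise_factor", lower = 1 + 1e-9)
  n <- length(raw$scans)
  if (n == 0L) stop_bad_arg("acquisition contains zero scans")
  if (n < min_window_scans) {
    stop_bad_arg("acquisition has fewer scans than 'min_window_scans'")
  }
  tic <- scan_tics(raw)

  # Background level from the leading scans; the stream must open in background.
  bg_level <- median(tic[seq_len(min_window_scans)])
  threshold <- rise_factor * bg_level
  high <- tic >= threshold
  if (high[1]) {
    stop_bad_arg("no background region identifiable: acquisition starts high")
  }
  if (all(high[-1])) {
    stop_bad_arg("no background region identifiable: all scans high")
  }

  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  background <- c(1L, ends[1] + 1L)

  keep <- runs$values & runs$lengths >= min_window_scans
  samples <- Map(function(s, e) c(s, e + 1L), starts[keep], ends[keep])

  structure(list(background = background, samples = unname(samples),
                 threshold = threshold, background_level = bg_level),
            class = "window_segmentation")
}

#' @export
print.window_segmentation <- function(x, ...) {
  cat(sprintf("<window_segmentation> background [%d, %d), %d sample window(s)\n",
              x$background[1], x$background[2], length(x$samples)))
  invisible(x)
}

#' Bin a centroid/profile peak list to unit mass
#'
#' Each peak is assigned to the integer bin `round(m/z)` under the half-open
#' convention that bin `k` covers `[k - 0.5, k + 0.5)` (round-half-up), and
#' intensities within a bin are summed. Peaks outside `bin_range` are dropped
#' and tallied; total intensity is conserved up to the reported dropped mass.
#'
#' @param mz Numeric m/z values (finite).
#' @param intensity Nonnegative intensities, same length as `mz`.
#' @param bin_range Inclusive integer interval `c(low, high)`.
#'
#' @return Named intensity vector over the bin range with attributes
#'   `dropped_mass` (total intensity outside the range) and `dropped_count`.
#' @export
bin_to_unit_mass <- function(mz, intensity, bin_range = c(11L, 1000L)) {
  if (length(mz) != length(intensity)) stop_bad_arg("'mz' and 'intensity' lengths differ")
  if (any(!is.finite(mz))) stop_bad_arg("m/z values must be finite")
  if (any(intensity < 0)) stop_bad_arg("negative intensity in peak list")
  bins <- seq(bin_range[1], bin_range[2])
  k <- round_half_up(mz)
  inside <- k >= bin_range[1] & k <= bin_range[2]
  out <- numeric(length(bins))
  if (any(inside)) {
    idx <- k[inside] - bin_range[1] + 1
    sums <- rowsum(intensity[inside], idx)
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  names(out) <- bins
  attr(out, "dropped_mass") <- sum(intensity[!inside])
  attr(out, "dropped_count") <- sum(!inside)
  out
}

#' Per-bin mean and standard deviation over a scan window
#'
#' Bins every scan in the window to unit mass (so all scans share one axis),
#' then returns the per-bin arithmetic mean and population standard deviation
#' (N divisor) across the window's scans.
#'
#' @param raw A `raw_acquisition`.
#' @param window Half-open scan-index interval `c(start, end)`.
#' @param bin_range Inclusive integer m/z interval.
#' @return List with `mean`, `sd` (named vectors) and `n_scans`.
#' @export
summarize_window <- function(raw, window, bin_range = c(11L, 1000L)) {
  stopifnot(inherits(raw, "raw_acquisition"))
  if (window[2] <= window[1] || window[2] > length(raw$scans) + 1L ||
      window[1] < 1L) {
    stop_bad_arg("empty or out-of-range window")
  }
  idx <- seq.int(window[1], window[2] - 1L)
  binned <- vapply(raw$scans[idx], function(s) {
    as.numeric(bin_to_unit_mass(s$mz, s$intensity, bin_range))
  }, numeric(bin_range[2] - bin_range[1] + 1L))
  # binned: bins x scans
  m <- rowMeans(binned)
  v <- rowMeans(binned^2) - m^2
  s <- sqrt(pmax(v, 0))
  bins <- seq(bin_range[1], bin_range[2])
  names(m) <- bins; names(s) <- bins
  list(mean = m, sd = s, n_scans = length(idx))
}

#' Subtract a background spectrum, clipping negatives to zero
#'
#' Elementwise `signal - background`; negative results are clipped to zero
#' (downstream chi-squared feature scoring requires nonnegative features) and
#' the total intensity removed by clipping is reported.
#'
#' @param signal,background Equal-length intensity vectors.
#' @return Corrected vector with attribute `clip_mass`.
#' @export
subtract_background <- function(signal, background) {
  if (length(signal) != length(background)) {
    stop_bad_arg("'signal' and 'background' must have equal length")
  }
  diff <- signal - background
  clipped <- pmax(diff, 0)
  attr(clipped, "clip_mass") <- -sum(diff[diff < 0])
  clipped
}

#' Normalise a spectrum to unit area
#'
#' @param spectrum Nonnegative intensity vector with at least one positive
#'   entry.
#' @return `spectrum / sum(spectrum)`, summing to 1 within 1e-9.
#' @export
normalize_unit_area <- function(spectrum) {
  total <- sum(spectrum)
  if (!is.finite(total) || total <= 0) {
    stop_bad_arg("cannot normalise an all-zero spectrum: empty measurement")
  }
  spectrum / total
}

#' Average unit-area replicate spectra into a processed spectrum
#'
#' Computes the per-bin arithmetic mean and population (N divisor) replicate
#' standard deviation. The mean of unit-area vectors itself has unit area and
#' is deliberately not re-normalised.
#'
#' @param spectra List of equal-length unit-area intensity vectors.
#' @param sample_id Optional sample identifier.
#' @return Object of class `processed_spectrum`: list with `sample_id`,
#'   `intensities`, `per_bin_sd`, `n_replicates`.
#' @export
average_replicates <- function(spectra, sample_id = NULL) {
  if (length(spectra) < 1L) stop_bad_arg("need at least one replicate")
  lens <- vapply(spectra, length, integer(1))
  if (length(unique(lens)) != 1L) stop_bad_arg("replicates must have equal length")
  sums <- vapply(spectra, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-6)) {
    stop_bad_arg("replicates must be unit-area normalised before averaging")
  }
  mat <- do.call(rbind, lapply(spectra, as.numeric))
  m <- colMeans(mat)
  v <- colMeans(mat^2) - m^2
  s <- sqrt(pmax(v, 0))
  names(m) <- names(spectra[[1]]); names(s) <- names(spectra[[1]])
  structure(list(sample_id = sample_id, intensities = m, per_bin_sd = s,
                 n_replicates = length(spectra)),
            class = "processed_spectrum")
}

#' @export
print.processed_spectrum <- function(x, ...) {
  cat(sprintf("<processed_spectrum> %s: %d bins, %d replicate(s), area %.9f\n",
              x$sample_id %||% "<unnamed>", length(x$intensities),
              x$n_replicates, sum(x$intensities)))
  invisible(x)
}

#' Process a raw acquisition into one spectrum
#'
#' Full preprocessing chain: segment the scan stream by TIC rise, bin each
#' window to unit mass and average it, subtract the background-window mean
#' from each sample-window mean, normalise each corrected spectrum to unit
#' area, and average the replicates. A warning is issued when the number of
#' detected sample windows differs from the expected replicate count.
#'
#' @param raw A `raw_acquisition`.
#' @param bin_range Inclusive integer m/z interval.
#' @param rise_factor,min_window_scans Segmentation parameters, see
#'   [segment_acquisition()].
#' @param expected_windows Expected number of sample windows (default 5).
#' @return A `processed_spectrum`.
#' @export
process_acquisition <- function(raw, bin_range = c(11L, 1000L), rise_factor = 5,
                                min_window_scans = 5L, expected_windows = 5L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bad_arg(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  seg <- stage("segment", segment_acquisition(raw, rise_factor, min_window_scans))
  if (length(seg$samples) == 0L) stop_bad_arg("[segment] no sample windows detected")
  if (length(seg$samples) != expected_windows) {
    warning(sprintf("detected %d sample window(s), expected %d",
                    length(seg$samples), expected_windows), call. = FALSE)
  }
  bg <- stage("background", summarize_window(raw, seg$background, bin_range))
  replicates <- lapply(seg$samples, function(w) {
    sm <- stage("window-average", summarize_window(raw, w, bin_range))
    corrected <- stage("subtract", subtract_background(sm$mean, bg$mean))
    stage("normalize", normalize_unit_area(corrected))
  })
  stage("average", average_replicates(replicates,
                                      sample_id = raw$metadata$sample_id))
}
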