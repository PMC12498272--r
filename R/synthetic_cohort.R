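# Synthetic cohort generation: clinical tables, spectrum matrices with planted
# class effects, and raw scan streams with known window boundaries. Everything
# is a pure function of (configuration, seed) so the downstream pipeline can be
# exercised and tested without any patient data.

#' Simulation configuration
#'
#' Bundles the structural parameters of a synthetic ASAP-MS acquisition
#' campaign: cohort size, the integer m/z bin range, replicate count, scan
#' cadence, window durations, and per-variable missingness fractions.
#'
#' The defaults describe a cohort of 283 patients measured five times each on
#' an instrument that completes a scan every 0.9 s, with spectra binned to the
#' 990 unit-mass bins from m/z 11 to 1000.
#'
#' @param n_patients Number of patients in the cohort.
#' @param bin_range Inclusive integer m/z interval, `c(low, high)`.
#' @param replicates_per_sample Replicate measurements per sample.
#' @param scan_period Scan cadence in seconds.
#' @param background_duration Duration of the leading background window (s).
#' @param sample_duration Duration of each sample-insertion window (s).
#' @param gap_duration Background gap between sample insertions (s).
#' @param missingness Named numeric vector of per-variable missing fractions in
#'   `[0, 1]`; the unnamed entry `.default` applies to variables not listed.
#'   Defaults emulate the skewed missingness pattern of a real registry
#'   (most variables ~6%, smoking history ~30%, imaging-derived MVO ~25%).
#' @param mvo_zero_fraction Zero-inflation probability for the MVO variable.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_patients = 283L,
                       bin_range = c(11L, 1000L),
                       replicates_per_sample = 5L,
                       scan_period = 0.9,
                       background_duration = 30,
                       sample_duration = 25,
                       gap_duration = 10,
                       missingness = NULL,
                       mvo_zero_fraction = 0.5) {
  check_number(n_patients, "n_patients", lower = 1)
  if (length(bin_range) != 2L || any(!is.finite(bin_range)) ||
      bin_range[2] < bin_range[1]) {
    stop_bad_arg("'bin_range' must be an inclusive integer interval c(low, high)")
  }
  bin_range <- as.integer(bin_range)
  check_number(replicates_per_sample, "replicates_per_sample", lower = 1)
  check_number(scan_period, "scan_period", lower = 1e-6)
  check_number(background_duration, "background_duration", lower = 1e-6)
  check_number(sample_duration, "sample_duration", lower = 1e-6)
  check_number(gap_duration, "gap_duration", lower = 1e-6)
  check_number(mvo_zero_fraction, "mvo_zero_fraction", lower = 0, upper = 1)

  default_missing <- c(
    .default = 0.06,
    ex_smoker = 0.30, smoking = 0.07, hfd = 0.20, died = 0.02,
    mvo = 0.25, imr = 0.25, tscore = 0.25, itime = 0.30,
    troponin = 0.15, creatinine = 0.10, bmi = 0.16
  )
  if (!is.null(missingness)) {
    bad <- missingness < 0 | missingness > 1 | !is.finite(missingness)
    if (any(bad)) {
      nm <- names(missingness)[bad]
      if (is.null(nm) || !nzchar(nm[1])) nm <- "<unnamed>"
      stop_bad_arg("invalid missing fraction (outside [0,1]) for variable(s): ",
                   paste(nm, collapse = ", "))
    }
    default_missing[names(missingness)] <- missingness
  }

  structure(list(
    n_patients = as.integer(n_patients),
    bin_range = bin_range,
    n_bins = bin_range[2] - bin_range[1] + 1L,
    replicates_per_sample = as.integer(replicates_per_sample),
    scan_period = scan_period,
    background_duration = background_duration,
    sample_duration = sample_duration,
    gap_duration = gap_duration,
    missingness = default_missing,
    mvo_zero_fraction = mvo_zero_fraction
  ), class = "sim_config")
}

missing_fraction <- function(config, variable) {
  m <- config$missingness
  if (variable %in% names(m)) unname(m[[variable]]) else unname(m[[".default"]])
}

#' Planted class-effect specification
#'
#' Describes how a binary outcome perturbs the synthetic spectra: which
#' unit-mass bins carry the effect, the multiplicative mean-intensity shift
#' applied to class-1 samples at those bins, and the replicate-level noise
#' (multiplicative log-normal with the given coefficient of variance).
#'
#' `biological_cv` adds per-patient, per-bin log-normal variation shared by all
#' replicates of a patient. The instrument-reproducibility statement behind
#' `noise_cv` (replicate CV below 40%) says nothing about inter-patient
#' variance, so the default is 0; raise it to make classification harder.
#'
#' @param effect_peaks Integer m/z bins carrying the class effect.
#' @param effect_size Multiplicative mean shift (> 0) for class-1 samples.
#' @param noise_cv Inter-replicate coefficient of variance, in `[0, 1)`.
#' @param baseline_profile Optional nonnegative mean-intensity vector over the
#'   configured bin range; defaults to [default_baseline_profile()].
#' @param biological_cv Inter-patient coefficient of variance (>= 0).
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(effect_peaks, effect_size, noise_cv,
                        baseline_profile = NULL, biological_cv = 0) {
  check_number(effect_size, "effect_size", lower = 1e-12)
  check_number(noise_cv, "noise_cv", lower = 0, upper = 1 - 1e-12)
  check_number(biological_cv, "biological_cv", lower = 0)
  effect_peaks <- as.integer(effect_peaks)
  if (!is.null(baseline_profile) && any(baseline_profile < 0)) {
    stop_bad_arg("'baseline_profile' must be nonnegative")
  }
  structure(list(effect_peaks = effect_peaks, effect_size = effect_size,
                 noise_cv = noise_cv, baseline_profile = baseline_profile,
                 biological_cv = biological_cv),
            class = "effect_spec")
}

#' Default synthetic baseline spectrum
#'
#' A smooth, strictly positive mean-intensity profile over the configured bin
#' range: a broad log-normal-shaped envelope peaking in the small-molecule
#' region plus a handful of fixed prominent peaks, mimicking the general shape
#' of an ambient-ionisation plasma fingerprint. Deterministic.
#'
#' @param bin_range Inclusive integer m/z interval.
#' @return Named nonnegative numeric vector, one entry per unit-mass bin.
#' @export
default_baseline_profile <- function(bin_range = c(11L, 1000L)) {
  bins <- seq(bin_range[1], bin_range[2])
  envelope <- 1000 * exp(-0.5 * ((log(bins) - log(180)) / 0.9)^2)
  peaks_at <- c(45, 46, 60, 89, 104, 114, 132, 156, 184, 212, 256, 301, 369, 520)
  peaks_at <- peaks_at[peaks_at >= bin_range[1] & peaks_at <= bin_range[2]]
  spikes <- numeric(length(bins))
  for (p in peaks_at) {
    spikes <- spikes + 4000 * exp(-0.5 * ((bins - p) / 1.2)^2)
  }
  out <- envelope + spikes + 5
  names(out) <- bins
  out
}

# Multiplicative log-normal noise factors with unit mean and the requested
# coefficient of variance. cv = 0 returns exact ones.
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic clinical table
#'
#' Draws a per-patient table of demographic and clinical variables with the
#' statistical structure the downstream analysis assumes: continuous variables
#' are right-skewed (log-normal), MVO is zero-inflated, binary variables have
#' realistic prevalences, and each variable is masked missing independently at
#' its configured fraction. Pure function of `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with one row per patient (`patient_id` first).
#' @export
generate_clinical_table <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 2L) stop_bad_arg("need n_patients >= 2")
  n <- config$n_patients

  withr::with_seed(as.integer(seed), {
    height <- rlnorm(n, log(172), 0.05)                 # cm
    weight <- rlnorm(n, log(82), 0.17)                  # kg
    tab <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age        = rlnorm(n, log(62), 0.16),            # years
      weight     = weight,
      height     = height,
      bmi        = weight / (height / 100)^2,
      bsa        = sqrt(weight * height / 3600),        # Mosteller, m^2
      sex        = rbinom(n, 1, 0.82),                  # 1 = male
      smoker     = rbinom(n, 1, 0.40),
      ex_smoker  = rbinom(n, 1, 0.48),
      hypertension = rbinom(n, 1, 0.42),
      diabetes   = rbinom(n, 1, 0.15),
      prev_history = rbinom(n, 1, 0.33),
      died       = rbinom(n, 1, 0.09),
      hfd        = rbinom(n, 1, 0.11),
      imr        = rlnorm(n, log(38), 0.70),
      itime      = rlnorm(n, log(5.5), 0.60),           # hours
      troponin   = rlnorm(n, log(48), 1.00),
      creatinine = rlnorm(n, log(77), 0.25),
      mvo        = ifelse(runif(n) < config$mvo_zero_fraction,
                          0, rlnorm(n, log(2), 1.0)),
      tscore     = sample(0:5, n, replace = TRUE,
                          prob = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.20)),
      stringsAsFactors = FALSE
    )
    tab$smoking <- as.integer(tab$smoker == 1 | tab$ex_smoker == 1)

    for (v in setdiff(names(tab), "patient_id")) {
      frac <- missing_fraction(config, v)
      if (frac > 0) tab[[v]][runif(n) < frac] <- NA
    }
    tab
  })
}

#' Generate a processed spectrum matrix with a planted class effect
#'
#' For each patient, draws `replicates_per_sample` replicate spectra around the
#' baseline profile with multiplicative log-normal noise of coefficient of
#' variance `noise_cv`. Patients in class 1 of the target variable have their
#' mean intensity at each effect peak multiplied by `effect_size`. Replicates
#' are then unit-area normalised and averaged exactly as the preprocessing
#' module does, so the output has the same conventions as a processed cohort.
#'
#' @param clinical Clinical table from [generate_clinical_table()].
#' @param effect An [effect_spec()].
#' @param target_variable Name of the clinical variable that defines classes;
#'   binarized with its default task rule (see [default_tasks()]).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param normalize If `FALSE`, skip the unit-area step and return the mean of
#'   the raw replicate draws (used to inspect pre-normalisation structure).
#'
#' @return Numeric matrix, patients x bins, rownames = patient IDs, colnames =
#'   integer bin labels; attribute `labels` holds the 0/1/NA class labels used.
#' @export
generate_spectrum_matrix <- function(clinical, effect, target_variable, config,
                                     seed, normalize = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "effect_spec"))
  bins <- seq(config$bin_range[1], config$bin_range[2])
  if (!all(effect$effect_peaks %in% bins)) {
    stop_bad_arg("effect_peaks must lie within the configured bin range")
  }
  vals <- clinical[[target_variable]]
  if (is.null(vals)) stop_bad_arg("unknown target variable '", target_variable, "'")
  if (all(is.na(vals))) {
    stop_bad_arg("target variable '", target_variable, "' is entirely missing")
  }
  task <- default_tasks()[[target_variable]]
  if (is.null(task)) task <- task_spec(target_variable, rule = "binary")
  labels <- binarize_variable(vals, task)$labels

  baseline <- effect$baseline_profile %||% default_baseline_profile(config$bin_range)
  if (length(baseline) != length(bins)) {
    stop_bad_arg("baseline_profile length must equal the bin count (",
                 length(bins), ")")
  }

  n <- nrow(clinical)
  nb <- length(bins)
  reps <- config$replicates_per_sample
  peak_idx <- match(effect$effect_peaks, bins)

  out <- withr::with_seed(as.integer(seed), {
    mat <- matrix(0, n, nb, dimnames = list(clinical$patient_id, bins))
    for (i in seq_len(n)) {
      mu <- baseline * lognormal_factors(nb, effect$biological_cv)
      if (!is.na(labels[i]) && labels[i] == 1L) {
        mu[peak_idx] <- mu[peak_idx] * effect$effect_size
      }
      reps_mat <- matrix(0, reps, nb)
      for (r in seq_len(reps)) {
        reps_mat[r, ] <- mu * lognormal_factors(nb, effect$noise_cv)
      }
      if (normalize) {
        reps_mat <- reps_mat / rowSums(reps_mat)
      }
      mat[i, ] <- colMeans(reps_mat)
    }
    mat
  })
  attr(out, "labels") <- labels
  out
}

#' Simulate a raw ASAP-MS acquisition from a known spectrum
#'
#' Emits a time-ordered scan stream at the configured cadence: one leading
#' background window, then five sample-insertion windows separated by
#' background gaps. Sample-window scans carry the supplied spectrum (scaled so
#' the total ion count rises well above the background median) on top of a low
#' flat instrument background. Ground-truth window boundaries are returned in
#' the object's `truth` element so segmentation is testable without manual
#' annotation.
#'
#' @param sample_spectrum Nonnegative intensity vector over the configured bin
#'   range (named by integer bin, or unnamed and assumed to cover it).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_sample_windows Number of sample-insertion windows (default 5).
#' @param rise_amplitude Ratio of sample-window TIC to background TIC
#'   (default 10; must comfortably exceed the segmentation rise factor).
#' @param noise_cv Per-scan multiplicative intensity noise CV (default 0).
#' @param sample_id Metadata label.
#'
#' @return An object of class `raw_acquisition`: list with `times`, `scans`
#'   (each a list with `mz`, `intensity`), `metadata`, and `truth` (half-open
#'   1-based scan-index intervals for the background and sample windows).
#' @export
simulate_raw_acquisition <- function(sample_spectrum, config, seed,
                                     n_sample_windows = 5L,
                                     rise_amplitude = 10,
                                     noise_cv = 0,
                                     sample_id = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  if (any(sample_spectrum < 0) || any(!is.finite(sample_spectrum))) {
    stop_bad_arg("'sample_spectrum' must be finite and nonnegative")
  }
  p <- config$scan_period
  if (config$background_duration < p || config$sample_duration < p ||
      config$gap_duration < p) {
    stop_bad_arg("window durations must be at least one scan period")
  }
  bins <- seq(config$bin_range[1], config$bin_range[2])
  if (length(sample_spectrum) != length(bins)) {
    stop_bad_arg("'sample_spectrum' must have one entry per bin in bin_range")
  }

  n_bg <- as.integer(floor(config$background_duration / p))
  n_samp <- as.integer(floor(config$sample_duration / p))
  n_gap <- as.integer(floor(config$gap_duration / p))

  # Flat instrument background carrying ~1/rise_amplitude of the sample TIC.
  total <- sum(sample_spectrum)
  if (total <= 0) stop_bad_arg("'sample_spectrum' must have positive total intensity")
  bg_level <- total / length(bins) / rise_amplitude
  bg_profile <- rep(bg_level, length(bins))

  # Build the scan-type sequence: background, then (gap, sample) x windows.
  types <- c(rep("bg", n_bg),
             rep(rep(c("gap", "sample"), n_sample_windows),
                 times = rep(c(n_gap, n_samp), n_sample_windows)))
  n_scans <- length(types)

  truth <- list(background = c(1L, n_bg + 1L), samples = vector("list", n_sample_windows))
  pos <- n_bg
  for (w in seq_len(n_sample_windows)) {
    pos <- pos + n_gap
    truth$samples[[w]] <- c(pos + 1L, pos + n_samp + 1L)
    pos <- pos + n_samp
  }

  scans <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_scans), function(i) {
      base <- if (types[i] == "sample") bg_profile + sample_spectrum else bg_profile
      list(mz = as.numeric(bins),
           intensity = base * lognormal_factors(length(bins), noise_cv))
    })
  })

  structure(list(
    times = (seq_len(n_scans) - 1) * p,
    scans = scans,
    metadata = list(sample_id = sample_id, instrument_mode = "synthetic",
                    scan_period = p),
    truth = truth
  ), class = "raw_acquisition")
}

#' @export
print.raw_acquisition <- function(x, ...) {
  cat(sprintf("<raw_acquisition> %d scans over %.1f s (sample '%s')\n",
              length(x$scans), max(x$times), x$metadata$sample_id %||% "?"))
  invisible(x)
}
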