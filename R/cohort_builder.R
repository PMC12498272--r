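# Cohort construction: binary task definitions over clinical variables,
# balanced undersampling, extreme-patient subsets, and demographic
# augmentation of spectrum matrices.

#' Binary classification task specification
#'
#' Defines how a clinical variable is turned into 0/1 class labels
#' ('Low'/'High'):
#' * `"binary"` — the variable is already 0/1 (no/yes);
#' * `"threshold"` — values strictly below the threshold are class 0, strictly
#'   above are class 1, and values exactly at the threshold go to
#'   `boundary_class` (counted in the boundary report unless the boundary is
#'   part of the published rule, `boundary_explicit = TRUE`);
#' * `"range"` — integer scores inside `range_low` are class 0, inside
#'   `range_high` class 1, anything else (e.g. a thrombus score of 0) is
#'   treated as missing and counted.
#'
#' @param variable Clinical variable name.
#' @param rule One of `"binary"`, `"threshold"`, `"range"`.
#' @param threshold Threshold value for `rule = "threshold"`.
#' @param range_low,range_high Inclusive integer intervals for `rule = "range"`.
#' @param boundary_class Class for values exactly at the threshold (default 0).
#' @param boundary_explicit Whether the boundary assignment is part of the
#'   published rule (e.g. MVO = 0 defines class 0) rather than a tie-break.
#' @return Object of class `task_spec`.
#' @export
task_spec <- function(variable, rule = c("binary", "threshold", "range"),
                      threshold = NULL, range_low = NULL, range_high = NULL,
                      boundary_class = 0L, boundary_explicit = FALSE) {
  rule <- match.arg(rule)
  if (rule == "threshold") check_number(threshold, "threshold")
  if (rule == "range" && (is.null(range_low) || is.null(range_high))) {
    stop_bad_arg("'range' rule needs both range_low and range_high")
  }
  structure(list(variable = variable, rule = rule, threshold = threshold,
                 range_low = range_low, range_high = range_high,
                 boundary_class = as.integer(boundary_class),
                 boundary_explicit = isTRUE(boundary_explicit),
                 labels = c("Low", "High")),
            class = "task_spec")
}

#' Default binary classification tasks
#'
#' The eight outcome tasks used throughout the pipeline: mortality and heart
#' failure diagnosis (already binary); MVO (zero versus non-zero); IMR
#' (threshold 40), ischemic time (6 h), peak troponin (50), creatinine on
#' admission (75); and thrombus score (grades 1-3 versus 4-5, grade 0 treated
#' as missing). The continuous tasks admit extreme-patient dataset variants;
#' mortality and HFD do not.
#'
#' @return Named list of [task_spec()] objects.
#' @export
default_tasks <- function() {
  list(
    died       = task_spec("died", "binary"),
    hfd        = task_spec("hfd", "binary"),
    mvo        = task_spec("mvo", "threshold", threshold = 0,
                           boundary_class = 0L, boundary_explicit = TRUE),
    imr        = task_spec("imr", "threshold", threshold = 40),
    tscore     = task_spec("tscore", "range", range_low = c(1L, 3L),
                           range_high = c(4L, 5L)),
    itime      = task_spec("itime", "threshold", threshold = 6),
    troponin   = task_spec("troponin", "threshold", threshold = 50),
    creatinine = task_spec("creatinine", "threshold", threshold = 75)
  )
}

# Tasks for which extreme-patient variants exist (continuous variables only).
extreme_eligible_tasks <- function() {
  c("mvo", "imr", "tscore", "itime", "troponin", "creatinine")
}

#' Binarize a clinical variable under a task rule
#'
#' @param values Vector of clinical values (may contain `NA`).
#' @param spec A [task_spec()].
#' @return List with `labels` (integer 0/1/`NA`), `n_boundary` (values exactly
#'   at an ambiguous threshold, 0 when the boundary is explicit in the rule)
#'   and `n_unassigned` (range-rule values outside both ranges).
#' @export
binarize_variable <- function(values, spec) {
  stopifnot(inherits(spec, "task_spec"))
  labels <- rep(NA_integer_, length(values))
  n_boundary <- 0L
  n_unassigned <- 0L
  ok <- !is.na(values)
  v <- values[ok]
  lab <- switch(spec$rule,
    binary = {
      if (!all(v %in% c(0, 1))) {
        stop_bad_arg("binary rule for '", spec$variable,
                     "' requires 0/1 values")
      }
      as.integer(v)
    },
    threshold = {
      out <- ifelse(v > spec$threshold, 1L, 0L)
      at <- v == spec$threshold
      out[at] <- spec$boundary_class
      if (!spec$boundary_explicit) n_boundary <- sum(at)
      out
    },
    range = {
      out <- rep(NA_integer_, length(v))
      out[v >= spec$range_low[1] & v <= spec$range_low[2]] <- 0L
      out[v >= spec$range_high[1] & v <= spec$range_high[2]] <- 1L
      n_unassigned <- sum(is.na(out))
      out
    }
  )
  labels[ok] <- lab
  list(labels = labels, n_boundary = n_boundary, n_unassigned = n_unassigned)
}

#' Balanced subset by majority-class undersampling
#'
#' Retains every minority-class sample and randomly undersamples the majority
#' class (without replacement) to the minority count, so that classifiers are
#' forced to use spectral features rather than class prevalence. Samples with
#' missing labels are excluded first. Deterministic per seed.
#'
#' @param labels Integer 0/1 labels (`NA` allowed, excluded).
#' @param seed Integer seed.
#' @return Sorted integer indices into `labels`.
#' @export
balanced_subset <- function(labels, seed) {
  idx0 <- which(!is.na(labels) & labels == 0L)
  idx1 <- which(!is.na(labels) & labels == 1L)
  if (length(idx0) == 0L || length(idx1) == 0L) {
    stop_bad_arg("both classes must be non-empty for balancing")
  }
  n <- min(length(idx0), length(idx1))
  withr::with_seed(as.integer(seed), {
    keep0 <- if (length(idx0) > n) sort(sample(idx0, n)) else idx0
    keep1 <- if (length(idx1) > n) sort(sample(idx1, n)) else idx1
    sort(c(keep0, keep1))
  })
}

#' Extreme-patient subset: lowest and highest tails of a continuous variable
#'
#' Selects the indices of the `n_per_tail` smallest and `n_per_tail` largest
#' non-missing values. Ties at either cut are broken deterministically by
#' sample-ID order; the two tails are always disjoint.
#'
#' @param values Continuous clinical values (`NA` allowed, excluded).
#' @param n_per_tail Tail size (20 and 30 are the conventional pilot sizes).
#' @param ids Secondary sort key (default: index order).
#' @return List with `low` and `high`, each sorted integer index vectors of
#'   length `n_per_tail`.
#' @export
extreme_subset <- function(values, n_per_tail, ids = seq_along(values)) {
  ok <- which(!is.na(values))
  if (length(ok) < 2L * n_per_tail) {
    stop_bad_arg("need at least 2 * n_per_tail non-missing values ",
                 "(have ", length(ok), ", need ", 2L * n_per_tail, ")")
  }
  ord <- ok[order(values[ok], ids[ok])]
  low <- sort(ord[seq_len(n_per_tail)])
  high <- sort(ord[seq.int(length(ord) - n_per_tail + 1L, length(ord))])
  list(low = low, high = high)
}

default_demographic_params <- function() {
  c("age", "weight", "height", "bmi", "bsa",
    "smoking", "hypertension", "diabetes", "prev_history")
}

demographic_binary_params <- function() {
  c("smoking", "hypertension", "diabetes", "prev_history", "smoker",
    "ex_smoker")
}

#' Append rescaled demographic parameters to a spectrum matrix
#'
#' Continuous parameters are linearly rescaled from their observed
#' `[min, max]` onto `[0, m]`, and binary parameters mapped to `{0, m}`, where
#' `m` is the median of all positive entries of the spectrum rows used for
#' fitting — so that demographic columns cannot dominate distance-based
#' learners. When `train_idx` is supplied, `m` and the min/max ranges are
#' computed from those rows only (and applied to all rows), which keeps
#' repeated-holdout evaluation leakage-free. Patients with any missing listed
#' parameter are dropped and counted. Requesting `sex` raises a warning and
#' the parameter is skipped.
#'
#' @param mat Spectrum matrix (samples x bins, rownames = patient IDs).
#' @param clinical Clinical table aligned with `mat` rows.
#' @param params Parameter names to append (default: the nine standard ones).
#' @param train_idx Optional row indices (into the *retained* rows) used to fit
#'   the rescaling; default all retained rows.
#' @return List with `matrix` (augmented, demographic columns named
#'   `demog_<param>`), `kept` (row indices of `mat` retained), `n_dropped`,
#'   and `m` (the rescaling ceiling).
#' @export
append_demographics <- function(mat, clinical, params = default_demographic_params(),
                                train_idx = NULL) {
  if (length(params) == 0L) {
    return(list(matrix = mat, kept = seq_len(nrow(mat)), n_dropped = 0L, m = NA_real_))
  }
  if ("sex" %in% params) {
    warning("patient sex is excluded from demographic augmentation; skipping it",
            call. = FALSE)
    params <- setdiff(params, "sex")
  }
  missing_params <- setdiff(params, names(clinical))
  if (length(missing_params)) {
    stop_bad_arg("clinical table lacks parameter(s): ",
                 paste(missing_params, collapse = ", "))
  }
  dem <- clinical[, params, drop = FALSE]
  keep <- which(complete.cases(dem))
  n_dropped <- nrow(mat) - length(keep)
  mat <- mat[keep, , drop = FALSE]
  dem <- dem[keep, , drop = FALSE]
  if (is.null(train_idx)) train_idx <- seq_len(nrow(mat))

  pos <- mat[train_idx, , drop = FALSE]
  pos <- pos[pos > 0]
  if (length(pos) == 0L) stop_bad_arg("spectrum matrix has no positive entries")
  m <- median(pos)

  aug <- matrix(0, nrow(mat), length(params),
                dimnames = list(rownames(mat), paste0("demog_", params)))
  for (j in seq_along(params)) {
    p <- params[j]
    x <- as.numeric(dem[[p]])
    if (p %in% demographic_binary_params() || all(x[train_idx] %in% c(0, 1))) {
      aug[, j] <- ifelse(x > 0, m, 0)
    } else {
      lo <- min(x[train_idx]); hi <- max(x[train_idx])
      if (hi == lo) {
        aug[, j] <- 0
      } else {
        aug[, j] <- (x - lo) / (hi - lo) * m
      }
    }
  }
  list(matrix = cbind(mat, aug), kept = keep, n_dropped = n_dropped, m = m)
}

#' Labeled dataset container
#'
#' Aligns a (possibly augmented) feature matrix with 0/1 labels and sample
#' IDs, plus a provenance record of how the dataset was built.
#'
#' @param x Feature matrix, samples x features.
#' @param labels Integer 0/1 labels, one per row.
#' @param ids Sample IDs (default rownames).
#' @param provenance Named list (task, subset type, demographics flag, ...).
#' @param demographics Optional raw demographic `data.frame` aligned with the
#'   rows, used for per-partition rescaling during evaluation.
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, labels, ids = rownames(x), provenance = list(),
                            demographics = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop_bad_arg("rows of 'x' and 'labels' must align")
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop_bad_arg("'labels' must be 0/1 with no missing values")
  }
  if (!is.null(demographics) && nrow(demographics) != nrow(x)) {
    stop_bad_arg("'demographics' must align with the rows of 'x'")
  }
  structure(list(x = x, labels = as.integer(labels),
                 ids = ids %||% as.character(seq_len(nrow(x))),
                 provenance = provenance, demographics = demographics),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%d / %d per class)%s\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 0L), sum(x$labels == 1L),
              if (!is.null(x$demographics)) ", with demographics" else ""))
  invisible(x)
}

#' Build a labeled dataset for a task from a spectrum matrix
#'
#' Applies the task rule, drops samples with missing labels, and constructs
#' either the balanced all-patients dataset or an extreme-patients dataset
#' (tails of the continuous variable, labelled low = 0 / high = 1, balanced by
#' construction). With `demographics = TRUE`, patients missing any of the nine
#' standard demographic parameters are dropped before balancing and the raw
#' parameters are carried in the dataset for per-partition rescaling.
#'
#' @param spectra Spectrum matrix, rows aligned with `clinical`.
#' @param clinical Clinical table.
#' @param task A [task_spec()] or the name of a default task.
#' @param variant `"all"`, `"extreme20"` or `"extreme30"`.
#' @param seed Seed for the balancing undersample.
#' @param demographics Logical; append demographic parameters.
#' @return A [labeled_dataset()].
#' @export
build_dataset <- function(spectra, clinical, task, variant = "all", seed = 1L,
                          demographics = FALSE) {
  if (is.character(task)) {
    task <- default_tasks()[[task]] %||%
      stop_bad_arg("unknown task '", task, "'")
  }
  stopifnot(inherits(task, "task_spec"))
  if (nrow(spectra) != nrow(clinical)) {
    stop_bad_arg("'spectra' and 'clinical' must have aligned rows")
  }
  if (variant != "all" && !(task$variable %in% extreme_eligible_tasks())) {
    stop_bad_arg("task '", task$variable,
                 "' has no extreme-patient variant (categorical outcome)")
  }

  keep <- seq_len(nrow(spectra))
  dem <- NULL
  if (demographics) {
    params <- default_demographic_params()
    missing_params <- setdiff(params, names(clinical))
    if (length(missing_params)) {
      stop_bad_arg("clinical table lacks parameter(s): ",
                   paste(missing_params, collapse = ", "))
    }
    ok <- complete.cases(clinical[, params, drop = FALSE])
    keep <- keep[ok]
  }
  spectra <- spectra[keep, , drop = FALSE]
  clinical <- clinical[keep, , drop = FALSE]

  if (variant == "all") {
    bin <- binarize_variable(clinical[[task$variable]], task)
    idx <- balanced_subset(bin$labels, seed)
    labels <- bin$labels[idx]
  } else if (variant %in% c("extreme20", "extreme30")) {
    n_tail <- if (variant == "extreme20") 20L else 30L
    if (task$rule == "binary") {
      stop_bad_arg("extreme variants are undefined for binary tasks")
    }
    tails <- extreme_subset(clinical[[task$variable]], n_tail,
                            ids = clinical$patient_id)
    idx <- c(tails$low, tails$high)
    labels <- rep(c(0L, 1L), each = n_tail)
  } else {
    stop_bad_arg("unknown variant '", variant, "'")
  }

  if (demographics) {
    dem <- clinical[idx, default_demographic_params(), drop = FALSE]
  }
  labeled_dataset(spectra[idx, , drop = FALSE], labels,
                  ids = clinical$patient_id[idx],
                  provenance = list(task = task$variable, variant = variant,
                                    demographics = demographics, seed = seed),
                  demographics = dem)
}
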