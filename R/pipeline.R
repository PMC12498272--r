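# Grid orchestration: run every task x dataset-variant x feature-method x
# model x demographics combination, export tidy result tables, per-task
# consensus reports, and group-wise intensity summaries for plotting.

#' Grid configuration
#'
#' @param tasks Character vector of task names (see [default_tasks()]).
#' @param variants Dataset variants for continuous tasks; categorical outcome
#'   tasks (mortality, HFD) only ever run the `"all"` variant, and requesting
#'   an extreme variant for them is a validation error.
#' @param feature_methods Feature-reduction methods to run.
#' @param models Classifier names.
#' @param demographics Logical vector of demographic-augmentation settings.
#' @param n_repeats Partitions per grid cell (default 200).
#' @param base_seed Base seed.
#' @param k,alpha Feature-selection parameters.
#' @param out_dir Optional directory for per-cell result caching; completed
#'   cells found on disk are skipped unless `force = TRUE` in [run_grid()].
#' @return Object of class `grid_config`.
#' @export
grid_config <- function(tasks = names(default_tasks()),
                        variants = c("all", "extreme20", "extreme30"),
                        feature_methods = c("none", "pearson", "overlap", "chi2"),
                        models = c("knn", "svm", "lda", "nbc", "rfc"),
                        demographics = c(FALSE, TRUE),
                        n_repeats = 200L, base_seed = 1L,
                        k = 40L, alpha = 0.05, out_dir = NULL) {
  unknown <- setdiff(tasks, names(default_tasks()))
  if (length(unknown)) stop_bad_arg("unknown task(s): ", paste(unknown, collapse = ", "))
  bad_variants <- setdiff(variants, c("all", "extreme20", "extreme30"))
  if (length(bad_variants)) {
    stop_bad_arg("unknown variant(s): ", paste(bad_variants, collapse = ", "))
  }
  structure(list(tasks = tasks, variants = variants,
                 feature_methods = feature_methods, models = models,
                 demographics = demographics, n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed), k = as.integer(k),
                 alpha = alpha, out_dir = out_dir),
            class = "grid_config")
}

# Variants actually valid for a task: extreme sets exist only for continuous
# variables.
valid_variants <- function(task, variants) {
  if (task %in% extreme_eligible_tasks()) variants
  else intersect(variants, "all")
}

#' Validate explicit task/variant requests
#'
#' @param tasks,variants Vectors of equal length describing requested cells.
#' @return Invisibly `TRUE`; errors when an extreme variant is requested for a
#'   categorical outcome task.
#' @export
validate_grid_request <- function(tasks, variants) {
  bad <- variants != "all" & !(tasks %in% extreme_eligible_tasks())
  if (any(bad)) {
    stop_bad_arg("extreme-patient variants are not defined for task(s): ",
                 paste(unique(tasks[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

cell_id <- function(task, variant, method, model, demog) {
  sprintf("%s_%s_%s_%s_%s", task, variant, method, model,
          if (demog) "demog" else "nodem")
}

summary_row <- function(s, task, variant, demog) {
  data.frame(task = task, variant = variant, feature_method = s$feature_method,
             model = s$model, demographics = demog,
             mean_kappa = s$mean_kappa, sd_kappa = s$sd_kappa,
             mean_accuracy = s$mean_accuracy, sd_accuracy = s$sd_accuracy,
             n_valid_partitions = s$n_valid, n_failed = s$n_failed,
             significant = s$significant, agreement = s$agreement,
             stringsAsFactors = FALSE)
}

#' Run the full analysis grid
#'
#' Executes every valid grid cell through [run_evaluation()], skipping extreme
#' variants for categorical outcome tasks, and returns a tidy results table,
#' a best-per-task table (the highest mean kappa and the setup achieving it),
#' and a per-task/variant consensus report built from the three
#' feature-reduction methods. When `config$out_dir` is set, each completed
#' cell is written to `<out_dir>/cell_<id>.csv` and re-runs skip cells already
#' on disk (`force = TRUE` recomputes).
#'
#' @param config A [grid_config()].
#' @param clinical Clinical table.
#' @param spectra Spectrum matrix aligned with `clinical` rows.
#' @param force Recompute cached cells.
#' @param consensus Also compute per-task consensus reports (default TRUE).
#' @return Object of class `grid_result`: list with `results` (tidy
#'   `data.frame`), `best_per_task`, `consensus` (named list of
#'   `consensus_report`), and `failures`.
#' @export
run_grid <- function(config, clinical, spectra, force = FALSE, consensus = TRUE) {
  stopifnot(inherits(config, "grid_config"))
  if (nrow(spectra) != nrow(clinical)) {
    stop_bad_arg("'spectra' and 'clinical' must have aligned rows")
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  rows <- list()
  failures <- list()
  consensus_reports <- list()

  for (task in config$tasks) {
    for (variant in valid_variants(task, config$variants)) {
      for (demog in config$demographics) {
        ds <- tryCatch(
          build_dataset(spectra, clinical, task, variant,
                        seed = config$base_seed, demographics = demog),
          error = function(e) e)
        if (inherits(ds, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            task = task, variant = variant, demographics = demog,
            model = NA_character_, feature_method = NA_character_,
            reason = conditionMessage(ds), stringsAsFactors = FALSE)
          next
        }
        for (method in config$feature_methods) {
          for (model in config$models) {
            id <- cell_id(task, variant, method, model, demog)
            cache <- if (!is.null(out_dir)) file.path(out_dir, paste0("cell_", id, ".csv"))
            if (!is.null(out_dir) && !force && file.exists(cache)) {
              rows[[id]] <- read.csv(cache, stringsAsFactors = FALSE)
              next
            }
            res <- tryCatch(
              run_evaluation(ds, model = model, feature_method = method,
                             n_repeats = config$n_repeats,
                             base_seed = config$base_seed, k = config$k,
                             alpha = config$alpha, keep_partitions = FALSE),
              error = function(e) e)
            if (inherits(res, "error")) {
              failures[[length(failures) + 1L]] <- data.frame(
                task = task, variant = variant, demographics = demog,
                model = model, feature_method = method,
                reason = conditionMessage(res), stringsAsFactors = FALSE)
              next
            }
            row <- summary_row(res, task, variant, demog)
            rows[[id]] <- row
            if (!is.null(out_dir)) write.csv(row, cache, row.names = FALSE)
          }
        }
      }
      if (consensus) {
        key <- paste(task, variant, sep = "_")
        if (is.null(consensus_reports[[key]])) {
          ds <- tryCatch(
            build_dataset(spectra, clinical, task, variant,
                          seed = config$base_seed, demographics = FALSE),
            error = function(e) NULL)
          if (!is.null(ds)) {
            consensus_reports[[key]] <- consensus_for_dataset(
              ds, n_repeats = config$n_repeats, base_seed = config$base_seed,
              k = config$k, alpha = config$alpha)
          }
        }
      }
    }
  }

  results <- do.call(rbind, unname(rows))
  best <- NULL
  if (!is.null(results) && nrow(results)) {
    best <- do.call(rbind, lapply(split(results, results$task), function(d) {
      d[which.max(d$mean_kappa), , drop = FALSE]
    }))
    rownames(best) <- NULL
  }
  structure(list(results = results, best_per_task = best,
                 consensus = consensus_reports,
                 failures = if (length(failures)) do.call(rbind, failures) else NULL),
            class = "grid_result")
}

#' Consensus report for one dataset over repeated partitions
#'
#' Draws `n_repeats` stratified 80:20 partitions and, within each training
#' split, runs all three feature-reduction methods; the per-method selection
#' frequencies feed the strict >75%-of-partitions consensus criterion.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_repeats Partitions (default 200).
#' @param base_seed Base seed.
#' @param k,alpha Selection parameters.
#' @param fraction Consensus threshold.
#' @return A `consensus_report`.
#' @export
consensus_for_dataset <- function(dataset, n_repeats = 200L, base_seed = 1L,
                                  k = 40L, alpha = 0.05, fraction = 0.75) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$labels
  selections <- vector("list", 3L * n_repeats)
  pos <- 0L
  for (i in seq_len(n_repeats)) {
    part <- stratified_partition(y, seed = derive_seed(base_seed, i))
    xt <- dataset$x[part$train, , drop = FALSE]
    yt <- y[part$train]
    for (method in c("pearson", "overlap", "chi2")) {
      pos <- pos + 1L
      selections[[pos]] <- select_features(xt, yt, method, k = k,
                                           alpha = alpha, partition = i)
    }
  }
  consensus_features(selections, fraction = fraction)
}

#' Group-wise intensity summaries for consensus peaks
#'
#' For every consensus bin and class, computes box-and-whisker statistics of
#' the normalised intensities: median, first and third quartiles (linear
#' interpolation), whisker ends at the farthest data point within 1.5 x IQR of
#' the box, and outliers beyond the whiskers; plus an independent two-sample
#' t-test (equal variances) between the classes per bin. Classes with fewer
#' than two samples are summarised without the t-test and flagged.
#'
#' @param consensus A `consensus_report` (non-empty).
#' @param dataset A [labeled_dataset()] whose columns include the consensus
#'   bins.
#' @return `data.frame`, one row per bin x class, with summary columns plus
#'   `t_statistic` and `p_value` (repeated across the bin's rows).
#' @export
export_group_distributions <- function(consensus, dataset) {
  stopifnot(inherits(consensus, "consensus_report"),
            inherits(dataset, "labeled_dataset"))
  bins <- consensus$consensus
  if (length(bins) == 0L) stop_bad_arg("consensus set is empty")
  missing_bins <- setdiff(bins, colnames(dataset$x))
  if (length(missing_bins)) {
    stop_bad_arg("dataset lacks consensus bin(s): ",
                 paste(missing_bins, collapse = ", "))
  }
  out <- list()
  for (b in bins) {
    v <- dataset$x[, b]
    groups <- split(v, dataset$labels)
    can_test <- all(vapply(groups, length, integer(1)) >= 2L)
    tt <- if (can_test) t.test(groups[["0"]], groups[["1"]], var.equal = TRUE)
    for (cls in names(groups)) {
      g <- groups[[cls]]
      q <- quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      inside <- g[g >= lo_fence & g <= hi_fence]
      outliers <- g[g < lo_fence | g > hi_fence]
      out[[length(out) + 1L]] <- data.frame(
        bin = b, class = as.integer(cls), n = length(g),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(inside), whisker_high = max(inside),
        n_outliers = length(outliers),
        outliers = paste(signif(outliers, 6), collapse = ";"),
        t_statistic = if (can_test) unname(tt$statistic) else NA_real_,
        p_value = if (can_test) tt$p.value else NA_real_,
        t_test_flagged = !can_test,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read a grid configuration from a YAML file
#'
#' Supported sections: `grid` (tasks, variants, feature_methods, models,
#' demographics, n_repeats, base_seed, k, alpha, out_dir). Unset fields take
#' the [grid_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `grid_config`.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$grid %||% cfg
  grid_config(
    tasks = g$tasks %||% names(default_tasks()),
    variants = g$variants %||% c("all", "extreme20", "extreme30"),
    feature_methods = g$feature_methods %||% c("none", "pearson", "overlap", "chi2"),
    models = g$models %||% c("knn", "svm", "lda", "nbc", "rfc"),
    demographics = as.logical(g$demographics %||% c(FALSE, TRUE)),
    n_repeats = g$n_repeats %||% 200L,
    base_seed = g$base_seed %||% 1L,
    k = g$k %||% 40L,
    alpha = g$alpha %||% 0.05,
    out_dir = g$out_dir
  )
}
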