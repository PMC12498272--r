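# Repeated stratified 80:20 holdout evaluation of the five classifier
# families, scored by percentage accuracy and Cohen's kappa, with the
# small-sample kappa significance rule and agreement-band interpretation.

#' Confusion counts
#'
#' @param truth,pred Binary 0/1 vectors (class 1 is "positive").
#' @return Object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop_bad_arg("length mismatch")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1)) {
    stop_bad_arg("classes must be 0/1")
  }
  structure(list(TP = sum(truth == 1L & pred == 1L),
                 TN = sum(truth == 0L & pred == 0L),
                 FP = sum(truth == 0L & pred == 1L),
                 FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

conf_total <- function(conf) conf$TP + conf$TN + conf$FP + conf$FN

#' Percentage accuracy from confusion counts
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param conf A [confusion_counts()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  n <- conf_total(conf)
  if (n == 0L) stop_bad_arg("empty confusion table")
  100 * (conf$TP + conf$TN) / n
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement: observed agreement `p_o = (TP + TN) / N`,
#' expected agreement from the marginals
#' `p_e = ((TP + FP)(TP + FN) + (FN + TN)(FP + TN)) / N^2`, and
#' `kappa = (p_o - p_e) / (1 - p_e)`, ranging over `[-1, 1]`. When both
#' marginals are degenerate (`p_e = 1`) kappa is undefined and `NA` is
#' returned; callers exclude such partitions from means with a count.
#'
#' @param conf A [confusion_counts()].
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  n <- conf_total(conf)
  if (n == 0L) stop_bad_arg("empty confusion table")
  p_o <- (conf$TP + conf$TN) / n
  p_e <- ((conf$TP + conf$FP) * (conf$TP + conf$FN) +
          (conf$FN + conf$TN) * (conf$FP + conf$TN)) / n^2
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Sample-size-dependent kappa significance threshold
#'
#' For small balanced datasets the kappa value needed for statistical
#' significance (p < 0.05) is higher: datasets of 50 or fewer samples (the
#' n = 20-per-class extreme sets and mortality/heart-failure-scale cohorts)
#' require kappa >= 0.6, datasets of up to 60 samples (n = 30 per class)
#' require kappa >= 0.5, and larger datasets use `default_threshold`.
#'
#' @param n_total Total dataset size (>= 4).
#' @param default_threshold Threshold for larger datasets (default 0, i.e.
#'   always report).
#' @return The kappa threshold.
#' @export
kappa_significance_threshold <- function(n_total, default_threshold = 0) {
  check_number(n_total, "n_total", lower = 4)
  if (n_total <= 50) return(0.6)
  if (n_total <= 60) return(0.5)
  default_threshold
}

#' Interpret a kappa value as a level of agreement
#'
#' Bands: below 0.2 "None", 0.2-0.4 "Weak", 0.4-0.6 "Fair", 0.6-0.8
#' "Moderate", 0.8-0.9 "Strong", above 0.9 "Very strong". Values exactly on a
#' shared boundary are assigned to the lower band.
#'
#' @param kappa Kappa in `[-1, 1]`.
#' @return Agreement label.
#' @export
interpret_kappa <- function(kappa) {
  check_number(kappa, "kappa", lower = -1, upper = 1)
  if (kappa < 0.2) "None"
  else if (kappa <= 0.4) "Weak"
  else if (kappa <= 0.6) "Fair"
  else if (kappa <= 0.8) "Moderate"
  else if (kappa <= 0.9) "Strong"
  else "Very strong"
}

#' Stratified train/test partition
#'
#' Within each class, `floor(ratio * n_class)` samples go to training and the
#' remainder to test; the split is a pure function of `(labels, ratio, seed)`.
#'
#' @param labels Binary 0/1 labels (at least 5 per class).
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with sorted `train` and `test` index vectors (disjoint,
#'   covering).
#' @export
stratified_partition <- function(labels, ratio = 0.8, seed = 1L) {
  check_number(ratio, "ratio", lower = 1e-9, upper = 1 - 1e-9)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop_bad_arg("'labels' must be 0/1 with no missing values")
  }
  train <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      if (length(idx) < 5L) {
        stop_bad_arg("class ", cls, " has fewer than 5 samples")
      }
      n_train <- floor(ratio * length(idx))
      if (n_train >= length(idx)) {
        stop_bad_arg("class ", cls, " would have an empty test set")
      }
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  list(train = train, test = sort(setdiff(seq_along(labels), train)))
}

#' Classifier registry
#'
#' The five classifier families used in the evaluation, each a pair of
#' `fit(x, y)` / `predict(fit, x)` closures with fixed hyperparameters:
#' k-nearest neighbours (k = 5, Euclidean), RBF support vector machine
#' (cost 1), linear discriminant analysis, Gaussian naive Bayes, and a random
#' forest with 100 trees. Hyperparameters can be overridden via `...`.
#'
#' @param knn_k Neighbours for KNN.
#' @param svm_cost Cost parameter for the RBF SVM.
#' @param rf_trees Trees in the random forest.
#' @return Named list of model entries (`knn`, `svm`, `lda`, `nbc`, `rfc`).
#' @export
default_classifiers <- function(knn_k = 5L, svm_cost = 1, rf_trees = 100L) {
  list(
    knn = list(
      fit = function(x, y) list(x = x, y = factor(y, levels = c(0L, 1L)), k = knn_k),
      predict = function(fit, x) {
        as.integer(as.character(class::knn(fit$x, x, fit$y, k = fit$k)))
      }
    ),
    svm = list(
      fit = function(x, y) {
        suppressWarnings(e1071::svm(x, factor(y, levels = c(0L, 1L)),
                                    kernel = "radial", cost = svm_cost,
                                    scale = FALSE))
      },
      predict = function(fit, x) as.integer(as.character(predict(fit, x)))
    ),
    lda = list(
      fit = function(x, y) suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0L, 1L)))),
      predict = function(fit, x) {
        as.integer(as.character(predict(fit, x)$class))
      }
    ),
    nbc = list(
      fit = function(x, y) e1071::naiveBayes(x, factor(y, levels = c(0L, 1L))),
      predict = function(fit, x) as.integer(as.character(predict(fit, x)))
    ),
    rfc = list(
      fit = function(x, y) {
        randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                   ntree = rf_trees)
      },
      predict = function(fit, x) as.integer(as.character(predict(fit, x)))
    )
  )
}

# Feature matrices carry tiny unit-area intensities; distance- and
# variance-sensitive learners work on a standardised copy whose scaling is fit
# on the training rows only.
standardize_train_test <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sdv, "/"))
}

select_features <- function(x, y, method, k = 40L, alpha = 0.05,
                            partition = NA_integer_) {
  switch(method,
    none = new_feature_selection("none", colnames(x),
                                 stats::setNames(rep(NA_real_, ncol(x)), colnames(x)),
                                 partition),
    pearson = pearson_select(x, y, alpha = alpha, partition = partition),
    overlap = overlap_select(x, y, k = k, partition = partition),
    chi2 = chi2_select(x, y, k = k, partition = partition),
    stop_bad_arg("unknown feature method '", method, "'")
  )
}

#' Evaluate one train/test partition
#'
#' Performs feature selection on the training rows only, optionally appends
#' per-partition rescaled demographics (ranges and the intensity median `m`
#' are fit on the training rows), standardises features on training
#' statistics, fits the requested classifier with seeded randomness, predicts
#' the test rows, and scores the confusion table.
#'
#' @param dataset A [labeled_dataset()].
#' @param train_idx,test_idx Row indices from [stratified_partition()].
#' @param model One of `"knn"`, `"svm"`, `"lda"`, `"nbc"`, `"rfc"`.
#' @param feature_method One of `"none"`, `"pearson"`, `"overlap"`, `"chi2"`.
#' @param k Feature count for overlap/chi2 selection.
#' @param alpha Significance level for Pearson selection.
#' @param seed Seed for classifier randomness.
#' @param classifiers Registry from [default_classifiers()].
#' @param partition Partition ID recorded in the result.
#' @return A `partition_result` list: `selection`, `confusion`, `accuracy`,
#'   `kappa`, `failed` (with `reason` when a partition is degenerate), and the
#'   model/feature-method names.
#' @export
evaluate_partition <- function(dataset, train_idx, test_idx, model = "lda",
                               feature_method = "none", k = 40L, alpha = 0.05,
                               seed = 1L, classifiers = default_classifiers(),
                               partition = NA_integer_) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  entry <- classifiers[[model]] %||% stop_bad_arg("unknown model '", model, "'")
  x <- dataset$x
  y <- dataset$labels

  sel <- select_features(x[train_idx, , drop = FALSE], y[train_idx],
                         feature_method, k = k, alpha = alpha,
                         partition = partition)
  if (length(sel$selected) == 0L) {
    return(structure(list(partition = partition, model = model,
                          feature_method = feature_method, selection = sel,
                          failed = TRUE, reason = "empty feature selection"),
                     class = "partition_result"))
  }

  train_x <- x[train_idx, sel$selected, drop = FALSE]
  test_x <- x[test_idx, sel$selected, drop = FALSE]

  if (!is.null(dataset$demographics)) {
    aug <- append_demographic_partition(train_x, test_x,
                                        dataset$demographics[train_idx, , drop = FALSE],
                                        dataset$demographics[test_idx, , drop = FALSE])
    train_x <- aug$train
    test_x <- aug$test
  }

  std <- standardize_train_test(train_x, test_x)
  pred <- withr::with_seed(as.integer(seed), {
    fit <- entry$fit(std$train, y[train_idx])
    entry$predict(fit, std$test)
  })
  conf <- confusion_counts(y[test_idx], pred)
  kap <- cohen_kappa(conf)
  structure(list(partition = partition, model = model,
                 feature_method = feature_method, selection = sel,
                 confusion = conf, accuracy = accuracy(conf), kappa = kap,
                 failed = is.na(kap),
                 reason = if (is.na(kap)) "degenerate marginals (kappa undefined)" else NA_character_),
            class = "partition_result")
}

# Per-partition demographic rescaling: continuous ranges and the intensity
# median m come from the training rows only and are applied to both splits.
append_demographic_partition <- function(train_x, test_x, train_dem, test_dem) {
  pos <- train_x[train_x > 0]
  m <- if (length(pos)) median(pos) else 1
  params <- names(train_dem)
  tr <- matrix(0, nrow(train_x), length(params),
               dimnames = list(NULL, paste0("demog_", params)))
  te <- matrix(0, nrow(test_x), length(params),
               dimnames = list(NULL, paste0("demog_", params)))
  for (j in seq_along(params)) {
    p <- params[j]
    xtr <- as.numeric(train_dem[[p]]); xte <- as.numeric(test_dem[[p]])
    if (p %in% demographic_binary_params() || all(xtr %in% c(0, 1))) {
      tr[, j] <- ifelse(xtr > 0, m, 0)
      te[, j] <- ifelse(xte > 0, m, 0)
    } else {
      lo <- min(xtr); hi <- max(xtr)
      if (hi == lo) next
      tr[, j] <- (xtr - lo) / (hi - lo) * m
      te[, j] <- (xte - lo) / (hi - lo) * m
    }
  }
  list(train = cbind(train_x, tr), test = cbind(test_x, te))
}

#' Repeated stratified holdout evaluation
#'
#' Repeats `n_repeats` times: draw a stratified 80:20 partition, select
#' features on the training rows, fit the classifier, predict the test rows,
#' and score accuracy and Cohen's kappa. Per-partition seeds are derived from
#' `base_seed` by a counter so any single partition is replayable. Degenerate
#' partitions (undefined kappa, empty selection) are excluded from the means
#' and counted.
#'
#' @inheritParams evaluate_partition
#' @param n_repeats Number of partitions (default 200).
#' @param ratio Training fraction (default 0.8).
#' @param base_seed Base seed for the partition sequence.
#' @param default_threshold Passed to [kappa_significance_threshold()].
#' @param permute_labels Run a permutation-null calibration: labels are
#'   freshly permuted (seeded) in every repetition before partitioning, so the
#'   summary estimates the chance-level accuracy and kappa of the full
#'   pipeline. A single fixed permutation would leave a systematic residual
#'   correlation with the true classes; re-permuting per repetition averages
#'   it out.
#' @param keep_partitions Keep the full per-partition result list (default
#'   TRUE; set FALSE to save memory in large grids, selections are then
#'   reduced to labels only).
#' @return Object of class `evaluation_summary`: means and SDs of accuracy and
#'   kappa, `n_valid`/`n_failed`, significance flag, agreement label, and
#'   `partitions` (list of `partition_result`).
#' @export
run_evaluation <- function(dataset, model = "lda", feature_method = "none",
                           n_repeats = 200L, ratio = 0.8, base_seed = 1L,
                           k = 40L, alpha = 0.05,
                           classifiers = default_classifiers(),
                           default_threshold = 0, permute_labels = FALSE,
                           keep_partitions = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$labels
  if (sum(y == 0L) != sum(y == 1L)) {
    warning("dataset classes are not balanced; accuracy is hard to interpret",
            call. = FALSE)
  }
  results <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    seed_i <- derive_seed(base_seed, i)
    ds_i <- dataset
    if (permute_labels) {
      ds_i$labels <- withr::with_seed(derive_seed(seed_i, 2L),
                                      sample(dataset$labels))
    }
    part <- stratified_partition(ds_i$labels, ratio = ratio, seed = seed_i)
    results[[i]] <- evaluate_partition(ds_i, part$train, part$test,
                                       model = model,
                                       feature_method = feature_method,
                                       k = k, alpha = alpha,
                                       seed = derive_seed(seed_i, 1L),
                                       classifiers = classifiers,
                                       partition = i)
  }
  failed <- vapply(results, function(r) isTRUE(r$failed), logical(1))
  acc <- vapply(results[!failed], `[[`, numeric(1), "accuracy")
  kap <- vapply(results[!failed], `[[`, numeric(1), "kappa")
  n_valid <- sum(!failed)
  sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
  mean_kappa <- mean(kap)
  thr <- kappa_significance_threshold(length(y), default_threshold)
  structure(list(
    mean_accuracy = mean(acc), sd_accuracy = sd0(acc),
    mean_kappa = mean_kappa, sd_kappa = sd0(kap),
    n_partitions = n_repeats, n_valid = n_valid, n_failed = sum(failed),
    single_partition = n_repeats == 1L,
    kappa_threshold = thr,
    significant = is.finite(mean_kappa) && mean_kappa >= thr,
    agreement = if (is.finite(mean_kappa)) {
      interpret_kappa(max(-1, min(1, mean_kappa)))
    } else NA_character_,
    model = model, feature_method = feature_method,
    provenance = dataset$provenance,
    partitions = if (keep_partitions) results else NULL
  ), class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_summary> %s + %s over %d partitions: ",
                     "accuracy %.1f%% (SD %.1f), kappa %.3f (SD %.3f) [%s%s]\n"),
              x$model, x$feature_method, x$n_partitions,
              x$mean_accuracy, x$sd_accuracy, x$mean_kappa, x$sd_kappa,
              x$agreement,
              if (x$significant) ", significant" else ""))
  invisible(x)
}
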