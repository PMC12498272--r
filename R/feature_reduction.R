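# Per-partition feature-selection methods and the cross-method consensus
# criterion. Three methods are provided: point-biserial (Pearson) correlation
# with a significance gate, distribution overlap integrals (smallest k), and
# chi-squared feature ranking (largest k).

new_feature_selection <- function(method, selected, score, partition = NA_integer_,
                                  extra = list()) {
  structure(c(list(method = method, selected = selected, score = score,
                   partition = partition), extra),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> method '%s': %d feature(s)\n",
              x$method, length(x$selected)))
  invisible(x)
}

check_xy <- function(x, y, min_per_class = 2L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_bad_arg("rows of 'x' and 'y' must align")
  if (!all(y %in% c(0L, 1L))) stop_bad_arg("'y' must be binary 0/1")
  if (sum(y == 0L) < min_per_class || sum(y == 1L) < min_per_class) {
    stop_bad_arg("need at least ", min_per_class, " samples per class")
  }
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  x
}

# Numeric sort key for bin labels ("demog_*" columns sort after all bins).
bin_sort_key <- function(labels) {
  key <- suppressWarnings(as.numeric(labels))
  key[is.na(key)] <- Inf
  key
}

#' Pearson (point-biserial) correlation feature selection
#'
#' For every feature, the Pearson correlation between intensity and the 0/1
#' class label (the point-biserial correlation) is tested two-sided; features
#' with P below `alpha` are selected. No multiple-testing correction is
#' applied by default, mirroring the plain per-peak significance gate;
#' `fdr = TRUE` switches the gate to Benjamini-Hochberg-adjusted P-values.
#' Constant features have undefined correlation, are assigned P = 1, and are
#' never selected.
#'
#' @param x Feature matrix (training rows only), samples x features.
#' @param y Binary 0/1 labels.
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg adjustment before gating.
#' @param normality_diagnostic Also report the fraction of features passing a
#'   Shapiro-Wilk normality test at P > 0.05 (descriptive only; costs one test
#'   per feature).
#' @param partition Optional partition ID recorded in the result.
#' @return A `feature_selection` with per-feature P-values as scores and, when
#'   requested, `normal_fraction`.
#' @export
pearson_select <- function(x, y, alpha = 0.05, fdr = FALSE,
                           normality_diagnostic = FALSE,
                           partition = NA_integer_) {
  x <- check_xy(x, y, min_per_class = 3L)
  n <- nrow(x)
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(as.numeric(cor(x, y)))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[sds == 0] <- 1
  names(p) <- colnames(x)
  gate <- if (fdr) stats::p.adjust(p, "BH") else p
  selected <- colnames(x)[gate < alpha]
  extra <- list(alpha = alpha, fdr = fdr)
  if (normality_diagnostic) {
    extra$normal_fraction <- mean(apply(x, 2, function(col) {
      if (sd(col) == 0) return(FALSE)
      shapiro.test(col)$p.value > 0.05
    }))
  }
  new_feature_selection("pearson", selected, p, partition, extra)
}

#' Overlap integral of two empirical distributions
#'
#' Both groups are histogrammed on the shared `edges`, each histogram is
#' normalised to unit sum, and the overlap integral is the sum over histogram
#' cells of the minimum of the two normalised frequencies. Identical
#' distributions give 1; distributions with disjoint occupied cells give 0.
#' Symmetric in its group arguments.
#'
#' @param values_class0,values_class1 Non-empty numeric vectors.
#' @param edges Increasing cell edges spanning the pooled range (the last cell
#'   is closed on the right).
#' @return Scalar in `[0, 1]`.
#' @export
overlap_integral <- function(values_class0, values_class1, edges) {
  if (length(values_class0) == 0L || length(values_class1) == 0L) {
    stop_bad_arg("both groups must be non-empty")
  }
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_bad_arg("'edges' must be strictly increasing")
  }
  pooled <- c(values_class0, values_class1)
  if (min(pooled) < edges[1] || max(pooled) > edges[length(edges)]) {
    stop_bad_arg("'edges' must span the pooled range of both groups")
  }
  ncell <- length(edges) - 1L
  h0 <- tabulate(findInterval(values_class0, edges, rightmost.closed = TRUE), ncell)
  h1 <- tabulate(findInterval(values_class1, edges, rightmost.closed = TRUE), ncell)
  sum(pmin(h0 / sum(h0), h1 / sum(h1)))
}

# Shared per-feature edge rule: pooled min-max split into ceiling(sqrt(n))
# equal-width cells, at least 5. A constant pooled feature gets one token
# cell, so both distributions coincide and the overlap is 1.
overlap_edges <- function(pooled) {
  lo <- min(pooled); hi <- max(pooled)
  if (hi == lo) return(c(lo - 0.5, hi + 0.5))
  ncell <- max(5L, ceiling(sqrt(length(pooled))))
  seq(lo, hi, length.out = ncell + 1L)
}

#' Overlap-integral feature selection (smallest k)
#'
#' Computes the per-feature overlap integral between the two class intensity
#' distributions (shared equal-width cells spanning the pooled range, see
#' Details) and selects the `k` features with the smallest overlap — those
#' whose intensity distributions differ most between classes. Ties at the cut
#' are broken by ascending bin label.
#'
#' @details The per-feature cell rule uses `max(5, ceiling(sqrt(n_pooled)))`
#' equal-width cells between the pooled minimum and maximum.
#'
#' @inheritParams pearson_select
#' @param k Number of features to select (default 40). When fewer features
#'   exist, all are selected with a warning.
#' @return A `feature_selection` with per-feature overlap integrals as scores.
#' @export
overlap_select <- function(x, y, k = 40L, partition = NA_integer_) {
  x <- check_xy(x, y, min_per_class = 2L)
  i0 <- y == 0L; i1 <- y == 1L
  score <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    overlap_integral(v[i0], v[i1], overlap_edges(v))
  }, numeric(1))
  names(score) <- colnames(x)
  if (ncol(x) < k) {
    warning(sprintf("only %d features available; selecting all", ncol(x)),
            call. = FALSE)
    k <- ncol(x)
  }
  ord <- order(score, bin_sort_key(colnames(x)))
  selected <- colnames(x)[ord[seq_len(k)]]
  new_feature_selection("overlap", selected, score, partition, list(k = k))
}

#' Chi-squared feature ranking (largest k)
#'
#' Frequency-style chi-squared statistic for nonnegative features: per
#' feature, the class-wise intensity sums are compared against the totals
#' expected from the class proportions, and features are ranked by the
#' statistic; the `k` highest-"importance" features are selected. Ties are
#' broken by ascending bin label.
#'
#' @inheritParams overlap_select
#' @return A `feature_selection` with per-feature chi-squared statistics as
#'   scores.
#' @export
chi2_select <- function(x, y, k = 40L, partition = NA_integer_) {
  x <- check_xy(x, y, min_per_class = 2L)
  if (any(x < 0)) {
    stop_bad_arg("chi-squared ranking requires nonnegative features; ",
                 "apply the background-subtraction clipping step first")
  }
  prior <- c(mean(y == 0L), mean(y == 1L))
  obs <- rbind(colSums(x[y == 0L, , drop = FALSE]),
               colSums(x[y == 1L, , drop = FALSE]))
  totals <- colSums(obs)
  exp <- outer(prior, totals)
  stat <- colSums((obs - exp)^2 / pmax(exp, .Machine$double.xmin))
  stat[totals == 0] <- 0
  names(stat) <- colnames(x)
  if (ncol(x) < k) {
    warning(sprintf("only %d features available; selecting all", ncol(x)),
            call. = FALSE)
    k <- ncol(x)
  }
  ord <- order(-stat, bin_sort_key(colnames(x)))
  selected <- colnames(x)[ord[seq_len(k)]]
  new_feature_selection("chi2", selected, stat, partition, list(k = k))
}

#' Cross-method consensus features
#'
#' A feature qualifies for the consensus set if, for each of the three
#' feature-reduction methods separately, it was selected in strictly more than
#' `fraction` of that method's training partitions.
#'
#' @param selections List of `feature_selection` objects covering at least one
#'   partition for each of the methods `pearson`, `overlap`, and `chi2`.
#' @param fraction Selection-frequency threshold (default 0.75; strict
#'   inequality).
#' @return Object of class `consensus_report`: list with `consensus` (bin
#'   labels), `fractions` (long `data.frame` of bin x method selection
#'   frequencies), `n_partitions` (per method), and `fraction` (the
#'   threshold).
#' @export
consensus_features <- function(selections, fraction = 0.75) {
  methods_required <- c("pearson", "overlap", "chi2")
  meth <- vapply(selections, function(s) s$method, character(1))
  per_method <- lapply(methods_required, function(m) selections[meth == m])
  names(per_method) <- methods_required
  n_parts <- vapply(per_method, length, integer(1))
  if (any(n_parts == 0L)) {
    stop_bad_arg("no partitions for method(s): ",
                 paste(methods_required[n_parts == 0L], collapse = ", "))
  }

  frac_tables <- lapply(methods_required, function(m) {
    counts <- table(unlist(lapply(per_method[[m]], `[[`, "selected")))
    if (length(counts) == 0L) return(numeric(0))
    f <- as.numeric(counts) / n_parts[[m]]
    names(f) <- names(counts)
    f
  })
  names(frac_tables) <- methods_required

  qualifying <- lapply(frac_tables, function(f) names(f)[f > fraction])
  consensus <- Reduce(intersect, qualifying)
  consensus <- consensus[order(bin_sort_key(consensus))]

  fractions <- do.call(rbind, lapply(methods_required, function(m) {
    f <- frac_tables[[m]]
    if (length(f) == 0L) return(NULL)
    data.frame(bin = names(f), method = m, fraction = as.numeric(f),
               stringsAsFactors = FALSE)
  }))

  structure(list(consensus = consensus, fractions = fractions,
                 n_partitions = n_parts, fraction = fraction),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d consensus feature(s) at > %.0f%% of partitions: %s\n",
              length(x$consensus), 100 * x$fraction,
              paste(x$consensus, collapse = ", ")))
  invisible(x)
}
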