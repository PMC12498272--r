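# Scoring machinery, partitioning, and the repeated-holdout evaluation loop.

test_that("accuracy and kappa reproduce the worked confusion example", {
  conf <- confusion_counts(truth = c(rep(1, 12), rep(0, 8)),
                           pred  = c(rep(1, 8), rep(0, 4), rep(0, 6), rep(1, 2)))
  expect_identical(conf$TP, 8L); expect_identical(conf$TN, 6L)
  expect_identical(conf$FP, 2L); expect_identical(conf$FN, 4L)
  expect_equal(accuracy(conf), 70)
  # p_o = 0.7, p_e = (10*12 + 10*8) / 400 = 0.5, kappa = 0.4
  expect_equal(cohen_kappa(conf), 0.4)
})

test_that("kappa edge cases behave as defined", {
  perfect <- structure(list(TP = 5L, TN = 7L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  expect_equal(cohen_kappa(perfect), 1)
  expect_equal(accuracy(perfect), 100)

  balanced_guess <- structure(list(TP = 3L, TN = 3L, FP = 3L, FN = 3L),
                              class = "confusion_counts")
  expect_equal(cohen_kappa(balanced_guess), 0)
  expect_equal(accuracy(balanced_guess), 50)

  # degenerate marginals: everything is one class in both truth and prediction
  degenerate <- structure(list(TP = 10L, TN = 0L, FP = 0L, FN = 0L),
                          class = "confusion_counts")
  expect_true(is.na(cohen_kappa(degenerate)))

  # label-swap invariance: swapping classes in truth and prediction together
  conf <- confusion_counts(c(1, 1, 0, 0, 1, 0), c(1, 0, 0, 1, 1, 0))
  swapped <- confusion_counts(1 - c(1, 1, 0, 0, 1, 0), 1 - c(1, 0, 0, 1, 1, 0))
  expect_equal(cohen_kappa(conf), cohen_kappa(swapped))
})

test_that("kappa and accuracy match the vector oracle over random confusion tables", {
  withr::with_seed(101L, {
    for (i in seq_len(2000)) {
      counts <- rmultinom(1, sample(4:60, 1), prob = runif(4, 0.05, 1))[, 1]
      v <- vectors_from_counts(counts[1], counts[2], counts[3], counts[4])
      conf <- confusion_counts(v$truth, v$pred)
      o <- oracle_scores(v$truth, v$pred)
      expect_equal(accuracy(conf), o$accuracy, tolerance = 1e-12)
      if (o$kappa_defined) {
        expect_equal(cohen_kappa(conf), o$kappa, tolerance = 1e-12)
      } else {
        expect_true(is.na(cohen_kappa(conf)))
      }
    }
  })
})

test_that("significance thresholds depend on the dataset size", {
  expect_equal(kappa_significance_threshold(40), 0.6)
  expect_equal(kappa_significance_threshold(46), 0.6)
  expect_equal(kappa_significance_threshold(50), 0.6)
  expect_equal(kappa_significance_threshold(60), 0.5)
  expect_equal(kappa_significance_threshold(220), 0)
  expect_equal(kappa_significance_threshold(220, default_threshold = 0.3), 0.3)
})

test_that("kappa values map to agreement bands with lower-band boundaries", {
  expect_identical(interpret_kappa(0.1), "None")
  expect_identical(interpret_kappa(0.2), "Weak")
  expect_identical(interpret_kappa(0.4), "Weak")
  expect_identical(interpret_kappa(0.5), "Fair")
  expect_identical(interpret_kappa(0.6), "Fair")
  expect_identical(interpret_kappa(0.71), "Moderate")
  expect_identical(interpret_kappa(0.8), "Moderate")
  expect_identical(interpret_kappa(0.9), "Strong")
  expect_identical(interpret_kappa(0.95), "Very strong")
  expect_identical(interpret_kappa(-0.5), "None")
  expect_error(interpret_kappa(1.2), "kappa")
})

test_that("stratified partitions split 80:20 within each class", {
  labels <- rep(c(0L, 1L), each = 25)
  p <- stratified_partition(labels, seed = 3L)
  expect_identical(sum(labels[p$train] == 0L), 20L)
  expect_identical(sum(labels[p$train] == 1L), 20L)
  expect_identical(sum(labels[p$test] == 0L), 5L)
  expect_identical(sum(labels[p$test] == 1L), 5L)
  expect_length(intersect(p$train, p$test), 0L)
  expect_setequal(c(p$train, p$test), seq_along(labels))

  expect_identical(stratified_partition(labels, seed = 9L),
                   stratified_partition(labels, seed = 9L))

  expect_error(stratified_partition(rep(c(0L, 1L), c(4, 26))), "fewer than 5")
})

test_that("test-set membership frequency is close to 0.2 over many seeds", {
  labels <- rep(c(0L, 1L), each = 25)
  counts <- integer(length(labels))
  for (s in 1:200) {
    p <- stratified_partition(labels, seed = s)
    counts[p$test] <- counts[p$test] + 1L
  }
  freq <- counts / 200
  # binomial(200, 0.2): 4-sigma band per sample
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 200)))
})

test_that("the evaluation loop is reproducible and flags single partitions", {
  ds <- make_planted_cohort(seed = 21L, n_per_class = 10L)
  e1 <- run_evaluation(ds, model = "lda", feature_method = "chi2",
                       n_repeats = 5L, base_seed = 11L)
  e2 <- run_evaluation(ds, model = "lda", feature_method = "chi2",
                       n_repeats = 5L, base_seed = 11L)
  expect_equal(e1$mean_kappa, e2$mean_kappa)
  expect_equal(e1$mean_accuracy, e2$mean_accuracy)
  expect_identical(vapply(e1$partitions, `[[`, numeric(1), "kappa"),
                   vapply(e2$partitions, `[[`, numeric(1), "kappa"))

  single <- run_evaluation(ds, model = "nbc", feature_method = "none",
                           n_repeats = 1L, base_seed = 2L)
  expect_true(single$single_partition)
  expect_identical(single$sd_kappa, 0)
  expect_identical(single$sd_accuracy, 0)
})

test_that("every classifier family learns the strongly planted signal", {
  ds <- make_planted_cohort(seed = 23L, n_per_class = 15L)
  for (model in c("knn", "svm", "lda", "nbc", "rfc")) {
    ev <- run_evaluation(ds, model = model, feature_method = "overlap",
                         n_repeats = 10L, base_seed = 5L,
                         keep_partitions = FALSE)
    expect_gt(ev$mean_kappa, 0.5)
  }
})

test_that("mutating test rows changes neither selection nor the fitted model", {
  ds <- make_planted_cohort(seed = 25L, n_per_class = 10L)
  part <- stratified_partition(ds$labels, seed = 31L)
  ds2 <- ds
  ds2$x[part$test, ] <- withr::with_seed(
    32L, matrix(runif(length(part$test) * ncol(ds$x)), length(part$test)))

  for (method in c("pearson", "overlap", "chi2")) {
    r1 <- evaluate_partition(ds, part$train, part$test, model = "lda",
                             feature_method = method, seed = 3L)
    r2 <- evaluate_partition(ds2, part$train, part$test, model = "lda",
                             feature_method = method, seed = 3L)
    expect_identical(r1$selection$selected, r2$selection$selected)
    expect_identical(r1$selection$score, r2$selection$score)
  }

  # same probe rows through models fitted with and without mutated test rows
  ds3 <- ds
  probe <- part$train[1:6]
  r1 <- evaluate_partition(ds, part$train, probe, model = "rfc",
                           feature_method = "chi2", seed = 9L)
  ds3$x[part$test, ] <- ds3$x[part$test, ] * 3
  r3 <- evaluate_partition(ds3, part$train, probe, model = "rfc",
                           feature_method = "chi2", seed = 9L)
  expect_identical(r1$confusion, r3$confusion)
})

test_that("failed partitions are excluded with a count", {
  # no informative features and alpha tiny -> empty pearson selection
  y <- rep(c(0L, 1L), each = 10)
  x <- withr::with_seed(41L, matrix(rnorm(20 * 8), 20, 8,
                                    dimnames = list(NULL, 1:8)))
  ds <- labeled_dataset(x, y)
  ev <- run_evaluation(ds, model = "lda", feature_method = "pearson",
                       n_repeats = 10L, base_seed = 3L, alpha = 1e-12)
  expect_identical(ev$n_failed, 10L)
  expect_identical(ev$n_valid, 0L)
})
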