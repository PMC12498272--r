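# Feature-reduction methods: selection behaviour, score laws, oracles, and
# the consensus criterion.

make_xy <- function(n = 40L, p = 30L, seed = 1L) {
  y <- rep(c(0L, 1L), each = n / 2)
  x <- withr::with_seed(seed, matrix(rlnorm(n * p, 0, 0.3), n, p,
                                     dimnames = list(NULL, 100 + seq_len(p))))
  list(x = x, y = y)
}

test_that("point-biserial selection matches cor.test and gates at alpha", {
  d <- make_xy(seed = 2L)
  x <- d$x
  x[, 1] <- d$y + withr::with_seed(3L, rnorm(40, 0, 1e-6))  # ~ the label itself
  x[, 2] <- 5                                               # constant
  sel <- pearson_select(x, d$y)
  expect_true(colnames(x)[1] %in% sel$selected)
  expect_false(colnames(x)[2] %in% sel$selected)
  expect_identical(unname(sel$score[2]), 1)
  expect_lt(sel$score[1], 1e-10)

  # independent oracle: stats::cor.test per feature
  for (j in c(1, 5, 9, 20)) {
    ct <- cor.test(x[, j], d$y)
    expect_equal(unname(sel$score[j]), ct$p.value, tolerance = 1e-10)
  }
})

test_that("null features are selected at roughly the alpha rate", {
  hits <- 0L; trials <- 0L
  y <- rep(c(0L, 1L), each = 25)
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(rnorm(50 * 200), 50, 200,
                                    dimnames = list(NULL, seq_len(200))))
    sel <- pearson_select(x, y, alpha = 0.05)
    hits <- hits + length(sel$selected)
    trials <- trials + 200L
  }
  rate <- hits / trials
  # 1000 independent null features; binomial 3-sigma band around 0.05
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("normality diagnostic reports a fraction in [0, 1]", {
  y <- rep(c(0L, 1L), each = 20)
  x <- withr::with_seed(7L, matrix(rnorm(40 * 50), 40, 50,
                                   dimnames = list(NULL, seq_len(50))))
  sel <- pearson_select(x, y, normality_diagnostic = TRUE)
  expect_gte(sel$normal_fraction, 0)
  expect_lte(sel$normal_fraction, 1)
  # genuinely normal features mostly pass Shapiro-Wilk
  expect_gt(sel$normal_fraction, 0.8)
})

test_that("overlap integral obeys its laws and the hand-computed example", {
  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  edges <- c(-0.5, 0.5, 1.5, 2.5)
  # hand histogram arithmetic: A -> (.5,.5,0), B -> (0,.5,.5), overlap 0.5
  expect_equal(overlap_integral(a, b, edges), 0.5)
  # symmetry
  expect_equal(overlap_integral(b, a, edges), overlap_integral(a, b, edges))
  # identical inputs -> 1
  expect_equal(overlap_integral(a, a, edges), 1)
  # disjoint occupied cells -> 0
  expect_equal(overlap_integral(c(0, 0.2), c(2, 2.2), c(-0.5, 0.5, 1.5, 2.5)), 0)

  # range [0,1] and affine invariance on random groups
  for (s in 1:20) {
    g <- withr::with_seed(s, list(u = rnorm(30), v = rnorm(25, 0.5)))
    pooled <- c(g$u, g$v)
    e <- seq(min(pooled), max(pooled), length.out = 9)
    o <- overlap_integral(g$u, g$v, e)
    expect_gte(o, 0); expect_lte(o, 1)
    o2 <- overlap_integral(3 * g$u + 2, 3 * g$v + 2, 3 * e + 2)
    expect_equal(o2, o, tolerance = 1e-12)
  }

  expect_error(overlap_integral(numeric(0), 1, c(0, 2)), "non-empty")
  expect_error(overlap_integral(0.5, 5, c(0, 1)), "span")
})

test_that("overlap selection returns the k smallest with the declared tie rule", {
  d <- make_xy(n = 30L, p = 10L, seed = 9L)
  x <- d$x
  x[d$y == 1L, 3] <- x[d$y == 1L, 3] * 4  # one strongly separated feature
  sel <- overlap_select(x, d$y, k = 4L)
  expect_length(sel$selected, 4L)
  expect_true(colnames(x)[3] %in% sel$selected)
  # selection equals the k smallest scores under (score, bin) ordering
  ord <- order(sel$score, as.numeric(names(sel$score)))
  expect_identical(sel$selected, names(sel$score)[ord[1:4]])

  # k = number of features -> identity selection (with a warning when k larger)
  sel_all <- overlap_select(x, d$y, k = 10L)
  expect_setequal(sel_all$selected, colnames(x))
  expect_warning(overlap_select(x, d$y, k = 50L), "selecting all")

  # exact ties break by ascending bin label
  xt <- cbind(`201` = rep(c(0, 1), 15), `105` = rep(c(0, 1), 15))
  selt <- overlap_select(xt, rep(c(0L, 1L), 15), k = 1L)
  expect_identical(selt$selected, "105")
})

test_that("chi-squared ranking matches a per-feature brute-force oracle", {
  d <- make_xy(n = 40L, p = 25L, seed = 12L)
  x <- d$x
  x[, 5] <- as.numeric(d$y)         # 0 for class 0, positive for class 1
  x[, 6] <- 2                        # constant across classes
  sel <- chi2_select(x, d$y, k = 10L)
  expect_length(sel$selected, 10L)
  expect_identical(names(which.max(sel$score)), colnames(x)[5])
  expect_equal(unname(sel$score[6]), 0, tolerance = 1e-12)

  # brute force per feature: class sums vs expected from class proportions
  n0 <- sum(d$y == 0L); n1 <- sum(d$y == 1L); n <- n0 + n1
  for (j in seq_len(ncol(x))) {
    o0 <- sum(x[d$y == 0L, j]); o1 <- sum(x[d$y == 1L, j])
    tot <- o0 + o1
    e0 <- tot * n0 / n; e1 <- tot * n1 / n
    stat <- (o0 - e0)^2 / e0 + (o1 - e1)^2 / e1
    expect_equal(unname(sel$score[j]), stat, tolerance = 1e-9)
  }

  expect_error(chi2_select(cbind(a = c(-1, 1, 1, 1, 2, 2)),
                           rep(c(0L, 1L), each = 3), k = 1L),
               "nonnegative")
})

test_that("selected sets always have size min(k, n_features)", {
  d <- make_xy(n = 30L, p = 12L, seed = 15L)
  for (k in c(1L, 5L, 12L)) {
    expect_length(overlap_select(d$x, d$y, k = k)$selected, k)
    expect_length(chi2_select(d$x, d$y, k = k)$selected, k)
  }
})

fake_selection <- function(method, selected, partition) {
  sel <- overlap_select(cbind(`11` = c(0, 0, 1, 1), `12` = c(0, 1, 0, 1)),
                        c(0L, 0L, 1L, 1L), k = 1L)
  sel$method <- method
  sel$selected <- selected
  sel$partition <- partition
  sel
}

test_that("consensus requires strictly more than the fraction for all methods", {
  sels <- list()
  # bin "7": all methods, 100% of 4 partitions. bin "8": exactly 75% for chi2.
  for (m in c("pearson", "overlap", "chi2")) {
    for (p in 1:4) {
      picked <- "7"
      if (m != "chi2" || p <= 3) picked <- c(picked, "8")
      sels[[length(sels) + 1L]] <- fake_selection(m, picked, p)
    }
  }
  rep75 <- consensus_features(sels, fraction = 0.75)
  expect_identical(rep75$consensus, "7")

  # monotone non-increasing in the threshold
  rep50 <- consensus_features(sels, fraction = 0.5)
  expect_true(all(rep75$consensus %in% rep50$consensus))
  expect_setequal(rep50$consensus, c("7", "8"))

  expect_error(consensus_features(sels[1:8]), "chi2")
})

test_that("selection depends on training rows only", {
  d <- make_xy(n = 40L, p = 20L, seed = 18L)
  train <- 1:30; test <- 31:40
  x2 <- d$x
  x2[test, ] <- withr::with_seed(19L, matrix(runif(10 * 20, 5, 6), 10, 20))
  for (fn in list(pearson_select,
                  function(x, y) overlap_select(x, y, k = 5L),
                  function(x, y) chi2_select(x, y, k = 5L))) {
    s1 <- fn(d$x[train, ], d$y[train])
    s2 <- fn(x2[train, ], d$y[train])
    expect_identical(s1$selected, s2$selected)
    expect_identical(s1$score, s2$score)
  }
})
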