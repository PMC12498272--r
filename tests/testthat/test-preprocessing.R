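# Preprocessing chain: segmentation, binning, background subtraction,
# normalisation, replicate averaging, and the composed pipeline.

make_flat_acquisition <- function(n_scans = 60L, level = 10, nbins = 20L) {
  structure(list(
    times = (seq_len(n_scans) - 1) * 0.9,
    scans = lapply(seq_len(n_scans), function(i) {
      list(mz = as.numeric(seq(11, 10 + nbins)), intensity = rep(level, nbins))
    }),
    metadata = list(sample_id = "flat"),
    truth = NULL
  ), class = "raw_acquisition")
}

test_that("a constant TIC stream is all background with zero sample windows", {
  raw <- make_flat_acquisition()
  seg <- segment_acquisition(raw)
  expect_identical(seg$background, c(1L, 61L))
  expect_length(seg$samples, 0L)
})

test_that("segmentation finds planted plateaus and rejects short transients", {
  raw <- make_flat_acquisition(100L)
  # two plateaus at 10x baseline: scans 21-40 and 61-75; one 2-scan spike at 90
  for (i in c(21:40, 61:75)) raw$scans[[i]]$intensity <- rep(100, 20)
  for (i in 90:91) raw$scans[[i]]$intensity <- rep(100, 20)
  seg <- segment_acquisition(raw, rise_factor = 5, min_window_scans = 5L)
  expect_identical(seg$samples, list(c(21L, 41L), c(61L, 76L)))
  expect_identical(seg$background, c(1L, 21L))

  expect_error(segment_acquisition(structure(list(times = numeric(0),
                                                  scans = list(),
                                                  metadata = list()),
                                             class = "raw_acquisition")),
               "zero scans")
  # stream that opens mid-insertion: the first scan towers over the next few
  high <- make_flat_acquisition(30L, level = 1)
  high$scans[[1]]$intensity <- rep(100, 20)
  expect_error(segment_acquisition(high), "starts high")
})

test_that("segmentation recovers simulated ground-truth windows", {
  cfg <- sim_config(bin_range = c(11L, 110L))
  s <- default_baseline_profile(c(11L, 110L))
  raw <- simulate_raw_acquisition(s, cfg, 17L, noise_cv = 0.05)
  seg <- segment_acquisition(raw)
  expect_identical(unname(seg$samples), unname(raw$truth$samples))
})

test_that("unit-mass binning follows round-half-up and conserves intensity", {
  v <- bin_to_unit_mass(c(100.2, 100.4), c(3, 4), c(11L, 1000L))
  expect_equal(unname(v["100"]), 7)
  # exactly .5 rounds up
  v2 <- bin_to_unit_mass(100.5, 1, c(11L, 1000L))
  expect_equal(unname(v2["101"]), 1)
  expect_equal(unname(v2["100"]), 0)

  # conservation with dropped mass, random peaks
  withr::with_seed(5L, {
    mz <- runif(1000, 0, 1200)
    int <- runif(1000, 0, 10)
  })
  v3 <- bin_to_unit_mass(mz, int, c(11L, 1000L))
  expect_lt(abs(sum(v3) + attr(v3, "dropped_mass") - sum(int)), 1e-9)

  # order invariance
  perm <- withr::with_seed(6L, sample(seq_along(mz)))
  v4 <- bin_to_unit_mass(mz[perm], int[perm], c(11L, 1000L))
  expect_equal(as.numeric(v3), as.numeric(v4), tolerance = 1e-12)

  expect_error(bin_to_unit_mass(100, -1, c(11L, 1000L)), "negative")
  expect_error(bin_to_unit_mass(NaN, 1, c(11L, 1000L)), "finite")
})

test_that("window summaries use the population SD and match brute force", {
  raw <- make_flat_acquisition(10L)
  sm <- summarize_window(raw, c(1L, 11L), c(11L, 30L))
  expect_true(all(sm$sd == 0))
  expect_true(all(sm$mean == 10))

  # two scans with bin-100 intensities 4 and 6: mean 5, population SD 1
  two <- structure(list(times = c(0, 0.9),
                        scans = list(list(mz = 100, intensity = 4),
                                     list(mz = 100, intensity = 6)),
                        metadata = list()), class = "raw_acquisition")
  sm2 <- summarize_window(two, c(1L, 3L), c(99L, 101L))
  expect_equal(unname(sm2$mean["100"]), 5)
  expect_equal(unname(sm2$sd["100"]), 1)

  # random window against per-bin brute-force means
  cfg <- sim_config(bin_range = c(11L, 60L))
  s <- seq_len(50) + 1
  raw3 <- simulate_raw_acquisition(s, cfg, 31L, noise_cv = 0.2)
  w <- raw3$truth$samples[[1]]
  sm3 <- summarize_window(raw3, w, c(11L, 60L))
  brute <- rowMeans(vapply(w[1]:(w[2] - 1L), function(i) {
    out <- numeric(50)
    k <- floor(raw3$scans[[i]]$mz + 0.5) - 10
    for (j in seq_along(k)) out[k[j]] <- out[k[j]] + raw3$scans[[i]]$intensity[j]
    out
  }, numeric(50)))
  expect_equal(unname(sm3$mean), brute, tolerance = 1e-12)

  expect_error(summarize_window(raw, c(5L, 5L), c(11L, 30L)), "empty")
})

test_that("background subtraction clips negatives and reports clip mass", {
  r <- subtract_background(c(5, 3), c(1, 4))
  expect_equal(as.numeric(r), c(4, 0))
  expect_equal(attr(r, "clip_mass"), 1)
  same <- subtract_background(c(2, 2), c(2, 2))
  expect_equal(as.numeric(same), c(0, 0))
  ident <- subtract_background(c(1, 2, 3), c(0, 0, 0))
  expect_equal(as.numeric(ident), c(1, 2, 3))
  expect_equal(attr(ident, "clip_mass"), 0)
  expect_error(subtract_background(1:3, 1:2), "length")
})

test_that("unit-area normalisation is exact, idempotent, and rejects empties", {
  expect_equal(normalize_unit_area(c(2, 2)), c(0.5, 0.5))
  v <- withr::with_seed(2L, runif(100))
  n1 <- normalize_unit_area(v)
  expect_lt(abs(sum(n1) - 1), 1e-9)
  expect_equal(normalize_unit_area(n1), n1, tolerance = 1e-12)
  expect_error(normalize_unit_area(rep(0, 5)), "empty measurement")
})

test_that("replicate averaging preserves unit area without re-normalising", {
  reps <- replicate(5, normalize_unit_area(withr::with_seed(3L, runif(30))),
                    simplify = FALSE)
  ps <- average_replicates(reps)
  expect_equal(unname(ps$intensities), unname(reps[[1]]), tolerance = 1e-12)
  expect_true(all(ps$per_bin_sd == 0))
  expect_identical(ps$n_replicates, 5L)

  ps2 <- average_replicates(list(c(1, 0), c(0, 1)))
  expect_equal(unname(ps2$intensities), c(0.5, 0.5))

  mixed <- lapply(1:5, function(i) normalize_unit_area(withr::with_seed(i, runif(30))))
  expect_lt(abs(sum(average_replicates(mixed)$intensities) - 1), 1e-9)

  expect_error(average_replicates(list()), "at least one")
  expect_error(average_replicates(list(c(0.5, 0.5), c(2, 2))), "unit-area")
})

test_that("processing a zero-noise acquisition recovers the source spectrum", {
  cfg <- sim_config(bin_range = c(11L, 210L))
  s <- default_baseline_profile(c(11L, 210L))
  raw <- simulate_raw_acquisition(s, cfg, 41L, noise_cv = 0)
  ps <- process_acquisition(raw, bin_range = c(11L, 210L))
  expect_lt(max(abs(ps$intensities - normalize_unit_area(s))), 1e-6)
  expect_lt(abs(sum(ps$intensities) - 1), 1e-9)
  expect_identical(ps$n_replicates, 5L)
})

test_that("processing warns on unexpected window counts and errors without samples", {
  cfg <- sim_config(bin_range = c(11L, 60L))
  s <- rep(1, 50)
  raw3 <- simulate_raw_acquisition(s, cfg, 42L, n_sample_windows = 3L)
  expect_warning(ps <- process_acquisition(raw3, bin_range = c(11L, 60L)),
                 "expected 5")
  expect_identical(ps$n_replicates, 3L)

  flat <- make_flat_acquisition()
  expect_error(process_acquisition(flat, bin_range = c(11L, 30L)),
               "no sample windows")
})
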