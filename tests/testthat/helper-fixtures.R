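# Shared fixtures, built in code at test time.

# Small configuration used by most unit tests (few patients, narrow bin range
# so generators stay fast).
tiny_config <- function(n_patients = 20L, bin_range = c(11L, 110L), ...) {
  sim_config(n_patients = n_patients, bin_range = bin_range, ...)
}

# The planted-effect study cohort: 25 patients per class, six effect bins at
# a three-fold mean shift, 30% replicate CV — the conditions under which the
# pipeline is expected to recover the planted signal.
planted_bins <- function() c(45L, 114L, 156L, 208L, 301L, 520L)

make_planted_cohort <- function(seed = 7L, n_per_class = 25L,
                                effect_size = 3, noise_cv = 0.3) {
  cfg <- sim_config(n_patients = 300L)
  clin <- generate_clinical_table(cfg, derive2(seed, 1))
  eff <- effect_spec(planted_bins(), effect_size = effect_size,
                     noise_cv = noise_cv)
  spec <- generate_spectrum_matrix(clin, eff, "hfd", cfg, derive2(seed, 2))
  lab <- attr(spec, "labels")
  i0 <- withr::with_seed(derive2(seed, 3),
                         sample(which(!is.na(lab) & lab == 0L), n_per_class))
  i1 <- withr::with_seed(derive2(seed, 4),
                         sample(which(!is.na(lab) & lab == 1L), n_per_class))
  idx <- sort(c(i0, i1))
  labeled_dataset(spec[idx, , drop = FALSE], lab[idx],
                  ids = clin$patient_id[idx],
                  provenance = list(task = "hfd", variant = "balanced25",
                                    planted = planted_bins()))
}

# Tiny deterministic seed derivation for fixtures (independent of the
# package's internal counter scheme).
derive2 <- function(seed, i) as.integer(seed * 131L + i)

# Independent kappa/accuracy oracle: computed from raw truth/prediction
# vectors, never via the package's confusion-count arithmetic.
oracle_scores <- function(truth, pred) {
  p_o <- mean(truth == pred)
  p_e <- mean(truth == 1) * mean(pred == 1) + mean(truth == 0) * mean(pred == 0)
  list(accuracy = 100 * p_o, kappa = (p_o - p_e) / (1 - p_e),
       kappa_defined = p_e < 1)
}

# Expand confusion counts into aligned truth/prediction vectors.
vectors_from_counts <- function(tp, tn, fp, fn) {
  list(truth = c(rep(1L, tp), rep(0L, tn), rep(0L, fp), rep(1L, fn)),
       pred  = c(rep(1L, tp), rep(0L, tn), rep(1L, fp), rep(0L, fn)))
}
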