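# Generator self-consistency, seeded determinism, noise behaviour.

test_that("the default generator reproduces the reference array structure", {
  cfg <- generator_config()
  gen <- generate_array(cfg)
  expect_equal(nrow(gen$array$cassettes), 116)
  expect_equal(sum(gen$array$cassettes$orf_present), 91)
  expect_equal(sum(!gen$array$cassettes$orf_present), 25)
  expect_equal(sum(gen$array$cassettes$orf_strand == -1, na.rm = TRUE), 8)

  # in-silico prediction (one tolerated mismatch) sees all 90 classes ...
  scm <- build_size_classes(predict_amplicons(gen$array, max_mismatch = 1))
  expect_equal(nrow(scm), 90)
  expect_equal(sum(scm$unique), 75)
  expect_setequal(scm$length, gen$truth$classes$length)

  # ... while the zero-mismatch wet PCR amplifies only the planted subset
  scm0 <- build_size_classes(predict_amplicons(gen$array, max_mismatch = 0))
  expect_equal(nrow(scm0), 62)
  expect_equal(sum(scm0$unique), 50)
  expect_equal(sum(scm0$n_members), 74)
  expect_setequal(scm0$length,
                  gen$truth$classes$length[gen$truth$classes$detected])
})

test_that("any feasible config round-trips through its own in-silico PCR", {
  for (seed in c(1, 2)) {
    cfg <- toy_config(5, rng_seed = seed)
    gen <- generate_array(cfg)
    scm <- build_size_classes(predict_amplicons(gen$array))
    expect_equal(nrow(scm), 5)
    expect_setequal(scm$length, gen$truth$classes$length)
    expect_setequal(unlist(scm$members), 1:5)
  }
})

test_that("generation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- toy_config(4, rng_seed = 9)
  write_synthetic_dataset(d1, cfg)
  write_synthetic_dataset(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  g1 <- generate_array(toy_config(4, rng_seed = 10))
  expect_false(identical(g1$array$sequence,
                         generate_array(cfg)$array$sequence))
})

test_that("noise-free fingerprints recover planted expression exactly up to
           one global scale per treatment", {
  levels <- matrix(c(4, 1, 0.25, 8,
                     4, 2, 2, 0), 4, 2,
                   dimnames = list(paste0("c", 1:4), c("ctrl", "stress")))
  cfg <- toy_config(4, levels = levels, noise_sigma = 0)
  gen <- generate_array(cfg)
  scm <- build_size_classes(predict_amplicons(gen$array))
  sim <- simulate_fingerprints(gen$truth, cfg)
  for (t in colnames(levels)) {
    res <- analyse_sample_set(
      Filter(function(f) f$treatment == t, sim$fingerprints),
      scm, sim$ladder)
    # reorder profile rows to class order
    ord <- match(gen$truth$classes$length, res$profile$length)
    got <- res$profile$ratio[ord]
    want <- levels[, t]
    on <- want > 0
    expect_equal(got[on] / got[on][1],
                 unname(want[on] / want[on][1]), tolerance = 1e-9)
    expect_true(all(is.na(got[!on])))
  }
})

test_that("replicate noise reproduces the configured %SE and converges", {
  cfg <- generator_config()
  gen <- generate_array(cfg)
  scm <- build_size_classes(predict_amplicons(gen$array, max_mismatch = 1))
  pct_se <- function(n_rep, seed) {
    cfg2 <- cfg
    cfg2$replicate_n <- n_rep
    sim <- simulate_fingerprints(gen$truth, cfg2, treatments = "28C",
                                 seed = seed)
    g <- Filter(function(f) f$material == "gDNA", sim$fingerprints)
    raw <- lapply(lapply(g, calibrate_sizes, ladder = sim$ladder),
                  bin_to_continuum)
    norm <- lapply(raw, normalize_fingerprint)
    cls <- match_classes(aggregate_replicates(norm, raw = raw), scm)
    mean(cls$pct_se[cls$detected], na.rm = TRUE)
  }
  triplicate <- median(vapply(401:405, function(s) pct_se(3, s), numeric(1)))
  expect_equal(triplicate, 12, tolerance = 0.2)
  # at n = 30 the %SE shrinks roughly as sqrt(3/30)
  large_n <- pct_se(30, 406)
  expect_equal(large_n, 12 * sqrt(3 / 30), tolerance = 0.25)
})

test_that("planted contamination fails the sample-set QC", {
  cfg <- toy_config(3)
  cfg$contamination <- list(treatment = "ctrl", material = "RNA",
                            size = 200, height = 500)
  gen <- generate_array(cfg)
  sim <- simulate_fingerprints(gen$truth, cfg)
  ctrl <- lapply(Filter(function(f) f$treatment == "ctrl", sim$fingerprints),
                 calibrate_sizes, ladder = sim$ladder)
  expect_false(check_contamination(ctrl)$pass)
  clean <- lapply(Filter(function(f) f$treatment == "stress",
                         sim$fingerprints),
                  calibrate_sizes, ladder = sim$ladder)
  expect_true(check_contamination(clean)$pass)
})
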