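# Analytical core: QC, normalization, replicate statistics, class matching,
# expression ratios, conditional calls, blocs, candidate promoter regions.

cal_fp <- function(material, size = numeric(), height = numeric(),
                   treatment = "t", rep = 1) {
  fingerprint(paste0(material, rep), material, treatment, rep,
              data.frame(size = size, height = height), calibrated = TRUE)
}

test_that("contamination QC matches the direct control-peak predicate", {
  cfg <- analysis_config()
  clean <- list(cal_fp("gDNA", 300, 1000), cal_fp("RNA"), cal_fp("water"))
  expect_true(check_contamination(clean, cfg)$pass)

  dirty <- list(cal_fp("gDNA", 300, 1000),
                cal_fp("RNA", 200, 10 * cfg$detect_height_min))
  res <- check_contamination(dirty, cfg)
  expect_false(res$pass)
  expect_equal(res$evidence$size, 200)

  expect_error(check_contamination(list(cal_fp("gDNA", 300, 10))),
               "control")

  set.seed(31)
  for (rep in 1:20) {
    sizes <- runif(5, 20, 1100)
    heights <- rexp(5, 1 / 60)
    fps <- list(cal_fp("RNA", sizes, heights), cal_fp("gDNA", 500, 900))
    want <- !any(sizes > cfg$norm_floor_bp &
                   heights >= cfg$detect_height_min)
    expect_equal(check_contamination(fps, cfg)$pass, want)
  }
})

test_that("normalization scales above-floor mass to exactly 1", {
  cfg <- analysis_config()
  one <- normalize_fingerprint(toy_binned(150, 37), cfg)
  expect_equal(unname(one$bins["150"]), 1)

  # peaks at/below the 90 bp floor are excluded from the normalizer
  two <- normalize_fingerprint(toy_binned(c(80, 150), c(5, 10)), cfg)
  expect_equal(unname(two$bins["150"]), 1)
  expect_equal(unname(two$bins["80"]), 0.5)

  set.seed(12)
  for (rep in 1:10) {
    bf <- toy_binned(runif(30, 95, 1050), rexp(30, 1 / 50))
    nf <- normalize_fingerprint(bf, cfg)
    bp <- as.integer(names(nf$bins))
    expect_equal(sum(nf$bins[bp > cfg$norm_floor_bp]), 1, tolerance = 1e-12)
  }

  expect_error(normalize_fingerprint(toy_binned(60, 10), cfg), "empty PCR")
})

test_that("significance threshold follows 1 + z * SE", {
  expect_equal(derive_threshold(50, 1.96), 1.98)
  expect_equal(round(derive_threshold(50, 1.96), 1),
               analysis_config()$conditional_fold)
  expect_equal(round(derive_threshold(12, 1.96), 2), 1.24)
  expect_lt(derive_threshold(1e-9), 1 + 1e-10)  # -> 1 as SE -> 0
})

test_that("replicate statistics give per-bin mean, SE and %SE", {
  reps <- list(toy_binned(200, 8), toy_binned(200, 10), toy_binned(200, 12))
  st <- aggregate_replicates(reps)
  i <- which(st$bp == 200)
  expect_equal(st$mean[i], 10)
  expect_equal(st$se[i], 2 / sqrt(3))          # sample sd 2, n = 3
  expect_equal(st$pct_se[i], 100 * 2 / sqrt(3) / 10, tolerance = 1e-12)
  expect_true(is.na(st$pct_se[which(st$bp == 300)]))

  same <- aggregate_replicates(list(toy_binned(200, 5), toy_binned(200, 5)))
  expect_true(all(same$se == 0))
  expect_error(aggregate_replicates(list(toy_binned(200, 5))), "replicates")
})

test_that("class matching folds the +1 bp poly-A satellite into its class", {
  cfg <- analysis_config()
  scm <- build_size_classes(data.frame(length = c(300, 302),
                                       cassette = 1:2))
  # signal only at L+1 is fully assigned to class L
  st <- aggregate_replicates(list(toy_binned(301, 10), toy_binned(301, 10)))
  m <- match_classes(st, scm, cfg)
  expect_equal(m$mean_norm[m$length == 300], 10)
  expect_equal(m$mean_norm[m$length == 302], 0)

  # window semantics: bin at L and L+1 summed per class
  st2 <- aggregate_replicates(list(toy_binned(c(300, 301, 302), c(6, 4, 9)),
                                   toy_binned(c(300, 301, 302), c(6, 4, 9))))
  m2 <- match_classes(st2, scm, cfg)
  expect_equal(m2$mean_norm, c(10, 9))
  expect_length(attr(m2, "unassigned"), 0)
})

test_that("class matching equals brute-force nearest assignment with the
           smaller-length tie rule", {
  cfg <- analysis_config(match_window = c(-1, 0, 1))
  set.seed(77)
  for (rep in 1:10) {
    lens <- sort(sample(seq(100, 160, 1), 8))
    scm <- build_size_classes(data.frame(length = lens,
                                         cassette = seq_along(lens)))
    bp <- sample(95:165, 15)
    h <- rexp(15, 1 / 20)
    st <- aggregate_replicates(list(toy_binned(bp, h), toy_binned(bp, h)))
    got <- match_classes(st, scm, cfg)
    # independent assignment
    want <- numeric(length(lens))
    for (k in seq_along(bp)) {
      b <- floor(bp[k] + 0.5)
      cand <- which((b - lens) %in% cfg$match_window)
      if (length(cand) == 0) next
      best <- cand[order(abs(b - lens[cand]), lens[cand])][1]
      want[best] <- want[best] + h[k]
    }
    expect_equal(got$mean_norm, want)
  }
})

test_that("expression ratios use gDNA stoichiometry and invert under swap", {
  cfg <- analysis_config()
  scm <- build_size_classes(data.frame(length = c(200, 300, 400),
                                       cassette = 1:3))
  mk <- function(h) {
    raw <- list(toy_binned(c(200, 300, 400), h),
                toy_binned(c(200, 300, 400), h))
    norm <- lapply(raw, normalize_fingerprint, cfg = cfg)
    match_classes(aggregate_replicates(norm, raw = raw), scm, cfg)
  }
  g <- mk(c(1000, 1000, 1000))
  c_same <- mk(c(1000, 1000, 1000))
  expect_equal(compute_expression(c_same, g, cfg)$ratio, rep(1, 3))

  c_var <- mk(c(2000, 1000, 500))
  fwd <- compute_expression(c_var, g, cfg)$ratio
  bwd <- compute_expression(g, c_var, cfg)$ratio
  expect_equal(fwd * bwd, rep(1, 3))

  # undetected gDNA class -> NA ratio, never zero
  g2 <- mk(c(1000, 1000, 10))
  p <- compute_expression(c_var, g2, cfg)
  expect_true(is.na(p$ratio[3]))
  expect_false(p$gdna_detected[3])
})

test_that("conditional calls implement the fold rule and its edge cases", {
  cfg <- analysis_config()
  scm <- build_size_classes(data.frame(length = c(200, 300), cassette = 1:2))
  prof <- function(r, det = !is.na(r)) {
    structure(data.frame(length = c(200, 300), n_members = 1, unique = TRUE,
                         members = I(list(1, 2)), gdna_detected = TRUE,
                         cdna_detected = det, ratio = r),
              class = c("expression_profile", "data.frame"))
  }
  same <- call_conditional(list(a = prof(c(1, 2)), b = prof(c(1, 2))), cfg)
  expect_equal(same$call, rep("constitutive", 2))

  ind <- call_conditional(list(a = prof(c(1, 1)), b = prof(c(11.4, 1.5))),
                          cfg)
  expect_equal(ind$call, c("conditional", "constitutive"))
  expect_equal(ind$max_fold, c(11.4, 1.5))
  expect_equal(ind$treatment_max[1], "b")

  onoff <- call_conditional(list(a = prof(c(NA, 1)), b = prof(c(3, 1))), cfg)
  expect_equal(onoff$call[1], "conditional_from_undetectable")

  never <- call_conditional(list(a = prof(c(NA, 1)), b = prof(c(NA, 1))),
                            cfg)
  expect_equal(never$call[1], "not_detected")

  # monotonicity: growing a planted fold never demotes conditional calls
  folds <- c(2, 2.5, 4, 8, 16)
  calls <- vapply(folds, function(f) {
    call_conditional(list(a = prof(c(1, 1)), b = prof(c(f, 1))), cfg)$call[1]
  }, "")
  expect_true(all(calls == "conditional"))
})

test_that("bloc detection equals exhaustive enumeration of maximal runs", {
  cfg <- analysis_config()
  scm4 <- build_size_classes(data.frame(length = c(110, 120, 130, 140),
                                        cassette = 1:4))
  prof4 <- structure(
    data.frame(length = c(110, 120, 130, 140), n_members = 1, unique = TRUE,
               members = I(as.list(1:4)), gdna_detected = TRUE,
               cdna_detected = TRUE, ratio = c(2, 2.5, 3, 50)),
    class = c("expression_profile", "data.frame"))
  b <- detect_blocs(prof4, scm4, cfg)
  expect_equal(b[, c("start", "end")], data.frame(start = 1L, end = 3L))

  set.seed(55)
  for (rep in 1:15) {
    n <- 12
    ratio <- ifelse(runif(n) < 0.6, round(exp(runif(n, 0, 3)), 2), NA)
    neutral <- is.na(ratio) & runif(n) < 0.4
    lens <- seq(100, by = 10, length.out = n)
    cassette <- 1:n
    # ambiguous classes get a fake second member to mark them non-unique
    members <- lapply(1:n, function(i) if (neutral[i]) c(i, 100 + i) else i)
    scm <- data.frame(length = lens, n_members = lengths(members),
                      unique = lengths(members) == 1, members = I(members))
    prof <- structure(
      data.frame(length = lens, n_members = scm$n_members,
                 unique = scm$unique, members = I(members),
                 gdna_detected = TRUE, cdna_detected = !is.na(ratio),
                 ratio = ratio),
      class = c("expression_profile", "data.frame"))
    got <- detect_blocs(prof, scm, cfg)
    want <- oracle_blocs(ratio, neutral, cfg$bloc_fold)
    expect_equal(got[, c("start", "end")],
                 want[, c("start", "end")], ignore_attr = TRUE)
  }
})

test_that("candidate promoter regions equal the direct predicate", {
  mk_calls <- function(call, gdna) {
    data.frame(length = seq_along(call) * 10 + 100, unique = TRUE,
               gdna_detected = gdna, n_expressed = NA, max_fold = NA,
               treatment_max = NA, call = call)
  }
  mk_scm <- function(n) {
    data.frame(length = seq_len(n) * 10 + 100, n_members = 1, unique = TRUE,
               members = I(as.list(seq_len(n))))
  }
  all_expr <- mk_calls(rep("constitutive", 5), rep(TRUE, 5))
  expect_length(candidate_promoter_regions(all_expr, mk_scm(5)), 0)

  # silent cassette flanked by expressed neighbours is reported
  calls <- mk_calls(c("conditional", "not_detected", "conditional",
                      "not_detected", "not_detected"),
                    c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(candidate_promoter_regions(calls, mk_scm(5)), c(2L, 4L))

  set.seed(99)
  states <- c("not_detected", "constitutive", "conditional")
  for (rep in 1:15) {
    n <- 10
    call <- sample(states, n, replace = TRUE)
    gdna <- runif(n) < 0.8
    got <- candidate_promoter_regions(mk_calls(call, gdna), mk_scm(n))
    expressed <- gdna & call != "not_detected"
    want <- which(vapply(seq_len(n), function(p) {
      nb <- c(p - 1, p + 1)
      nb <- nb[nb >= 1 & nb <= n]
      gdna[p] && call[p] == "not_detected" && any(expressed[nb])
    }, logical(1)))
    expect_equal(got, want)
  }
})
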