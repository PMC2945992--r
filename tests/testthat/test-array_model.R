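# In-silico attC PCR: primer expansion, site search, amplicon prediction and
# size-class construction.

test_that("degenerate expansion enumerates exactly the IUPAC variants", {
  expect_equal(expand_degenerate("ACGT"), "ACGT")

  primers <- attc_primers()
  yb4 <- expand_degenerate(primers$fwd)
  yb3 <- expand_degenerate(primers$rev)
  expect_length(yb4, 48)   # M,R,Y,D,S -> 2*2*2*3*2
  expect_length(yb3, 96)   # M,R,R,Y,D,S -> 2*2*2*2*3*2
  expect_setequal(yb4, oracle_expand(primers$fwd$iupac_seq))
  expect_setequal(yb3, oracle_expand(primers$rev$iupac_seq))

  # cardinality equals the analytic degeneracy product for arbitrary strings
  set.seed(7)
  codes <- names(ORACLE_IUPAC)
  for (i in 1:10) {
    s <- paste(sample(codes, sample(3:9, 1), replace = TRUE), collapse = "")
    expect_length(expand_degenerate(s),
                  prod(lengths(ORACLE_IUPAC[strsplit(s, "")[[1]]])))
  }

  expect_error(degenerate_primer("bad", "ACGU"), "IUPAC")
})

test_that("primer site search finds planted sites on both strands", {
  primers <- attc_primers()
  set.seed(11)
  variant <- sample(expand_degenerate(primers$fwd), 1)
  seq <- paste0(rand_seq(10), variant, rand_seq(30))
  hits <- find_primer_sites(seq, primers$fwd, max_mismatch = 0)
  expect_true(any(hits$start == 11 & hits$strand == 1))

  rc_variant <- oracle_revcomp(sample(expand_degenerate(primers$rev), 1))
  seq2 <- paste0(rc_variant, rand_seq(25))
  hits2 <- find_primer_sites(seq2, primers$rev, max_mismatch = 0)
  expect_true(any(hits2$start == 1 & hits2$strand == -1))
})

test_that("primer site search equals the exhaustive window-vs-expansion scan", {
  primers <- attc_primers()
  set.seed(42)
  for (mm in 0:1) {
    seq <- paste0(rand_seq(800),
                  sample(expand_degenerate(primers$fwd), 1),
                  rand_seq(400),
                  oracle_revcomp(sample(expand_degenerate(primers$fwd), 1)),
                  rand_seq(800))
    got <- find_primer_sites(seq, primers$fwd, max_mismatch = mm)
    want <- oracle_find_sites(seq, primers$fwd$iupac_seq, mm)
    expect_equal(got, want, info = paste("max_mismatch =", mm))
  }
})

test_that("amplicon prediction pairs each forward site with the nearest
           downstream reverse site", {
  cfg <- toy_config(3)
  gen <- generate_array(cfg)
  amp <- predict_amplicons(gen$array)
  expect_equal(nrow(amp), 3)
  expect_setequal(amp$length, gen$truth$classes$length)
  expect_equal(sort(amp$cassette), 1:3)

  # brute-force pairing oracle on the same sites
  primers <- attc_primers()
  f <- find_primer_sites(gen$array$sequence, primers$fwd)
  f <- f[f$strand == 1, ]
  r <- find_primer_sites(gen$array$sequence, primers$rev)
  r <- r[r$strand == -1, ]
  want <- oracle_pair_amplicons(f, r, 1100)
  expect_equal(amp$fwd_start, want$fwd_start)
  expect_equal(amp$length, want$length)
})

test_that("prediction is invariant under non-matching flanking sequence", {
  cfg <- toy_config(3)
  gen <- generate_array(cfg)
  amp <- predict_amplicons(gen$array)
  pad <- strrep("A", 400)
  arr2 <- gen$array
  arr2$sequence <- paste0(pad, arr2$sequence, pad)
  arr2$cassettes[c("start", "end", "orf_start", "orf_end", "attc_start",
                   "attc_end")] <-
    arr2$cassettes[c("start", "end", "orf_start", "orf_end", "attc_start",
                     "attc_end")] + 400L
  amp2 <- predict_amplicons(arr2)
  expect_equal(amp2$length, amp$length)
  expect_equal(amp2$cassette, amp$cassette)
  expect_equal(amp2$fwd_start, amp$fwd_start + 400L)
})

test_that("size classes partition amplicons and flag uniqueness", {
  amp <- data.frame(length = c(100, 200, 300), cassette = 1:3)
  scm <- build_size_classes(amp)
  expect_equal(nrow(scm), 3)
  expect_true(all(scm$unique))

  amp2 <- data.frame(length = c(250, 250, 300), cassette = c(1, 5, 2))
  scm2 <- build_size_classes(amp2)
  expect_equal(scm2$n_members, c(2L, 1L))
  expect_equal(scm2$unique, c(FALSE, TRUE))
  expect_equal(scm2$members[[1]], c(1, 5))

  # membership covers every amplifiable cassette exactly once
  cfg <- generator_config()
  gen <- generate_array(cfg)
  scm3 <- build_size_classes(predict_amplicons(gen$array, max_mismatch = 1))
  expect_equal(sort(unlist(scm3$members)), 1:116)
  expect_equal(sum(scm3$n_members), 116)
  expect_equal(sum(scm3$unique) + sum(!scm3$unique), nrow(scm3))
})

test_that("array FASTA + annotation round-trips through files", {
  cfg <- toy_config(3)
  gen <- generate_array(cfg)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cassette_array(gen$array, fa, tsv)
  back <- read_cassette_array(fa, tsv)
  expect_equal(back$sequence, gen$array$sequence)
  expect_equal(back$cassettes, gen$array$cassettes)
})
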