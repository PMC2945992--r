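# Synthetic-data generator: builds a DAT722-like cassette array whose
# in-silico attC PCR reproduces a configured size-class structure, plants a
# ground-truth expression program over stress-treatment series, and simulates
# noisy replicate fingerprints, nested-PCR observations and qPCR Ct tables.

# ---- packaged reference ground truth ---------------------------------------

# Position layout of the reference array: which cassette positions form which
# size classes, which classes the wet PCR can amplify, coding status and ORF
# strand.  The printed array statistics fix the arithmetic: 116 positions in
# 90 classes (75 unique + 15 ambiguous); 62 classes detectable (50 unique +
# 12 ambiguous); 74 accessible positions imply the 12 detectable ambiguous
# classes have two members each, leaving 17 members across the 3 undetectable
# ambiguous classes (6+6+5); 91 coding / 25 non-coding, 8 coding on the
# reverse strand (placed in undetectable classes, since the attC PCR cannot
# attribute expression to reverse-strand genes).
reference_layout <- function() {
  unique_expressed <- c(2, 5, 10, 11, 18, 20, 21, 22, 23, 31, 32, 33, 34, 35,
                        40, 42, 52, 54, 55, 57, 59, 66, 70, 88, 90, 92, 94,
                        95, 98, 102, 104, 107, 110, 113, 115)
  unique_stress <- c(7, 14, 26, 48, 63, 72, 84)
  unique_never <- c(19, 36, 60, 96, 99, 106, 108, 109)
  amb_detected <- list(a1 = c(3, 43), a2 = c(4, 44), a3 = c(6, 46),
                       a4 = c(13, 53), a5 = c(8, 49), a6 = c(9, 50),
                       a7 = c(16, 56), a8 = c(24, 64), a9 = c(25, 65),
                       a10 = c(27, 69), a11 = c(28, 71), a12 = c(30, 74))
  amb_undetected <- list(u1 = c(75, 76, 77, 78, 79, 80),
                         u2 = c(81, 82, 83, 85, 86, 87),
                         u3 = c(37, 38, 39, 41, 45))
  unique_undetected <- c(1, 12, 15, 17, 29, 47, 51, 58, 61, 62, 67, 68, 73,
                         89, 91, 93, 97, 100, 101, 103, 105, 111, 112, 114,
                         116)
  noncoding <- c(2, 5, 26, 40, 48, 66, 88, 102, 113,
                 12, 15, 29, 47, 51, 58, 61, 62, 67, 68, 73, 89, 91, 93,
                 97, 100)
  reverse_orf <- 75:82

  uniq <- sort(c(unique_expressed, unique_stress, unique_never,
                 unique_undetected))
  classes <- rbind(
    data.frame(class_id = paste0("c", uniq),
               detected = uniq %in% c(unique_expressed, unique_stress,
                                      unique_never),
               members = I(as.list(uniq))),
    data.frame(class_id = names(amb_detected), detected = TRUE,
               members = I(amb_detected)),
    data.frame(class_id = names(amb_undetected), detected = FALSE,
               members = I(amb_undetected))
  )
  all_members <- unlist(classes$members)
  stopifnot(sort(all_members) == 1:116, nrow(classes) == 90,
            sum(lengths(classes$members) == 1) == 75,
            sum(classes$detected) == 62)

  pos_class <- character(116)
  for (i in seq_len(nrow(classes))) {
    pos_class[classes$members[[i]]] <- classes$class_id[i]
  }
  positions <- data.frame(
    index = 1:116,
    class_id = pos_class,
    orf_present = !(1:116 %in% noncoding),
    orf_strand = ifelse(1:116 %in% reverse_orf, -1L, 1L),
    amplifiable = pos_class %in% classes$class_id[classes$detected]
  )
  positions$orf_strand[!positions$orf_present] <- NA_integer_
  stopifnot(sum(positions$orf_present) == 91,
            sum(!positions$orf_present) == 25,
            sum(positions$orf_present & positions$orf_strand == -1L,
                na.rm = TRUE) == 8,
            sum(positions$amplifiable) == 74)
  list(positions = positions, classes = classes)
}

# Ground-truth expression program of the reference study: relative cDNA
# abundance per detectable size class under each treatment.  Treatments other
# than the optimal-growth baseline are built from the baseline by explicit
# abundance *transfers* (from, to, amount), so every treatment conserves the
# summed transcript mass and the above-90 bp normalization sum is an exact
# cross-treatment standard.  Planted anchors: 39 classes expressed at 28C;
# 128-fold dynamic range between the classes of cassettes 95 and 11; classes
# of cassettes 23 and 70 constitutive; the class of cassette 57 induced
# 11.4-fold across the 18 h oxidative series (the study-wide maximum); the
# classes of cassettes 10/20/104 strongly induced under other stressors; the
# class of cassette 11 undetectable under oxidative stress.
reference_expression <- function(classes) {
  treatments <- c("4C", "14C", "28C",
                  paste0("H2O2_", c("0.0", "0.9", "1.8", "3.6"), "mM_30min"),
                  paste0("H2O2_", c("0.0", "0.9", "1.8", "3.6"), "mM_18h"))
  base <- c(c2 = 8, c5 = 8, c10 = 3, c11 = 1, c18 = 25, c20 = 4, c21 = 40,
            c22 = 35, c23 = 30, c31 = 4, c32 = 5, c33 = 6, c34 = 5, c35 = 4,
            c40 = 12, c42 = 12, c52 = 10, c54 = 10, c55 = 16, c57 = 2,
            c59 = 16, c66 = 20, c70 = 5, c88 = 6, c90 = 6, c92 = 28,
            c94 = 9, c95 = 128, c98 = 9, c102 = 14, c104 = 5, c107 = 7,
            c110 = 7, c113 = 11, c115 = 11,
            a1 = 10, a4 = 10, a8 = 3, a12 = 3)
  tr <- function(from, to, amount) data.frame(from, to, amount)
  transfers <- list(
    "14C" = rbind(
      tr("c92", "c10", 7), tr("c66", "c11", 1.5), tr("c2", "c5", 5.6),
      tr("c88", "c90", 4), tr("c113", "c115", 6.6), tr("c94", "c98", 6.3),
      tr("c55", "a3", 10)),
    "4C" = rbind(
      tr("c95", "c7", 40), tr("c95", "c14", 43),
      tr("c40", "c18", 8), tr("c42", "c18", 8), tr("c52", "c18", 6),
      tr("c54", "c18", 6), tr("c102", "c18", 10),
      tr("c92", "c104", 18), tr("c59", "c104", 13), tr("c55", "c104", 12),
      tr("c21", "a2", 24),
      tr("c66", "c31", 6), tr("c66", "c32", 6), tr("c94", "c32", 1.5),
      tr("c22", "c33", 9), tr("c22", "c34", 2), tr("a1", "c34", 5.5),
      tr("a1", "c35", 1.5), tr("c94", "c35", 4.5)),
    "H2O2_0.9mM_30min" = rbind(
      tr("c107", "c26", 5), tr("c11", "c26", 1), tr("c5", "c110", 6),
      tr("c92", "c110", 5)),
    "H2O2_1.8mM_30min" = rbind(
      tr("c66", "c48", 12), tr("c11", "c48", 1), tr("c21", "a5", 15),
      tr("c2", "c20", 6)),
    "H2O2_3.6mM_30min" = rbind(
      tr("c95", "c20", 29), tr("c115", "c20", 7), tr("c22", "c63", 24),
      tr("c11", "c63", 1), tr("c55", "a6", 10), tr("c59", "a6", 10),
      tr("a4", "a7", 7), tr("c40", "a7", 5), tr("c92", "a8", 6),
      tr("c98", "c90", 7), tr("c94", "c90", 3), tr("c52", "a12", 5)),
    "H2O2_0.9mM_18h" = rbind(
      tr("c92", "c57", 1), tr("c11", "c72", 1), tr("c21", "c72", 7)),
    "H2O2_1.8mM_18h" = rbind(
      tr("c92", "c57", 6), tr("c11", "a9", 1), tr("c66", "a9", 14)),
    "H2O2_3.6mM_18h" = rbind(
      tr("c92", "c57", 14), tr("c102", "c57", 6.8), tr("c11", "c84", 1),
      tr("c95", "c84", 24), tr("c55", "a10", 12), tr("c21", "a11", 10))
  )
  expr <- matrix(0, nrow = nrow(classes), ncol = length(treatments),
                 dimnames = list(classes$class_id, treatments))
  expr[names(base), ] <- base
  for (t in names(transfers)) {
    for (i in seq_len(nrow(transfers[[t]]))) {
      mv <- transfers[[t]][i, ]
      expr[mv$from, t] <- expr[mv$from, t] - mv$amount
      expr[mv$to, t] <- expr[mv$to, t] + mv$amount
    }
  }
  stopifnot(all(expr >= 0),
            max(abs(colSums(expr) - sum(base))) < 1e-9,
            sum(expr[, "28C"] > 0) == 39)
  expr
}

reference_series <- function() {
  list(thermal = c("4C", "14C", "28C"),
       oxidative_30min = paste0("H2O2_", c("0.0", "0.9", "1.8", "3.6"),
                                "mM_30min"),
       oxidative_18h = paste0("H2O2_", c("0.0", "0.9", "1.8", "3.6"),
                              "mM_18h"))
}

#' Synthetic-study generator configuration
#'
#' The default configuration is the packaged reference study: a 116-cassette
#' array in 90 size classes (75 unique), 91 coding / 25 non-coding cassettes
#' with 8 reverse-strand ORFs, 62 classes amplifiable by the wet attC PCR, a
#' planted expression program over a thermal and two oxidative stress series
#' (39 classes expressed under optimal growth, 128-fold dynamic range,
#' 11.4-fold maximal induction, two constitutive classes), a sigma-70
#' consensus promoter bridging the cassette 20/21 attC junction with 40-fold
#' downstream qPCR activity, and replicate noise calibrated to average about
#' 12 %SE across detected classes at n = 3.
#'
#' @param positions,classes Layout tables (defaults: the reference layout).
#'   `positions` has one row per cassette (`index`, `class_id`,
#'   `orf_present`, `orf_strand`, `amplifiable`); `classes` one row per size
#'   class (`class_id`, `detected`, list-column `members`).
#' @param expression Abundance matrix, classes x treatments.
#' @param series Named list of treatment-label vectors, one per stressor
#'   series.
#' @param noise_sigma Lognormal sd of the multiplicative per-amplicon
#'   replicate noise.
#' @param replicate_n PCR replicates per sample (default 3).
#' @param polya_frac Fraction of each amplicon's product carrying the +1 bp
#'   poly-A tail (default 0.5).
#' @param height_scale Fluorescence units per abundance unit (default 1000).
#' @param rng_seed Seed making every generated artefact deterministic.
#' @param attc_mid_len Length of the attC segment between the two primer
#'   sites (default 40 bp, giving 83 bp attC sites).
#' @param flank_len Random flanking sequence on each side of the array.
#' @param len_range Amplicon length range (bp) the class lengths are drawn
#'   from; lengths are distinct even integers so a +1 bp poly-A satellite can
#'   never collide with a neighbouring class.
#' @param promoter Planted promoter truth: list with `junction` (cassette
#'   index whose downstream attC carries the promoter), `fold`
#'   (downstream:bridging transcript ratio), `efficiency`, `ct_sd`, `c0`
#'   (qPCR model), or `NULL` for none.
#' @param contamination Optional planted control contamination: list with
#'   `treatment`, `material` (`"RNA"`/`"water"`), `size` (bp), `height`.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(positions = NULL, classes = NULL,
                             expression = NULL, series = reference_series(),
                             noise_sigma = 0.238, replicate_n = 3,
                             polya_frac = 0.5, height_scale = 1000,
                             rng_seed = 722, attc_mid_len = 40,
                             flank_len = 150, len_range = c(150, 1000),
                             promoter = list(junction = 20, fold = 40,
                                             efficiency = 2, ct_sd = 0.1,
                                             c0 = 30),
                             contamination = NULL) {
  if (is.null(positions) || is.null(classes)) {
    lay <- reference_layout()
    positions <- positions %||% lay$positions
    classes <- classes %||% lay$classes
  }
  if (is.null(expression)) expression <- reference_expression(classes)
  n <- nrow(positions)
  stopifnot(identical(as.integer(positions$index), seq_len(n)),
            all(positions$class_id %in% classes$class_id),
            all(sort(unlist(classes$members)) == seq_len(n)),
            all(expression >= 0),
            nrow(expression) == nrow(classes),
            identical(rownames(expression), classes$class_id),
            replicate_n >= 1, noise_sigma >= 0,
            polya_frac >= 0, polya_frac < 1,
            nrow(classes) <= length(seq(len_range[1], len_range[2], 2)))
  if (!is.null(promoter)) {
    stopifnot(promoter$junction %in% positions$index,
              promoter$fold > 0, attc_mid_len >= 33)
  }
  structure(list(positions = positions, classes = classes,
                 expression = expression, series = series,
                 noise_sigma = noise_sigma, replicate_n = replicate_n,
                 polya_frac = polya_frac, height_scale = height_scale,
                 rng_seed = rng_seed, attc_mid_len = attc_mid_len,
                 flank_len = flank_len, len_range = len_range,
                 promoter = promoter, contamination = contamination),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", nrow(x$positions), "cassettes in",
      nrow(x$classes), "size classes (", sum(x$classes$detected),
      "amplifiable ),", ncol(x$expression), "treatments, noise sigma",
      x$noise_sigma, "\n")
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# introduce exactly one mismatch into a concrete primer-site sequence: at
# `at`, substitute a base incompatible with the primer's IUPAC code there
mismatch_site <- function(site, iupac, at) {
  code <- substr(iupac, at, at)
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
  substr(site, at, at) <- setdiff(c("A", "C", "G", "T"), allowed)[1]
  site
}

#' Generate a synthetic cassette array with planted primer sites
#'
#' Builds a random-background array in which every attC junction carries a
#' concrete variant of the reverse (YB3, minus strand) and forward (YB4)
#' primer sites, so that amplicon lengths are controlled exactly by cassette
#' body lengths.  Cassettes of undetectable size classes get a single planted
#' mismatch in their forward primer site: in-silico prediction at one
#' tolerated mismatch still sees them, the zero-mismatch wet PCR does not.
#' The configured promoter consensus is planted inside the attC of the
#' configured junction.  Deterministic under `cfg$rng_seed`.
#'
#' @param cfg A [generator_config()].
#' @return List with `array` (a [cassette_array()]) and `truth` (class
#'   `ground_truth`): the realised class lengths, layout, expression program,
#'   promoter location and transcript start.
#' @export
generate_array <- function(cfg) {
  with_seed(cfg$rng_seed, {
    primers <- attc_primers()
    yb4 <- expand_degenerate(primers$fwd)
    yb3 <- expand_degenerate(primers$rev)
    n_cass <- nrow(cfg$positions)
    n_cls <- nrow(cfg$classes)
    lens <- sample(seq(cfg$len_range[1], cfg$len_range[2], 2), n_cls)
    classes <- cfg$classes
    classes$length <- lens
    cls_len <- stats::setNames(lens, classes$class_id)
    overhead <- nchar(primers$fwd$iupac_seq) + nchar(primers$rev$iupac_seq)
    body_len <- cls_len[cfg$positions$class_id] - overhead
    stopifnot(all(body_len >= 76))  # room for a 60 bp ORF at offset 15

    make_attc <- function(j) {
      mid <- rand_dna(cfg$attc_mid_len)
      if (!is.null(cfg$promoter) && j == cfg$promoter$junction) {
        substr(mid, 4, 9) <- "TTGACA"
        substr(mid, 27, 32) <- "TATAAT"
      }
      fwd_site <- sample(yb4, 1)
      # the forward site in attC j belongs to cassette j+1's amplicon
      if (j < n_cass && !cfg$positions$amplifiable[j + 1]) {
        fwd_site <- mismatch_site(fwd_site, primers$fwd$iupac_seq, 10)
      }
      paste0(rc(sample(yb3, 1)), mid, fwd_site)
    }

    pieces <- character(2 * n_cass + 3)
    pieces[1] <- rand_dna(cfg$flank_len)
    pieces[2] <- make_attc(0)
    for (i in seq_len(n_cass)) {
      pieces[2 * i + 1] <- rand_dna(body_len[i])
      pieces[2 * i + 2] <- make_attc(i)
    }
    pieces[2 * n_cass + 3] <- rand_dna(cfg$flank_len)
    seqs <- paste(pieces, collapse = "")

    attc_len <- cfg$attc_mid_len + overhead
    # offsets: piece k starts at cumsum of previous lengths + 1
    starts <- cumsum(c(1, nchar(pieces)))[seq_along(pieces)]
    body_start <- starts[2 * seq_len(n_cass) + 1]
    attc_start <- starts[2 * seq_len(n_cass) + 2]
    cass <- data.frame(
      index = cfg$positions$index,
      start = body_start,
      end = attc_start + attc_len - 1L,
      orf_present = cfg$positions$orf_present,
      orf_strand = cfg$positions$orf_strand,
      orf_start = ifelse(cfg$positions$orf_present, body_start + 15L, NA),
      orf_end = ifelse(cfg$positions$orf_present,
                       body_start + 15L + 59L, NA),
      attc_start = attc_start,
      attc_end = attc_start + attc_len - 1L
    )
    array <- cassette_array("synthetic_reference_array", seqs, cass,
                            integron_promoter_pos = 100L)

    promoter_truth <- NULL
    if (!is.null(cfg$promoter)) {
      j <- cfg$promoter$junction
      attc_j_start <- cass$attc_start[j]
      m35 <- attc_j_start + nchar(primers$rev$iupac_seq) + 3L
      m10 <- attc_j_start + nchar(primers$rev$iupac_seq) + 26L
      promoter_truth <- c(cfg$promoter,
                          list(minus35_offset = m35, minus10_offset = m10,
                               transcript_start = m10 + 5L + 7L))
    }
    truth <- structure(
      list(classes = classes, positions = cfg$positions,
           expression = cfg$expression, series = cfg$series,
           promoter = promoter_truth,
           contamination = cfg$contamination),
      class = "ground_truth")
    list(array = array, truth = truth)
  })
}

#' Simulate replicate fragment fingerprints from planted ground truth
#'
#' gDNA peak heights are proportional to per-class amplifiable copy number
#' (the stoichiometric standard); cDNA heights to the planted expression
#' abundance.  Each amplicon's product gets independent multiplicative
#' lognormal noise per replicate, and a `polya_frac` fraction of its mass is
#' shifted +1 bp (poly-A tailing).  Every sample set includes an RNA and a
#' water control, empty unless contamination is planted.  Peak sizes are
#' emitted in instrument migration units together with the ladder that maps
#' them back to bp (the synthetic instrument migrates linearly in size).
#'
#' @param truth `ground_truth` from [generate_array()].
#' @param cfg The [generator_config()].
#' @param treatments Treatment labels to simulate (default: all columns of
#'   the expression program).
#' @param seed RNG seed (default `cfg$rng_seed + 1`).
#' @return List with `fingerprints` (list of [fingerprint()]s, sizes in
#'   migration units) and `ladder` (a [ladder_calibration()]).
#' @export
simulate_fingerprints <- function(truth, cfg,
                                  treatments = colnames(truth$expression),
                                  seed = cfg$rng_seed + 1) {
  copies <- vapply(truth$classes$members, function(m) {
    sum(truth$positions$amplifiable[m])
  }, numeric(1))
  lens <- truth$classes$length
  migrate <- function(bp) 1200 - bp
  make_fp <- function(treatment, material, rep, abundance) {
    on <- which(abundance > 0)
    peaks <- if (length(on) > 0) {
      h <- abundance[on] * cfg$height_scale *
        exp(stats::rnorm(length(on), 0, cfg$noise_sigma))
      data.frame(
        size = migrate(c(lens[on], lens[on] + 1)),
        height = c(h * (1 - cfg$polya_frac), h * cfg$polya_frac))
    } else {
      data.frame(size = numeric(), height = numeric())
    }
    fingerprint(paste(treatment, material, rep, sep = "_"), material,
                treatment, rep, peaks, calibrated = FALSE)
  }
  fps <- list()
  with_seed(seed, {
    for (t in treatments) {
      for (r in seq_len(cfg$replicate_n)) {
        fps <- c(fps, list(make_fp(t, "gDNA", r, copies)))
        fps <- c(fps, list(make_fp(t, "cDNA", r,
                                   truth$expression[, t] * (copies > 0))))
      }
      for (ctrl in c("RNA", "water")) {
        peaks <- data.frame(size = numeric(), height = numeric())
        cont <- truth$contamination
        if (!is.null(cont) && cont$treatment == t &&
            cont$material == ctrl) {
          peaks <- data.frame(size = migrate(cont$size),
                              height = cont$height)
        }
        fps <- c(fps, list(fingerprint(paste(t, ctrl, 1, sep = "_"), ctrl,
                                       t, 1, peaks, calibrated = FALSE)))
      }
    }
  })
  bp_pts <- seq(50, 1100, 50)
  list(fingerprints = fps,
       ladder = ladder_calibration(migrate(bp_pts), bp_pts))
}

#' Simulate qPCR Ct values for the planted promoter
#'
#' Ct = c0 - log_E(relative abundance) + Gaussian noise; the
#' downstream:bridging abundance ratio equals the planted promoter activity.
#'
#' @param truth `ground_truth` with promoter truth set.
#' @param cfg The [generator_config()].
#' @param seed RNG seed (default `cfg$rng_seed + 2`).
#' @return `data.frame` with `primer_pair` (`"bridging"`/`"downstream"`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(truth, cfg, seed = cfg$rng_seed + 2) {
  p <- truth$promoter
  if (is.null(p)) stop("no promoter truth in this ground truth")
  ct0 <- function(abundance) p$c0 - log(abundance, base = p$efficiency)
  n <- cfg$replicate_n
  with_seed(seed, {
    data.frame(
      primer_pair = rep(c("bridging", "downstream"), each = n),
      replicate = rep(seq_len(n), 2),
      ct = c(ct0(1) + stats::rnorm(n, 0, p$ct_sd),
             ct0(p$fold) + stats::rnorm(n, 0, p$ct_sd)))
  })
}

#' Simulate nested-PCR promoter-localisation observations
#'
#' Places forward primer sites in the ORFs of the given cassettes and a
#' reverse primer at the end of the target cassette's ORF, then records which
#' pairs amplify: a cDNA pair amplifies iff both sites lie downstream of the
#' planted transcript start; every pair amplifies on gDNA.
#'
#' @param gen A [generate_array()] result.
#' @param fwd_cassettes Cassette indices carrying forward primers (default
#'   16:19 and 21, the bracket around the planted junction).
#' @param rev_cassette Cassette carrying the reverse primer (default 21).
#' @return List with `obs` (observations `data.frame`) and `primer_sites`
#'   (name/start/end table), ready for [infer_transcript_interval()].
#' @export
simulate_nested_pcr <- function(gen, fwd_cassettes = c(16:19, 21),
                                rev_cassette = 21) {
  cass <- gen$array$cassettes
  tss <- gen$truth$promoter$transcript_start
  if (is.null(tss)) stop("no promoter truth in this ground truth")
  sites <- rbind(
    data.frame(name = paste0("VhC", fwd_cassettes, "f"),
               start = cass$orf_start[fwd_cassettes],
               end = cass$orf_start[fwd_cassettes] + 19),
    data.frame(name = paste0("VhC", rev_cassette, "r"),
               start = cass$orf_end[rev_cassette] - 19,
               end = cass$orf_end[rev_cassette]))
  fwd_names <- paste0("VhC", fwd_cassettes, "f")
  rev_name <- paste0("VhC", rev_cassette, "r")
  obs <- rbind(
    data.frame(fwd = fwd_names, rev = rev_name, template = "cDNA",
               amplified = cass$orf_start[fwd_cassettes] >= tss),
    data.frame(fwd = fwd_names, rev = rev_name, template = "gDNA",
               amplified = TRUE))
  list(obs = obs, primer_sites = sites)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the array FASTA and annotation TSV, the primer table, the ladder
#' CSV, one peak-table CSV per stressor series, the qPCR Ct CSV, a
#' ground-truth YAML and a run manifest, so the file-based pipeline can be
#' run end to end.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [generator_config()].
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_dataset <- function(dir, cfg = generator_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_array(cfg)
  write_cassette_array(gen$array, file.path(dir, "array.fasta"),
                       file.path(dir, "cassettes.tsv"))
  primers <- attc_primers()
  utils::write.table(
    data.frame(name = c(primers$fwd$name, primers$rev$name),
               iupac_seq = c(primers$fwd$iupac_seq, primers$rev$iupac_seq),
               orientation = c("fwd", "rev"),
               label = c(primers$fwd$label, primers$rev$label)),
    file.path(dir, "primers.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sim <- simulate_fingerprints(gen$truth, cfg)
  utils::write.csv(data.frame(migration = sim$ladder$migration,
                              bp = sim$ladder$bp),
                   file.path(dir, "ladder.csv"), row.names = FALSE,
                   quote = FALSE)
  write_peak_table(sim$fingerprints, file.path(dir, "peaks.csv"))
  if (!is.null(cfg$promoter)) {
    utils::write.csv(simulate_qpcr(gen$truth, cfg),
                     file.path(dir, "qpcr.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  truth_dump <- list(
    classes = lapply(seq_len(nrow(gen$truth$classes)), function(i) {
      list(class_id = gen$truth$classes$class_id[i],
           length = gen$truth$classes$length[i],
           detected = gen$truth$classes$detected[i],
           members = as.integer(gen$truth$classes$members[[i]]))
    }),
    expression = apply(gen$truth$expression, 2, as.list),
    promoter = gen$truth$promoter,
    note = "synthetic emulation; no claim about any real cassette array")
  yaml::write_yaml(truth_dump, file.path(dir, "truth.yaml"))
  manifest <- list(
    array_fasta = "array.fasta", annotation = "cassettes.tsv",
    primers = "primers.tsv", peaks = "peaks.csv", ladder = "ladder.csv",
    qpcr = if (!is.null(cfg$promoter)) "qpcr.csv",
    series = cfg$series, seed = cfg$rng_seed,
    predict_max_mismatch = 1)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}
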