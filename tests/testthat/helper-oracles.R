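# Independent brute-force oracles and tiny fixture builders.  The oracles
# re-derive results from first principles (hand-coded IUPAC table, exhaustive
# window scans and enumerations) so they share no code path with the package.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expand <- function(iupac) {
  sets <- ORACLE_IUPAC[strsplit(iupac, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", sapply(lapply(strsplit(s, ""), rev), paste,
                                collapse = ""))
}

# exhaustive window-vs-expansion scan on both strands
oracle_find_sites <- function(seq, iupac, mm = 0) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  scan_one_strand <- function(patterns, strand) {
    L <- nchar(patterns[1])
    if (n < L) return(NULL)
    n_off <- n - L + 1
    best <- rep(L, n_off)
    for (p in patterns) {
      pc <- strsplit(p, "")[[1]]
      mism <- integer(n_off)
      for (j in seq_len(L)) {
        mism <- mism + (chars[j:(n_off + j - 1)] != pc[j])
      }
      best <- pmin(best, mism)
    }
    hit <- which(best <= mm)
    if (length(hit) == 0) return(NULL)
    data.frame(start = hit, end = hit + L - 1, strand = strand)
  }
  pats <- oracle_expand(iupac)
  out <- rbind(scan_one_strand(pats, 1L),
               scan_one_strand(oracle_revcomp(pats), -1L))
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = integer()))
  }
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# all fwd/rev site pairs filtered by max product length, keeping per forward
# site the shortest product
oracle_pair_amplicons <- function(fsites, rsites, max_len) {
  out <- NULL
  for (i in seq_len(nrow(fsites))) {
    lens <- rsites$end - fsites$start[i] + 1
    ok <- which(rsites$start > fsites$end[i] & lens <= max_len)
    if (length(ok) == 0) next
    j <- ok[which.min(lens[ok])]
    out <- rbind(out, data.frame(fwd_start = fsites$start[i],
                                 rev_end = rsites$end[j],
                                 length = lens[j]))
  }
  out
}

# exhaustive enumeration of maximal qualifying blocs over a per-position
# status vector: numeric ratio = expressed, NA_neutral = skipped, NA_break
oracle_blocs <- function(ratio, neutral, fold) {
  n <- length(ratio)
  expressed <- which(!is.na(ratio))
  qualifies <- function(i, j) {
    span <- i:j
    if (any(is.na(ratio[span]) & !neutral[span])) return(FALSE)
    mem <- span[!is.na(ratio[span])]
    if (length(mem) < 2 || i %in% mem == FALSE || j %in% mem == FALSE) {
      return(FALSE)
    }
    max(ratio[mem]) / min(ratio[mem]) < fold
  }
  cand <- NULL
  for (i in expressed) for (j in expressed[expressed > i]) {
    if (qualifies(i, j)) cand <- rbind(cand, data.frame(start = i, end = j))
  }
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer()))
  }
  maximal <- sapply(seq_len(nrow(cand)), function(k) {
    !any(cand$start <= cand$start[k] & cand$end >= cand$end[k] &
           (cand$start < cand$start[k] | cand$end > cand$end[k]))
  })
  out <- cand[maximal, ]
  out[order(out$start), ]
}

# exhaustive (-35, spacer, -10) enumeration
oracle_sigma70 <- function(seq, minus35 = "TTGACA", minus10 = "TATAAT",
                           spacers = 15:19, min_score = 9) {
  chars <- strsplit(seq, "")[[1]]
  c35 <- strsplit(minus35, "")[[1]]
  c10 <- strsplit(minus10, "")[[1]]
  out <- NULL
  for (off in seq_len(length(chars) - 11 - min(spacers))) {
    for (s in spacers) {
      o10 <- off + 6 + s
      if (o10 + 5 > length(chars)) next
      score <- sum(chars[off:(off + 5)] == c35) +
        sum(chars[o10:(o10 + 5)] == c10)
      if (score >= min_score) {
        out <- rbind(out, data.frame(minus35_offset = off,
                                     minus10_offset = o10, spacer = s,
                                     score = score))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(minus35_offset = integer(), minus10_offset = integer(),
                      spacer = integer(), score = integer()))
  }
  out[order(-out$score, out$minus35_offset, out$spacer), ]
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small all-unique generator configuration for pipeline-level tests
toy_config <- function(n = 3, levels = NULL, treatments = c("ctrl", "stress"),
                       ...) {
  positions <- data.frame(index = seq_len(n),
                          class_id = paste0("c", seq_len(n)),
                          orf_present = TRUE, orf_strand = 1L,
                          amplifiable = TRUE)
  classes <- data.frame(class_id = paste0("c", seq_len(n)), detected = TRUE,
                        members = I(as.list(seq_len(n))))
  if (is.null(levels)) {
    levels <- matrix(1, n, length(treatments),
                     dimnames = list(classes$class_id, treatments))
  }
  generator_config(positions = positions, classes = classes,
                   expression = levels,
                   series = list(s = colnames(levels)),
                   promoter = NULL, ...)
}

# binned fingerprint built directly from (bp, height) pairs
toy_binned <- function(bp, height, min_bp = 50, max_bp = 1100) {
  fp <- fingerprint("t", "cDNA", "x", 1,
                    data.frame(size = bp, height = height),
                    calibrated = TRUE)
  bin_to_continuum(fp, min_bp, max_bp)
}
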