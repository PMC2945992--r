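# Cassette-array model and in-silico degenerate-primer attC PCR.
#
# A gene cassette array is represented as a plain DNA string plus an ordered
# annotation table of cassettes.  Coordinates are 1-based inclusive
# (Biostrings/IRanges convention); cassette indices are 1-based ordinals as in
# "cassette 21".

#' Degenerate PCR primer
#'
#' A primer written over the IUPAC nucleotide alphabet, e.g. the attC PCR
#' primers returned by [attc_primers()].
#'
#' @param name Primer name.
#' @param iupac_seq Primer sequence over IUPAC codes (A, C, G, T, R, Y, S, W,
#'   K, M, B, D, H, V, N).
#' @param label Optional fluorophore tag (e.g. `"6FAM"`).
#' @return An object of class `degenerate_primer`.
#' @examples
#' p <- degenerate_primer("YB4", "TCACMCCTTARYDSGGCGTTA", label = "6FAM")
#' length(expand_degenerate(p))  # 48 concrete sequences
#' @export
degenerate_primer <- function(name, iupac_seq, label = NULL) {
  iupac_seq <- toupper(iupac_seq)
  chars <- strsplit(iupac_seq, "")[[1]]
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in primer '", name, "': ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, iupac_seq = iupac_seq, label = label),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat("<degenerate_primer>", x$name, x$iupac_seq,
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  invisible(x)
}

#' The attC PCR primer pair
#'
#' The degenerate primers used for the multiplex attC PCR: the forward primer
#' binds the conserved region of each attC site oriented toward the downstream
#' cassette, the reverse primer binds the next attC on the opposite strand, so
#' each product spans one cassette.
#'
#' @return A list with elements `fwd` (YB4) and `rev` (YB3), both
#'   [degenerate_primer()] objects.
#' @export
attc_primers <- function() {
  list(
    fwd = degenerate_primer("YB4", "TCACMCCTTARYDSGGCGTTA", label = "6FAM"),
    rev = degenerate_primer("YB3", "GAATCMCTCTTRARYDSTTTGT", label = "6FAM")
  )
}

#' Expand a degenerate primer into all concrete sequences
#'
#' @param primer A [degenerate_primer()] (or a plain IUPAC string).
#' @param max_variants Safety cap on the number of expansions.
#' @return Character vector of concrete A/C/G/T sequences; its length equals
#'   the product of the per-position code degeneracies.
#' @export
expand_degenerate <- function(primer, max_variants = 1e6) {
  if (is.character(primer)) primer <- degenerate_primer("primer", primer)
  chars <- strsplit(primer$iupac_seq, "")[[1]]
  sets <- lapply(Biostrings::IUPAC_CODE_MAP[chars],
                 function(s) strsplit(s, "")[[1]])
  card <- prod(lengths(sets))
  if (card > max_variants) {
    stop("primer expands to ", card, " variants (> max_variants)")
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

#' Locate degenerate-primer binding sites on a sequence
#'
#' Reports every position where the primer (forward strand) or its reverse
#' complement (reverse strand) matches with at most `max_mismatch`
#' mismatches, treating IUPAC codes in the primer as ambiguities.
#'
#' @param seq DNA sequence (character string or `DNAString`).
#' @param primer A [degenerate_primer()].
#' @param max_mismatch Maximum number of mismatches tolerated (default 0).
#' @return `data.frame` with columns `start`, `end` (1-based inclusive) and
#'   `strand` (+1 forward, -1 reverse), sorted by `start`.
#' @export
find_primer_sites <- function(seq, primer, max_mismatch = 0) {
  stopifnot(max_mismatch >= 0)
  subject <- if (methods::is(seq, "DNAString")) seq else {
    if (!nzchar(seq)) stop("empty sequence")
    Biostrings::DNAString(seq)
  }
  pat <- Biostrings::DNAString(primer$iupac_seq)
  hit_df <- function(m, strand) {
    if (length(m) == 0) {
      return(data.frame(start = integer(), end = integer(),
                        strand = integer()))
    }
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               strand = strand)
  }
  fwd <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                  fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                  max.mismatch = max_mismatch,
                                  fixed = "subject")
  out <- rbind(hit_df(fwd, 1L), hit_df(rev, -1L))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cassette array object
#'
#' @param name Array name.
#' @param sequence DNA sequence (character string, A/C/G/T/N).
#' @param cassettes `data.frame` with one row per cassette and columns
#'   `index`, `start`, `end`, `orf_present`, `orf_strand`, `orf_start`,
#'   `orf_end`, `attc_start`, `attc_end` (coordinates 1-based inclusive;
#'   `attc_*` give the cassette's downstream attC).
#' @param integron_promoter_pos Optional position of the integron promoter Pc
#'   upstream of the array.
#' @return An object of class `cassette_array`.
#' @export
cassette_array <- function(name, sequence, cassettes,
                           integron_promoter_pos = NULL) {
  required <- c("index", "start", "end", "orf_present", "orf_strand",
                "orf_start", "orf_end", "attc_start", "attc_end")
  missing_cols <- setdiff(required, names(cassettes))
  if (length(missing_cols) > 0) {
    stop("cassette annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cassettes <- cassettes[order(cassettes$start), required]
  n <- nrow(cassettes)
  if (!identical(as.integer(cassettes$index), seq_len(n))) {
    stop("cassette indices must run 1..N in array order")
  }
  if (any(cassettes$start > cassettes$end) ||
      any(cassettes$end > nchar(sequence)) || any(cassettes$start < 1)) {
    stop("cassette intervals out of sequence bounds")
  }
  if (n > 1 && any(cassettes$start[-1] <= cassettes$end[-n])) {
    stop("cassette regions overlap")
  }
  if (any(cassettes$attc_start > cassettes$attc_end)) {
    stop("empty attC region")
  }
  orf <- cassettes$orf_present
  if (any(orf & (is.na(cassettes$orf_start) | is.na(cassettes$orf_end)))) {
    stop("orf_present cassettes need orf_start/orf_end")
  }
  if (any(orf & (cassettes$orf_start < cassettes$start |
                 cassettes$orf_end > cassettes$end), na.rm = TRUE)) {
    stop("ORF interval outside its cassette")
  }
  rownames(cassettes) <- NULL
  structure(list(name = name, sequence = sequence, cassettes = cassettes,
                 integron_promoter_pos = integron_promoter_pos),
            class = "cassette_array")
}

#' @export
print.cassette_array <- function(x, ...) {
  cat("<cassette_array>", x$name, ":", nrow(x$cassettes), "cassettes,",
      nchar(x$sequence), "bp,", sum(x$cassettes$orf_present), "coding\n")
  invisible(x)
}

#' Predict attC PCR amplicons by in-silico PCR
#'
#' Finds all forward- and reverse-primer binding sites and pairs each forward
#' site with the nearest downstream reverse-strand site within
#' `max_product_len`, the dominant product of a multi-template PCR.  Product
#' length is measured from the 5' end of the forward primer match through the
#' 3' end of the reverse primer match, inclusive.  Each amplicon is assigned
#' to the cassette it spans (maximal overlap with the annotated cassette
#' regions).
#'
#' @param array A [cassette_array()].
#' @param fwd,rev Forward and reverse [degenerate_primer()]s (defaults: the
#'   attC pair from [attc_primers()]).
#' @param max_product_len Longest product considered amplifiable (default
#'   1100 bp, the practical upper resolution of the fragment analyser).
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return `data.frame` with columns `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`, `length`, `cassette`.
#' @export
predict_amplicons <- function(array, fwd = attc_primers()$fwd,
                              rev = attc_primers()$rev,
                              max_product_len = 1100, max_mismatch = 0) {
  subject <- Biostrings::DNAString(array$sequence)
  fsites <- find_primer_sites(subject, fwd, max_mismatch)
  fsites <- fsites[fsites$strand == 1L, , drop = FALSE]
  rsites <- find_primer_sites(subject, rev, max_mismatch)
  rsites <- rsites[rsites$strand == -1L, , drop = FALSE]
  empty <- data.frame(fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      length = integer(), cassette = integer())
  if (nrow(fsites) == 0 || nrow(rsites) == 0) {
    warning("no amplicons: forward or reverse primer sites absent")
    return(empty)
  }
  rows <- lapply(seq_len(nrow(fsites)), function(i) {
    fs <- fsites$start[i]
    cand <- rsites[rsites$start > fsites$end[i] &
                   rsites$end - fs + 1L <= max_product_len, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    j <- which.min(cand$end)
    data.frame(fwd_start = fs, fwd_end = fsites$end[i],
               rev_start = cand$start[j], rev_end = cand$end[j],
               length = cand$end[j] - fs + 1L)
  })
  amp <- do.call(rbind, rows)
  if (is.null(amp)) {
    warning("no amplicons within max_product_len")
    return(empty)
  }
  cass <- array$cassettes
  amp$cassette <- vapply(seq_len(nrow(amp)), function(i) {
    ov <- pmin(amp$rev_end[i], cass$end) - pmax(amp$fwd_start[i], cass$start) + 1L
    ov[ov < 0] <- 0L
    if (all(ov == 0)) NA_integer_ else cass$index[which.max(ov)]
  }, integer(1))
  rownames(amp) <- NULL
  amp
}

#' Group predicted amplicons into size classes
#'
#' Amplicons are classed by exact product length; a class is *unique* when a
#' single cassette position produces it and *ambiguous* otherwise.
#'
#' @param amplicons Output of [predict_amplicons()].
#' @return A `size_class_map`: `data.frame` with columns `length`,
#'   `n_members`, `unique` and a list-column `members` of cassette indices,
#'   sorted by length.
#' @export
build_size_classes <- function(amplicons) {
  split_members <- split(amplicons$cassette, amplicons$length)
  lens <- as.integer(names(split_members))
  out <- data.frame(length = lens,
                    n_members = lengths(split_members))
  out$unique <- out$n_members == 1L
  out$members <- I(unname(lapply(split_members,
                                 function(m) sort(unique(unname(m))))))
  out <- out[order(out$length), ]
  rownames(out) <- NULL
  class(out) <- c("size_class_map", "data.frame")
  out
}

#' @export
print.size_class_map <- function(x, ...) {
  cat("<size_class_map>", nrow(x), "size classes (", sum(x$unique),
      "unique,", sum(!x$unique), "ambiguous ),",
      sum(x$n_members), "cassette positions\n")
  invisible(x)
}

# ---- file I/O -------------------------------------------------------------

#' Read a cassette array from FASTA + annotation TSV
#'
#' @param fasta Path to a single-record FASTA with the array sequence.
#' @param annotation Path to the cassette annotation TSV (tab-separated, with
#'   header: `index`, `start`, `end`, `orf_present`, `orf_strand`,
#'   `orf_start`, `orf_end`, `attc_start`, `attc_end`).
#' @return A [cassette_array()].
#' @export
read_cassette_array <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1) stop("expected a single FASTA record")
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  ann$orf_present <- as.logical(ann$orf_present)
  cassette_array(names(seqs), as.character(seqs[[1]]), ann)
}

#' Write a cassette array to FASTA + annotation TSV
#'
#' @param array A [cassette_array()].
#' @param fasta,annotation Output paths.
#' @export
write_cassette_array <- function(array, fasta, annotation) {
  s <- Biostrings::DNAStringSet(array$sequence)
  names(s) <- array$name
  Biostrings::writeXStringSet(s, fasta)
  utils::write.table(array$cassettes, annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(array)
}

#' Read a primer table
#'
#' @param path TSV with header columns `name`, `iupac_seq`, `orientation`
#'   (`fwd`/`rev`) and optionally `label`.
#' @return Named list of [degenerate_primer()]s with an `orientation`
#'   attribute on each element.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "iupac_seq", "orientation")
  if (!all(need %in% names(tab))) {
    stop("primer table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    p <- degenerate_primer(tab$name[i], tab$iupac_seq[i],
                           label = if ("label" %in% names(tab)) tab$label[i])
    attr(p, "orientation") <- tab$orientation[i]
    p
  })
  names(out) <- tab$name
  out
}

#' Write the size-class map as TSV
#'
#' @param scm A [build_size_classes()] result.
#' @param path Output path; columns `length`, `members` (comma-separated
#'   cassette indices), `unique`.
#' @export
write_size_classes <- function(scm, path) {
  flat <- data.frame(length = scm$length,
                     members = vapply(scm$members, paste, "", collapse = ","),
                     unique = scm$unique)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scm)
}
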