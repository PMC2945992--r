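# Intra-array promoter localisation: sigma-70 consensus scanning across attC
# junctions, nested-PCR transcript-start interval logic, and qPCR relative
# quantitation of promoter activity.

#' Sigma-70 promoter model
#'
#' Consensus -35 / -10 hexamers with an admissible spacer range, scored by a
#' simple match count against the two consensus elements (12 positions total).
#'
#' @param minus35 -35 consensus (default `"TTGACA"`).
#' @param minus10 -10 consensus (default `"TATAAT"`).
#' @param spacer_range Admissible -35 to -10 spacer lengths in bp (default
#'   15:19).
#' @param min_score Minimum total matched positions for a hit (default 9 of
#'   12, admitting partial -35/-10 homology while keeping random background
#'   hits rare).
#' @return Object of class `sigma70_model`.
#' @export
sigma70_model <- function(minus35 = "TTGACA", minus10 = "TATAAT",
                          spacer_range = 15:19, min_score = 9) {
  stopifnot(nchar(minus35) == 6, nchar(minus10) == 6,
            length(spacer_range) >= 1, min_score <= 12)
  structure(list(minus35 = toupper(minus35), minus10 = toupper(minus10),
                 spacer_range = as.integer(spacer_range),
                 min_score = as.integer(min_score)),
            class = "sigma70_model")
}

#' Scan a sequence for sigma-70-type promoter placements
#'
#' Enumerates every (-35 offset, spacer, -10 offset) placement on the forward
#' strand (cassettes are uniformly oriented by attC, so only the forward
#' strand can drive cassette transcription) and reports placements whose total
#' consensus match count reaches the model threshold.
#'
#' @param seq DNA sequence (character string).
#' @param model A [sigma70_model()].
#' @return `data.frame` sorted by score (descending) then offset:
#'   `minus35_offset`, `minus10_offset` (1-based starts), `spacer`, `score`.
#' @export
scan_sigma70 <- function(seq, model = sigma70_model()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  need <- 12 + min(model$spacer_range)
  if (n < need) stop("sequence shorter than one promoter placement")
  c35 <- strsplit(model$minus35, "")[[1]]
  c10 <- strsplit(model$minus10, "")[[1]]
  # match counts of each hexamer at every start offset
  count_matches <- function(cons) {
    m <- integer(n - 5)
    for (j in 1:6) m <- m + (chars[j:(n - 6 + j)] == cons[j])
    m
  }
  m35 <- count_matches(c35)
  m10 <- count_matches(c10)
  hits <- lapply(model$spacer_range, function(s) {
    shift <- 6 + s                      # -10 start relative to -35 start
    len35 <- length(m35) - shift
    if (len35 < 1) return(NULL)
    score <- m35[seq_len(len35)] + m10[seq_len(len35) + shift]
    ok <- which(score >= model$min_score)
    if (length(ok) == 0) return(NULL)
    data.frame(minus35_offset = ok, minus10_offset = ok + shift, spacer = s,
               score = score[ok])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(minus35_offset = integer(), minus10_offset = integer(),
                      spacer = integer(), score = integer())
  }
  out <- out[order(-out$score, out$minus35_offset, out$spacer), ]
  rownames(out) <- NULL
  out
}

#' Annotate promoter hits with the attC junction they bridge
#'
#' @param hits A [scan_sigma70()] result on the array sequence.
#' @param array The [cassette_array()].
#' @return `hits` with a `junction` column: the cassette index whose
#'   downstream attC contains any part of the placement (NA when none).
#' @export
assign_junctions <- function(hits, array) {
  cass <- array$cassettes
  hits$junction <- vapply(seq_len(nrow(hits)), function(i) {
    lo <- hits$minus35_offset[i]
    hi <- hits$minus10_offset[i] + 5
    j <- which(cass$attc_start <= hi & cass$attc_end >= lo)
    if (length(j) == 0) NA_integer_ else cass$index[j[1]]
  }, integer(1))
  hits
}

#' Infer the transcript 5'-end interval from nested-PCR observations
#'
#' Successive nested primer pairs either amplify a cDNA species or not, while
#' every pair must amplify on gDNA (primer-site integrity control).  The
#' transcript 5' end (and its promoter) lies strictly between the rightmost
#' forward-primer site whose cDNA pair fails and the leftmost forward-primer
#' site whose cDNA pair succeeds.
#'
#' @param obs `data.frame` with columns `fwd`, `rev` (primer names),
#'   `template` (`"cDNA"`/`"gDNA"`) and `amplified` (logical).
#' @param primer_sites `data.frame` with columns `name`, `start`, `end`
#'   giving each primer's binding interval on the array sequence.
#' @return List with `lower`, `upper` (exclusive interval bounds on the array
#'   sequence) and `bracketed` (`FALSE` when every cDNA pair succeeded, so the
#'   start is only known to lie upstream of the leftmost forward site).
#' @export
infer_transcript_interval <- function(obs, primer_sites) {
  site <- function(p) {
    i <- match(p, primer_sites$name)
    if (is.na(i)) stop("unknown primer: ", p)
    primer_sites[i, c("start", "end")]
  }
  cdna <- obs[obs$template == "cDNA", , drop = FALSE]
  gdna <- obs[obs$template == "gDNA", , drop = FALSE]
  for (i in seq_len(nrow(cdna))) {
    ok <- gdna$amplified[gdna$fwd == cdna$fwd[i] & gdna$rev == cdna$rev[i]]
    if (length(ok) == 0 || !all(ok)) {
      stop("pair ", cdna$fwd[i], "/", cdna$rev[i],
           " lacks a positive gDNA control")
    }
  }
  fails <- cdna[!cdna$amplified, , drop = FALSE]
  succ <- cdna[cdna$amplified, , drop = FALSE]
  # consistency: with the same reverse primer, success can never lie upstream
  # of a failure (a longer species contains the shorter one)
  for (r in unique(cdna$rev)) {
    f <- fails[fails$rev == r, , drop = FALSE]
    s <- succ[succ$rev == r, , drop = FALSE]
    if (nrow(f) == 0 || nrow(s) == 0) next
    f_min <- min(vapply(f$fwd, function(p) site(p)$start, numeric(1)))
    bad <- s$fwd[vapply(s$fwd, function(p) site(p)$start, numeric(1)) < f_min]
    if (length(bad) > 0) {
      stop("inconsistent nested-PCR observations: pair ", bad[1], "/", r,
           " amplified upstream of failing pair ",
           f$fwd[which.min(vapply(f$fwd, function(p) site(p)$start,
                                  numeric(1)))], "/", r)
    }
  }
  upper <- if (nrow(succ) > 0) {
    min(vapply(succ$fwd, function(p) site(p)$start, numeric(1)))
  } else {
    NA_real_
  }
  if (nrow(fails) == 0) {
    return(list(lower = -Inf, upper = upper, bracketed = FALSE))
  }
  lower <- max(vapply(fails$fwd, function(p) site(p)$end, numeric(1)))
  list(lower = lower, upper = upper, bracketed = is.finite(lower) &&
         !is.na(upper))
}

#' Promoter activity from bridging vs downstream qPCR
#'
#' Relative quantitation of two amplicons on the same cDNA template: one
#' bridging the putative promoter, one wholly downstream.  The fold change
#' `E^(Ct_bridging - Ct_downstream)` measures the extra transcript initiating
#' between the two amplicons; values above 1 indicate an active promoter, and
#' a residual bridging signal (fold < Inf) reports read-through transcript
#' from further upstream.
#'
#' @param ct_bridging,ct_downstream Ct values (cycles); vectors are averaged.
#' @param efficiency Per-cycle amplification factor E (default 2.0, perfect
#'   doubling).
#' @return Fold increase of downstream over bridging transcript.
#' @export
qpcr_fold_change <- function(ct_bridging, ct_downstream, efficiency = 2.0) {
  stopifnot(all(ct_bridging > 0), all(ct_downstream > 0),
            efficiency > 1, efficiency <= 2)
  efficiency ^ (mean(ct_bridging) - mean(ct_downstream))
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `primer_pair` (`"bridging"`/`"downstream"`),
#'   `replicate`, `ct`.
#' @return `data.frame` of the measurements.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("primer_pair", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}
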