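# Analytical core: contamination QC, inter-PCR normalization, replicate
# statistics, peak-to-size-class matching, cDNA/gDNA expression ratios,
# conditional calls, expression blocs and candidate promoter regions.

#' Analysis configuration
#'
#' Tunable thresholds of the expression analysis.
#'
#' @param norm_floor_bp Only peaks strictly above this size (bp) enter the
#'   inter-PCR normalization sum (default 90, excluding primer artefacts).
#' @param detect_height_min Minimum mean raw peak height (fluorescence units)
#'   for a size class to count as detected; applied before normalization
#'   (default 50).
#' @param match_window Allowed observed-minus-predicted bp offsets when
#'   matching bins to predicted class lengths; the default `c(0, 1)` absorbs
#'   the +1 bp poly-A tailing bias.
#' @param conditional_fold Minimum fold change between treatments for a class
#'   to be called conditionally expressed (default 2.0, the 95%-confidence
#'   rule from [derive_threshold()] at 50 %SE).
#' @param bloc_fold Upper bound (exclusive) on the max/min expression ratio
#'   within a bloc of adjacent co-expressed cassettes (default 3.0).
#' @param z_value Normal quantile of the significance rule (default 1.96).
#' @param se_assumed Conservative per-amplicon relative standard error used to
#'   derive `conditional_fold` (default 0.50, i.e. 50 %SE).
#' @param ambiguous_breaks Whether ambiguously-located size classes break bloc
#'   contiguity (default `FALSE`: they are skipped neutrally).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(norm_floor_bp = 90, detect_height_min = 50,
                            match_window = c(0, 1), conditional_fold = 2.0,
                            bloc_fold = 3.0, z_value = 1.96,
                            se_assumed = 0.50, ambiguous_breaks = FALSE) {
  stopifnot(norm_floor_bp > 0, detect_height_min > 0, conditional_fold > 0,
            bloc_fold > 0, z_value > 0, se_assumed > 0)
  structure(list(norm_floor_bp = norm_floor_bp,
                 detect_height_min = detect_height_min,
                 match_window = as.integer(match_window),
                 conditional_fold = conditional_fold, bloc_fold = bloc_fold,
                 z_value = z_value, se_assumed = se_assumed,
                 ambiguous_breaks = isTRUE(ambiguous_breaks)),
            class = "analysis_config")
}

#' Minimum significant fold change from replicate variability
#'
#' A change is significant at the level implied by `z` when it exceeds
#' `1 + z * percent_se / 100`.  At the conservative 50 %SE per amplicon and
#' z = 1.96 this gives 1.98, the two-fold rule.
#'
#' @param percent_se Relative standard error of a replicate amplicon
#'   measurement, in percent.
#' @param z Normal quantile (default 1.96 for 95% confidence).
#' @return The minimum significant fold change (exact, un-rounded).
#' @export
derive_threshold <- function(percent_se, z = 1.96) {
  stopifnot(percent_se > 0)
  1 + z * percent_se / 100
}

#' Screen a sample set for DNA contamination
#'
#' A set fails when any control (RNA or water) fingerprint carries a peak at
#' size above `norm_floor_bp` with height at or above `detect_height_min`.
#' Failing sets must be discarded entirely.
#'
#' @param samples List of calibrated [fingerprint()]s including at least one
#'   RNA or water control.
#' @param cfg An [analysis_config()].
#' @return List with `pass` (logical) and `evidence` (`data.frame` of
#'   offending control peaks).
#' @export
check_contamination <- function(samples, cfg = analysis_config()) {
  is_ctrl <- vapply(samples, function(fp) fp$material %in% c("RNA", "water"),
                    logical(1))
  if (!any(is_ctrl)) {
    stop("no RNA/water control in sample set; contamination QC impossible")
  }
  evidence <- do.call(rbind, lapply(samples[is_ctrl], function(fp) {
    if (!fp$calibrated) stop("controls must be calibrated before QC")
    bad <- fp$peaks$size > cfg$norm_floor_bp &
      fp$peaks$height >= cfg$detect_height_min
    if (!any(bad)) return(NULL)
    data.frame(sample_id = fp$sample_id, material = fp$material,
               size = fp$peaks$size[bad], height = fp$peaks$height[bad])
  }))
  if (is.null(evidence)) {
    evidence <- data.frame(sample_id = character(), material = character(),
                           size = numeric(), height = numeric())
  }
  list(pass = nrow(evidence) == 0, evidence = evidence)
}

#' Normalize a binned fingerprint by its above-floor peak-height sum
#'
#' Divides every bin by the sum of bins strictly above `norm_floor_bp`, the
#' inter-PCR standard; afterwards the above-floor bins sum to exactly 1.
#'
#' @param bf A [bin_to_continuum()] result.
#' @param cfg An [analysis_config()].
#' @return The binned fingerprint with normalized bins and a `normalizer`
#'   element recording the divisor.
#' @export
normalize_fingerprint <- function(bf, cfg = analysis_config()) {
  bp <- as.integer(names(bf$bins))
  norm <- sum(bf$bins[bp > cfg$norm_floor_bp])
  if (norm <= 0) stop("empty PCR: no peak mass above ", cfg$norm_floor_bp,
                      " bp to normalize by")
  bf$bins <- bf$bins / norm
  bf$normalizer <- norm
  bf
}

#' Per-bin replicate statistics
#'
#' @param reps List (length >= 2) of replicate [bin_to_continuum()] results on
#'   the same continuum, normally after [normalize_fingerprint()].
#' @param raw Optional list of the same replicates before normalization, kept
#'   so detection can be assessed on raw heights.
#' @return Object of class `replicate_stats`: list with `bp`, replicate
#'   matrices `mat` (and `raw`), and per-bin `mean`, `se` (sample sd / sqrt n)
#'   and `pct_se` (100 * se/mean, `NA` where the mean is 0).
#' @export
aggregate_replicates <- function(reps, raw = NULL) {
  if (length(reps) < 2) stop("need at least 2 replicates")
  as_vec <- function(x) if (inherits(x, "binned_fingerprint")) x$bins else x
  mat <- vapply(reps, as_vec, numeric(length(as_vec(reps[[1]]))))
  bp <- as.integer(rownames(mat) %||% names(as_vec(reps[[1]])))
  n <- ncol(mat)
  m <- unname(rowMeans(mat))
  se <- unname(apply(mat, 1, stats::sd)) / sqrt(n)
  pct <- ifelse(m > 0, 100 * se / m, NA_real_)
  rawmat <- if (!is.null(raw)) {
    vapply(raw, as_vec, numeric(nrow(mat)))
  }
  structure(list(bp = bp, mat = mat, raw = rawmat, n = n, mean = m, se = se,
                 pct_se = pct),
            class = "replicate_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match observed bins to predicted size classes
#'
#' Each occupied bin is offered to the predicted classes whose match window
#' (`length + match_window`) covers it; the nearest class wins, ties going to
#' the smaller length, and each bin is consumed by at most one class.  A
#' class's height is the sum of its won bins (per replicate, so class-level
#' mean/SE are exact), which folds the +1 bp poly-A satellite back into its
#' parent class.
#'
#' @param stats A [aggregate_replicates()] result.
#' @param scm A [build_size_classes()] map.
#' @param cfg An [analysis_config()].
#' @return `data.frame` (class `class_stats`) with one row per size class:
#'   `length`, `n_members`, `unique`, `members` (list-column), `mean_norm`,
#'   `se`, `pct_se`, `mean_raw`, `detected`; attribute `unassigned` lists
#'   occupied bins claimed by no class.
#' @export
match_classes <- function(stats, scm, cfg = analysis_config()) {
  if (nrow(scm) == 0) stop("empty size-class map")
  bp <- stats$bp
  occupied <- rowSums(stats$mat) > 0
  if (!is.null(stats$raw)) occupied <- occupied | rowSums(stats$raw) > 0
  occupied <- which(occupied)
  assign_class <- rep(NA_integer_, length(bp))
  for (i in occupied) {
    deltas <- bp[i] - scm$length
    ok <- which(deltas %in% cfg$match_window)
    if (length(ok) == 0) next
    best <- ok[order(abs(deltas[ok]), scm$length[ok])][1]
    assign_class[i] <- best
  }
  sum_rows <- function(mat, idx) {
    if (length(idx) == 0) return(numeric(ncol(mat)))
    colSums(mat[idx, , drop = FALSE])
  }
  out <- scm[, c("length", "n_members", "unique", "members")]
  n <- stats$n
  per_class <- lapply(seq_len(nrow(scm)), function(k) {
    idx <- which(assign_class == k)
    v <- sum_rows(stats$mat, idx)
    r <- if (!is.null(stats$raw)) sum_rows(stats$raw, idx)
    m <- mean(v)
    se <- stats::sd(v) / sqrt(n)
    data.frame(mean_norm = m, se = se,
               pct_se = if (m > 0) 100 * se / m else NA_real_,
               mean_raw = if (!is.null(r)) mean(r) else NA_real_)
  })
  out <- cbind(out, do.call(rbind, per_class))
  out$detected <- if (!is.null(stats$raw)) {
    !is.na(out$mean_raw) & out$mean_raw >= cfg$detect_height_min
  } else {
    out$mean_norm > 0
  }
  attr(out, "unassigned") <- bp[occupied][is.na(assign_class[occupied])]
  class(out) <- c("class_stats", "data.frame")
  out
}

#' Per-class expression ratios from cDNA and gDNA class statistics
#'
#' Expression ratio = mean normalized cDNA height / mean normalized gDNA
#' height, using the stoichiometric relationship of cassettes in gDNA as the
#' quantitative standard.  The ratio is `NA` (never silently zero) where the
#' class is undetected in gDNA, and flagged undetected where the cDNA signal
#' is below the detection floor.
#'
#' @param cdna,gdna [match_classes()] results over the same size-class map.
#' @param cfg An [analysis_config()].
#' @param treatment Treatment label stored on the profile.
#' @return `data.frame` (class `expression_profile`) with columns `length`,
#'   `n_members`, `unique`, `members`, `gdna_detected`, `cdna_detected`,
#'   `ratio`.
#' @export
compute_expression <- function(cdna, gdna, cfg = analysis_config(),
                               treatment = NA_character_) {
  if (!identical(cdna$length, gdna$length)) {
    stop("cDNA and gDNA statistics use different size-class maps")
  }
  out <- cdna[, c("length", "n_members", "unique", "members")]
  out$gdna_detected <- gdna$detected
  out$cdna_detected <- cdna$detected
  out$ratio <- ifelse(out$gdna_detected & out$cdna_detected & gdna$mean_norm > 0,
                      cdna$mean_norm / gdna$mean_norm, NA_real_)
  attr(out, "treatment") <- treatment
  class(out) <- c("expression_profile", "data.frame")
  out
}

#' Call conditional expression across a treatment series
#'
#' For every size class the maximum fold change across treatment pairs (among
#' treatments where the class is expressed) is compared with
#' `conditional_fold`.  Classes expressed in some treatments but undetectable
#' in others are `conditional_from_undetectable`; classes never expressed are
#' `not_detected`.
#'
#' @param profiles Named list of [compute_expression()] profiles, one per
#'   treatment of the series (>= 2).
#' @param cfg An [analysis_config()].
#' @return `data.frame` with `length`, `unique`, `gdna_detected`,
#'   `n_expressed`, `max_fold`, `treatment_max` and `call` in
#'   `not_detected` / `constitutive` / `conditional` /
#'   `conditional_from_undetectable`.
#' @export
call_conditional <- function(profiles, cfg = analysis_config()) {
  if (length(profiles) < 2) stop("need >= 2 treatments in a series")
  lens <- profiles[[1]]$length
  for (p in profiles[-1]) {
    if (!identical(p$length, lens)) stop("profiles use different class maps")
  }
  ratios <- vapply(profiles, function(p) p$ratio, numeric(length(lens)))
  detected <- vapply(profiles, function(p) p$cdna_detected & p$gdna_detected,
                     logical(length(lens)))
  gdna_any <- apply(vapply(profiles, function(p) p$gdna_detected,
                           logical(length(lens))), 1, any)
  n_expr <- rowSums(detected)
  call <- character(length(lens))
  max_fold <- rep(NA_real_, length(lens))
  tr_max <- rep(NA_character_, length(lens))
  for (i in seq_along(lens)) {
    r <- ratios[i, detected[i, ]]
    if (length(r) >= 1) {
      max_fold[i] <- if (length(r) >= 2) max(r) / min(r) else 1
      tr_max[i] <- names(profiles)[detected[i, ]][which.max(r)]
    }
    call[i] <- if (n_expr[i] == 0) {
      "not_detected"
    } else if (n_expr[i] < ncol(detected) && gdna_any[i]) {
      "conditional_from_undetectable"
    } else if (!is.na(max_fold[i]) && max_fold[i] >= cfg$conditional_fold) {
      "conditional"
    } else {
      "constitutive"
    }
  }
  data.frame(length = lens, unique = profiles[[1]]$unique,
             gdna_detected = gdna_any, n_expressed = n_expr,
             max_fold = max_fold, treatment_max = tr_max, call = call)
}

#' Detect blocs of similarly expressed adjacent cassettes
#'
#' A bloc is a maximal run of at least two adjacent expressed cassette
#' positions whose expression ratios differ by less than `bloc_fold`
#' (max/min).  Only uniquely-located size classes contribute positions;
#' ambiguous classes are by default skipped neutrally (neither members nor
#' breaks; set `ambiguous_breaks` in the config to treat them as breaks).
#'
#' @param profile A [compute_expression()] profile.
#' @param scm The [build_size_classes()] map (defines positions).
#' @param cfg An [analysis_config()].
#' @return `data.frame` with `start`, `end` (cassette indices, inclusive),
#'   `n_members`, `min_ratio`, `max_ratio`.
#' @export
detect_blocs <- function(profile, scm, cfg = analysis_config()) {
  n_pos <- max(unlist(scm$members))
  ratio_at <- rep(NA_real_, n_pos)       # expressed unique positions
  neutral <- rep(FALSE, n_pos)           # ambiguous positions
  for (i in seq_len(nrow(profile))) {
    mem <- profile$members[[i]]
    if (profile$unique[i]) {
      if (isTRUE(profile$cdna_detected[i]) && !is.na(profile$ratio[i])) {
        ratio_at[mem] <- profile$ratio[i]
      }
    } else if (!cfg$ambiguous_breaks) {
      neutral[mem] <- TRUE
    }
  }
  # collapse neutral (ambiguous) positions out: expressed positions separated
  # only by ambiguous ones stay adjacent; every other position breaks a run
  keep <- which(!neutral)
  vals <- ratio_at[keep]
  expressed <- !is.na(vals)
  run_id <- cumsum(c(TRUE, diff(expressed) != 0))
  blocs <- list()
  for (run in split(seq_along(keep), run_id)) {
    if (!expressed[run[1]] || length(run) < 2) next
    blocs <- c(blocs, maximal_blocs(vals[run], keep[run], cfg$bloc_fold))
  }
  out <- do.call(rbind, blocs)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      n_members = integer(), min_ratio = numeric(),
                      max_ratio = numeric())
  }
  rownames(out) <- NULL
  out
}

# maximal windows with max/min < fold and length >= 2
maximal_blocs <- function(vals, idx, fold) {
  n <- length(vals)
  qual <- function(i, j) max(vals[i:j]) / min(vals[i:j]) < fold
  out <- list()
  i <- 1
  while (i < n) {
    if (!qual(i, i + 1)) { i <- i + 1; next }
    j <- i + 1
    while (j < n && qual(i, j + 1)) j <- j + 1
    # maximal to the left?
    if (i == 1 || !qual(i - 1, j)) {
      out <- c(out, list(data.frame(start = idx[i], end = idx[j],
                                    n_members = j - i + 1,
                                    min_ratio = min(vals[i:j]),
                                    max_ratio = max(vals[i:j]))))
    }
    i <- i + 1
  }
  out
}

#' Candidate intra-array promoter positions
#'
#' Positions whose cassette is detectable in gDNA but never expressed in any
#' treatment, lying adjacent to at least one expressed cassette: the expressed
#' neighbour requires a promoter downstream of the silent position.
#'
#' @param calls A [call_conditional()] result computed over all treatments of
#'   the study combined.
#' @param scm The [build_size_classes()] map.
#' @return Sorted integer vector of candidate cassette positions.
#' @export
candidate_promoter_regions <- function(calls, scm) {
  n_pos <- max(unlist(scm$members))
  status <- rep("unknown", n_pos)
  members <- scm$members
  for (i in seq_len(nrow(calls))) {
    mem <- members[[i]]
    if (!calls$unique[i]) next
    status[mem] <- if (!calls$gdna_detected[i]) {
      "undetectable"
    } else if (calls$call[i] == "not_detected") {
      "never_expressed"
    } else {
      "expressed"
    }
  }
  cand <- which(status == "never_expressed")
  has_expr_neighbour <- vapply(cand, function(p) {
    nb <- c(p - 1, p + 1)
    nb <- nb[nb >= 1 & nb <= n_pos]
    any(status[nb] == "expressed")
  }, logical(1))
  sort(cand[has_expr_neighbour])
}
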