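# End-to-end orchestration: manifest-driven runs from files to report TSVs.

#' Read a run manifest
#'
#' A flat YAML file naming the inputs and the experiment structure: paths
#' (relative to the manifest) for `array_fasta`, `annotation`, `primers`,
#' `peaks`, `ladder`, optional `qpcr`; `series`, a named map of stressor
#' series to ordered treatment-label lists; optional `predict_max_mismatch`
#' and [analysis_config()] overrides under `config`; optional `seed`.
#'
#' @param path Manifest YAML path.
#' @return Manifest list with absolute paths and a `base_dir` element.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  man$base_dir <- dirname(normalizePath(path))
  for (f in c("array_fasta", "annotation", "primers", "peaks", "ladder",
              "qpcr")) {
    if (!is.null(man[[f]])) {
      man[[f]] <- file.path(man$base_dir, man[[f]])
      if (!file.exists(man[[f]])) stop("manifest path missing: ", man[[f]])
    }
  }
  if (is.null(man$series) || any(lengths(man$series) < 2)) {
    stop("manifest must define series with >= 2 treatments each")
  }
  man
}

#' Analyse one treatment's sample set into an expression profile
#'
#' Runs the per-treatment stages in order: size calibration, contamination
#' QC, binning to the 1 bp continuum, inter-PCR normalization, replicate
#' statistics, class matching, and the cDNA/gDNA expression ratio.
#'
#' @param fps List of [fingerprint()]s for one treatment (gDNA and cDNA
#'   replicates plus RNA/water controls).
#' @param scm [build_size_classes()] map.
#' @param ladder [ladder_calibration()] (may be `NULL` when fingerprints are
#'   already calibrated).
#' @param cfg An [analysis_config()].
#' @return List with `qc` (from [check_contamination()]), and when QC passes
#'   `profile` ([compute_expression()]), `gdna` and `cdna` class statistics.
#' @export
analyse_sample_set <- function(fps, scm, ladder = NULL,
                               cfg = analysis_config()) {
  treatment <- fps[[1]]$treatment
  if (!is.null(ladder)) fps <- lapply(fps, calibrate_sizes, ladder = ladder)
  qc <- check_contamination(fps, cfg)
  if (!qc$pass) return(list(qc = qc, profile = NULL))
  stats_for <- function(material) {
    sel <- Filter(function(fp) fp$material == material, fps)
    if (length(sel) < 2) {
      stop("treatment ", treatment, ": need >= 2 ", material, " replicates")
    }
    raw <- lapply(sel, bin_to_continuum)
    norm <- lapply(raw, normalize_fingerprint, cfg = cfg)
    match_classes(aggregate_replicates(norm, raw = raw), scm, cfg)
  }
  gdna <- stats_for("gDNA")
  cdna <- stats_for("cDNA")
  list(qc = qc, gdna = gdna, cdna = cdna,
       profile = compute_expression(cdna, gdna, cfg, treatment = treatment))
}

#' Run the full pipeline from a manifest
#'
#' Executes predict -> calibrate -> qc -> normalize -> aggregate -> match ->
#' express -> call -> blocs -> candidate promoter regions (plus promoter scan
#' and qPCR when inputs are present) and writes the report TSVs.
#'
#' @param manifest Manifest path or the list from [read_manifest()].
#' @param out_dir Report directory (default `reports` next to the manifest).
#' @param cfg An [analysis_config()]; manifest `config` entries override its
#'   fields.
#' @return Invisibly, a list with the size-class map, per-treatment profiles,
#'   per-series conditional calls, combined calls, blocs, candidate promoter
#'   positions, promoter hits, qPCR fold and the QC log.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, cfg = analysis_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(manifest$config)) {
    cfg <- do.call(analysis_config,
                   utils::modifyList(unclass(cfg), manifest$config))
  }
  out_dir <- out_dir %||% file.path(manifest$base_dir, "reports")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  array <- stage("predict",
                 read_cassette_array(manifest$array_fasta,
                                     manifest$annotation))
  primers <- stage("predict", read_primer_table(manifest$primers))
  ori <- vapply(primers, attr, "", which = "orientation")
  mm <- manifest$predict_max_mismatch %||% 0
  amp <- stage("predict",
               predict_amplicons(array, fwd = primers[[which(ori == "fwd")]],
                                 rev = primers[[which(ori == "rev")]],
                                 max_mismatch = mm))
  scm <- build_size_classes(amp)
  write_size_classes(scm, file.path(out_dir, "size_classes.tsv"))

  ladder <- stage("calibrate", read_ladder(manifest$ladder))
  fps <- stage("calibrate", read_peak_table(manifest$peaks))
  treatments <- unique(vapply(fps, function(f) f$treatment, ""))
  sets <- lapply(treatments, function(t) {
    Filter(function(f) f$treatment == t, fps)
  })
  names(sets) <- treatments

  results <- lapply(treatments, function(t) {
    stage(paste0("qc/express [", t, "]"),
          analyse_sample_set(sets[[t]], scm, ladder, cfg))
  })
  names(results) <- treatments
  qc_log <- data.frame(
    treatment = treatments,
    qc_pass = vapply(results, function(r) r$qc$pass, logical(1)),
    n_samples = vapply(sets, length, integer(1)))
  utils::write.table(qc_log, file.path(out_dir, "qc_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results <- Filter(function(r) r$qc$pass, results)
  if (length(results) == 0) {
    stop("all sample sets failed contamination QC; nothing to analyse")
  }
  profiles <- lapply(results, function(r) r$profile)

  # expression map (one ratio column per treatment)
  emap <- data.frame(
    class_bp = scm$length,
    members = vapply(scm$members, paste, "", collapse = ","),
    unique = scm$unique)
  for (t in names(profiles)) emap[[t]] <- profiles[[t]]$ratio
  utils::write.table(emap, file.path(out_dir, "expression_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  calls_by_series <- lapply(manifest$series, function(tt) {
    tt <- intersect(tt, names(profiles))
    if (length(tt) < 2) return(NULL)
    call_conditional(profiles[tt], cfg)
  })
  calls_by_series <- Filter(Negate(is.null), calls_by_series)
  combined <- if (length(profiles) >= 2) call_conditional(profiles, cfg)
  cmap <- data.frame(class_bp = scm$length,
                     members = emap$members, unique = scm$unique)
  if (!is.null(combined)) {
    cmap$call <- combined$call
    cmap$max_fold <- combined$max_fold
    cmap$treatment_max <- combined$treatment_max
  }
  for (s in names(calls_by_series)) {
    cmap[[paste0("call_", s)]] <- calls_by_series[[s]]$call
    cmap[[paste0("max_fold_", s)]] <- calls_by_series[[s]]$max_fold
  }
  utils::write.table(cmap, file.path(out_dir, "conditional_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  blocs <- do.call(rbind, lapply(names(profiles), function(t) {
    b <- detect_blocs(profiles[[t]], scm, cfg)
    if (nrow(b) == 0) return(NULL)
    cbind(treatment = t, b)
  }))
  if (is.null(blocs)) {
    blocs <- data.frame(treatment = character(), start = integer(),
                        end = integer(), n_members = integer(),
                        min_ratio = numeric(), max_ratio = numeric())
  }
  utils::write.table(blocs, file.path(out_dir, "blocs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  candidates <- if (!is.null(combined)) {
    candidate_promoter_regions(combined, scm)
  } else {
    integer()
  }
  utils::write.table(data.frame(position = candidates),
                     file.path(out_dir, "candidate_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hits <- stage("scan-promoters", {
    h <- scan_sigma70(array$sequence)
    assign_junctions(h, array)
  })
  utils::write.table(utils::head(hits[order(-hits$score), ], 50),
                     file.path(out_dir, "promoter_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  qpcr_fold <- NULL
  if (!is.null(manifest$qpcr)) {
    qpcr <- stage("qpcr", read_qpcr_table(manifest$qpcr))
    qpcr_fold <- qpcr_fold_change(
      qpcr$ct[qpcr$primer_pair == "bridging"],
      qpcr$ct[qpcr$primer_pair == "downstream"])
    utils::write.table(data.frame(fold_downstream_vs_bridging = qpcr_fold),
                       file.path(out_dir, "qpcr_fold.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  invisible(list(size_classes = scm, profiles = profiles,
                 calls_by_series = calls_by_series, combined_calls = combined,
                 blocs = blocs, candidate_promoters = candidates,
                 promoter_hits = hits, qpcr_fold = qpcr_fold,
                 qc_log = qc_log, out_dir = out_dir))
}
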