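# Fragment-analysis fingerprints: peak-table I/O, ladder calibration and
# binning onto an integer bp continuum.

MATERIALS <- c("gDNA", "cDNA", "RNA", "water")

#' Fingerprint object
#'
#' One sample's fragment-analysis peak profile.
#'
#' @param sample_id Sample identifier.
#' @param material One of `"gDNA"`, `"cDNA"`, `"RNA"`, `"water"` (RNA and
#'   water are contamination controls).
#' @param treatment Free-text treatment label (e.g. `"28C"`,
#'   `"H2O2_1.8mM_18h"`).
#' @param replicate PCR replicate number (1-based).
#' @param peaks `data.frame` with columns `size` and `height`; `size` is in
#'   migration units before calibration, bp after.
#' @param calibrated Logical; whether `size` is already in bp.
#' @return Object of class `fingerprint`.
#' @export
fingerprint <- function(sample_id, material, treatment, replicate,
                        peaks = data.frame(size = numeric(),
                                           height = numeric()),
                        calibrated = FALSE) {
  material <- as.character(material)
  if (!material %in% MATERIALS) {
    stop("unknown material '", material, "' (expected ",
         paste(MATERIALS, collapse = "/"), ")")
  }
  if (any(peaks$height < 0)) stop("negative peak height")
  peaks <- peaks[order(peaks$size), c("size", "height")]
  rownames(peaks) <- NULL
  structure(list(sample_id = as.character(sample_id), material = material,
                 treatment = as.character(treatment),
                 replicate = as.integer(replicate), peaks = peaks,
                 calibrated = isTRUE(calibrated)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$sample_id, paste0("[", x$material, "]"),
      x$treatment, paste0("rep", x$replicate, ":"), nrow(x$peaks), "peaks",
      if (x$calibrated) "(bp)" else "(migration units)", "\n")
  invisible(x)
}

#' Read a peak-table CSV into fingerprints
#'
#' The CSV has one row per peak with header `sample_id`, `material`,
#' `treatment`, `replicate`, `size`, `height`, plus an optional `calibrated`
#' column (logical, constant per sample).  A sample with no peaks (e.g. a
#' clean RNA control) is declared by a single row with empty `size` and
#' `height` fields.
#'
#' @param path CSV path.
#' @return List of [fingerprint()] objects.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "material", "treatment", "replicate", "size",
            "height")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("peak table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.na(tab$height) & tab$height < 0)
  if (length(bad) > 0) {
    stop("negative height at row ", bad[1])
  }
  if (!"calibrated" %in% names(tab)) tab$calibrated <- FALSE
  key <- paste(tab$sample_id, tab$material, tab$treatment, tab$replicate,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    rows <- tab[idx, ]
    dup <- duplicated(rows$size[!is.na(rows$size)])
    if (any(dup)) {
      stop("duplicate (sample, size) row for sample '", rows$sample_id[1],
           "' at row ", idx[which(dup)[1]])
    }
    peaks <- rows[!is.na(rows$size), c("size", "height")]
    fingerprint(rows$sample_id[1], rows$material[1], rows$treatment[1],
                rows$replicate[1], peaks, calibrated = rows$calibrated[1])
  })
  names(out) <- NULL
  out
}

#' Write fingerprints to a peak-table CSV
#'
#' Inverse of [read_peak_table()]; the round trip is lossless.
#'
#' @param fps List of [fingerprint()]s.
#' @param path Output CSV path.
#' @export
write_peak_table <- function(fps, path) {
  rows <- lapply(fps, function(fp) {
    if (nrow(fp$peaks) == 0) {
      peaks <- data.frame(size = NA_real_, height = NA_real_)
    } else {
      peaks <- fp$peaks
    }
    data.frame(sample_id = fp$sample_id, material = fp$material,
               treatment = fp$treatment, replicate = fp$replicate,
               size = peaks$size, height = peaks$height,
               calibrated = fp$calibrated)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(fps)
}

#' Ladder calibration object
#'
#' Size-standard fragments pairing instrument migration values with known bp.
#'
#' @param migration Migration-unit values of the ladder fragments.
#' @param bp Known fragment sizes in bp; must be strictly monotone in
#'   migration order (calibration must be invertible).
#' @return Object of class `ladder_calibration`.
#' @export
ladder_calibration <- function(migration, bp) {
  if (length(migration) < 2 || length(bp) != length(migration)) {
    stop("ladder needs at least 2 (migration, bp) pairs")
  }
  ord <- order(migration)
  migration <- migration[ord]
  bp <- bp[ord]
  d <- diff(bp)
  if (!(all(d > 0) || all(d < 0))) {
    stop("ladder bp must be strictly monotone with migration")
  }
  structure(list(migration = migration, bp = bp),
            class = "ladder_calibration")
}

#' Read a ladder CSV (columns `migration`, `bp`)
#' @param path CSV path.
#' @return A [ladder_calibration()].
#' @export
read_ladder <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ladder_calibration(tab$migration, tab$bp)
}

#' Calibrate peak sizes from migration units to bp
#'
#' Piecewise-linear interpolation between ladder points.  Peaks beyond the
#' ladder ends are extrapolated with the terminal segment's slope for at most
#' one segment length (flagged with a message); farther peaks are an error.
#'
#' @param fp A [fingerprint()] with `size` in migration units (or a bare
#'   numeric vector of migration values).
#' @param ladder A [ladder_calibration()].
#' @return The fingerprint with `size` in bp and `calibrated = TRUE` (or the
#'   calibrated numeric vector).
#' @export
calibrate_sizes <- function(fp, ladder) {
  x <- ladder$migration
  y <- ladder$bp
  calibrate_vec <- function(m) {
    n <- length(x)
    lo <- x[1] - (x[2] - x[1])
    hi <- x[n] + (x[n] - x[n - 1])
    if (any(m < lo | m > hi)) {
      stop("peak migration more than one segment beyond ladder span")
    }
    out <- stats::approx(x, y, xout = m, rule = 1)$y
    below <- m < x[1]
    above <- m > x[n]
    if (any(below)) {
      out[below] <- y[1] + (m[below] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    }
    if (any(above)) {
      out[above] <- y[n] +
        (m[above] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    }
    if (any(below | above)) {
      message(sum(below | above), " peak(s) extrapolated beyond ladder ends")
    }
    out
  }
  if (is.numeric(fp)) return(calibrate_vec(fp))
  if (fp$calibrated) return(fp)
  if (nrow(fp$peaks) > 0) {
    fp$peaks$size <- calibrate_vec(fp$peaks$size)
    fp$peaks <- fp$peaks[order(fp$peaks$size), ]
    rownames(fp$peaks) <- NULL
  }
  fp$calibrated <- TRUE
  fp
}

#' Bin a calibrated fingerprint onto an integer bp continuum
#'
#' Each peak's height is added to the bin `round(size)` (half-up); peaks
#' outside `[min_bp, max_bp]` are dropped and counted.
#'
#' @param fp A calibrated [fingerprint()].
#' @param min_bp,max_bp Continuum range (defaults 50 and 1100 bp).
#' @return Object of class `binned_fingerprint`: a list with `bins` (named
#'   numeric vector indexed by integer bp), `min_bp`, `max_bp`, `n_dropped`
#'   and the sample metadata in `meta`.
#' @export
bin_to_continuum <- function(fp, min_bp = 50, max_bp = 1100) {
  if (!fp$calibrated) stop("fingerprint must be calibrated before binning")
  bins <- stats::setNames(numeric(max_bp - min_bp + 1),
                          as.character(min_bp:max_bp))
  n_dropped <- 0L
  if (nrow(fp$peaks) > 0) {
    b <- floor(fp$peaks$size + 0.5)  # round half-up; no ties possible
    keep <- b >= min_bp & b <= max_bp
    n_dropped <- sum(!keep)
    if (any(keep)) {
      add <- tapply(fp$peaks$height[keep], b[keep], sum)
      bins[names(add)] <- bins[names(add)] + add
    }
  }
  structure(list(bins = bins, min_bp = min_bp, max_bp = max_bp,
                 n_dropped = n_dropped,
                 meta = fp[c("sample_id", "material", "treatment",
                             "replicate")]),
            class = "binned_fingerprint")
}

#' @export
print.binned_fingerprint <- function(x, ...) {
  cat("<binned_fingerprint>", x$meta$sample_id, paste0("[", x$meta$material,
      "]"), x$meta$treatment, paste0("rep", x$meta$replicate, ":"),
      sum(x$bins > 0), "occupied bins in", x$min_bp, "-", x$max_bp, "bp\n")
  invisible(x)
}
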