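# Nearest peak to each theoretical m/z within a tolerance window, against a
# sorted peak vector. Ties in |delta| break toward the lower-m/z peak.
# Returns integer peak indices (NA where no peak falls in the window).
.nearest_peaks <- function(peak_mz, theo_mz, tol_da) {
  n <- length(peak_mz)
  if (n == 0L || length(theo_mz) == 0L) {
    return(rep(NA_integer_, length(theo_mz)))
  }
  hi <- findInterval(theo_mz, peak_mz) # last peak <= theo
  lo <- pmax(hi, 1L)
  up <- pmin(hi + 1L, n)
  d_lo <- abs(peak_mz[lo] - theo_mz)
  d_up <- abs(peak_mz[up] - theo_mz)
  pick <- ifelse(d_lo <= d_up, lo, up)          # <= : lower-m/z peak wins ties
  d <- pmin(d_lo, d_up)
  pick[hi == 0L] <- 1L                          # theo below all peaks
  d[hi == 0L] <- abs(peak_mz[1L] - theo_mz[hi == 0L])
  ifelse(d <= tol_da, pick, NA_integer_)
}

#' Annotate a spectrum against a PSM
#'
#' Generates theoretical fragments (including neutral-loss variants when
#' enabled), matches each fragment to the observed peak with smallest
#' absolute m/z difference inside the tolerance window, then extends each
#' monoisotopic match over its isotope cluster (see
#' [match_isotope_cluster()]). A single peak may carry several fragment
#' labels. Errors are recorded signed as observed minus theoretical.
#'
#' @param spec a [spectrum()] (may be empty).
#' @param psm an [xl_psm()].
#' @param settings an [annotation_settings()].
#' @return Object of class `annotated_spectrum`: list with `spectrum`, `psm`,
#'   `settings`, `fragments` (the `fragment_ions` table) and `matches`, a
#'   data frame with columns `peak_index`, `fragment_index` (row in
#'   `fragments`), `isotope_peak` (0 = monoisotopic), `error_Da`,
#'   `error_ppm`. The first annotation is snapshotted for [revert()].
#' @export
#' @examples
#' psm <- psm_from_sequences("PEPTIDE")
#' spec <- spectrum(c(227.10263, 500), c(100, 5))
#' annotate(spec, psm, annotation_settings("10ppm", c("b", "y")))
annotate <- function(spec, psm, settings = annotation_settings()) {
  stopifnot(inherits(spec, "spectrum"), inherits(psm, "xl_psm"),
            inherits(settings, "annotation_settings"))
  frags <- apply_neutral_losses(generate_fragments(psm, settings),
                                settings$losses_enabled)
  peak_mz <- spec$peaks$mz
  tol <- settings$tolerance
  matches <- data.frame(peak_index = integer(), fragment_index = integer(),
                        isotope_peak = integer(), error_Da = numeric(),
                        error_ppm = numeric())
  if (nrow(frags) > 0L && length(peak_mz) > 0L) {
    tol_da <- .tolerance_da(tol, frags$mz)
    hit <- .nearest_peaks(peak_mz, frags$mz, tol_da)
    keep <- which(!is.na(hit))
    if (length(keep)) {
      err <- peak_mz[hit[keep]] - frags$mz[keep]
      matches <- data.frame(
        peak_index = hit[keep],
        fragment_index = keep,
        isotope_peak = 0L,
        error_Da = err,
        error_ppm = err / frags$mz[keep] * 1e6
      )
    }
  }
  ann <- structure(list(
    spectrum = spec, psm = psm, settings = settings,
    fragments = frags, matches = matches, original = NULL
  ), class = "annotated_spectrum")
  ann$matches <- .extend_isotope_clusters(ann)
  ann
}

# Isotope-cluster extension for every monoisotopic match of an annotation.
.extend_isotope_clusters <- function(ann, max_k = 6L) {
  mono <- ann$matches[ann$matches$isotope_peak == 0L, , drop = FALSE]
  if (nrow(mono) == 0L) return(ann$matches)
  out <- list(ann$matches)
  for (r in seq_len(nrow(mono))) {
    out[[length(out) + 1L]] <-
      .isotope_cluster_rows(ann, mono[r, , drop = FALSE], max_k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Rows (isotope_peak >= 1) for one monoisotopic match: walk k = 1,2,... at
# spacing 1.0033548378/charge Th from the matched peak, stop at first gap.
.isotope_cluster_rows <- function(ann, match_row, max_k = 6L) {
  peak_mz <- ann$spectrum$peaks$mz
  charge <- ann$fragments$charge[match_row$fragment_index]
  base <- peak_mz[match_row$peak_index]
  spacing <- physical_constants$isotope_spacing / charge
  rows <- list()
  for (k in seq_len(max_k)) {
    expected <- base + k * spacing
    tol_da <- .tolerance_da(ann$settings$tolerance, expected)
    hit <- .nearest_peaks(peak_mz, expected, tol_da)
    if (is.na(hit)) break # first gap terminates the cluster
    err <- peak_mz[hit] - expected
    rows[[k]] <- data.frame(
      peak_index = hit, fragment_index = match_row$fragment_index,
      isotope_peak = k, error_Da = err, error_ppm = err / expected * 1e6
    )
  }
  if (length(rows)) do.call(rbind, rows) else ann$matches[0, , drop = FALSE]
}

#' Extend one monoisotopic match over its isotope cluster
#'
#' Searches for peaks at `matched m/z + k * 1.0033548378 / charge` Th for
#' k = 1, 2, ... within the annotation tolerance, stopping at the first gap
#' (clusters are capped at k <= 6).
#'
#' @param ann an [annotate()]d spectrum.
#' @param match_row one-row data frame: a monoisotopic row of `ann$matches`.
#' @param max_k cluster cap.
#' @return Data frame of additional match rows with `isotope_peak` = k.
#' @export
match_isotope_cluster <- function(ann, match_row, max_k = 6L) {
  stopifnot(inherits(ann, "annotated_spectrum"),
            match_row$isotope_peak == 0L)
  .isotope_cluster_rows(ann, match_row, max_k)
}

#' QC error points for a spectrum annotation
#'
#' One point per monoisotopic peak match: the matched peak's intensity or
#' m/z on x, the match error in ppm on y (signed, observed minus
#' theoretical, or absolute when `absolute = TRUE`). Points carry the
#' peptide id (alpha/beta) and loss status for two-colour rendering.
#'
#' @param ann an [annotate()]d spectrum.
#' @param axis `"intensity"` or `"mz"`.
#' @param absolute plot |error| instead of signed error?
#' @return Data frame with columns `x`, `error_ppm`, `peptide_id`, `loss`,
#'   `label`, `peak_index`.
#' @export
qc_points <- function(ann, axis = c("intensity", "mz"), absolute = FALSE) {
  stopifnot(inherits(ann, "annotated_spectrum"))
  axis <- match.arg(axis)
  m <- ann$matches[ann$matches$isotope_peak == 0L, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(x = numeric(), error_ppm = numeric(),
                      peptide_id = character(), loss = character(),
                      label = character(), peak_index = integer(),
                      stringsAsFactors = FALSE))
  }
  x <- ann$spectrum$peaks[[axis]][m$peak_index]
  err <- if (absolute) abs(m$error_ppm) else m$error_ppm
  data.frame(
    x = x, error_ppm = err,
    peptide_id = ann$fragments$peptide_id[m$fragment_index],
    loss = ann$fragments$loss[m$fragment_index],
    label = ann$fragments$label[m$fragment_index],
    peak_index = m$peak_index,
    stringsAsFactors = FALSE
  )
}

#' Measure the distance between two peaks
#'
#' Converts the m/z distance between two peaks into neutral mass deltas for
#' charge states 1..`max_charge` and reports amino-acid residues whose
#' monoisotopic mass lies within `tolerance` of each delta — useful for
#' explaining unannotated peaks.
#'
#' @param spec a [spectrum()].
#' @param peak_a,peak_b peak indices (1-based, in m/z order).
#' @param max_charge highest charge state considered (>= 1).
#' @param tolerance matching tolerance (see [parse_tolerance()]); ppm
#'   tolerances are taken relative to the mass delta.
#' @return Data frame with columns `charge`, `mass_delta` (Da) and
#'   `residues` (comma-separated one-letter codes, `""` when none match).
#' @export
#' @examples
#' s <- spectrum(c(200, 257.02146), c(1, 1))
#' measure(s, 1, 2, max_charge = 2, tolerance = "0.005Da")
measure <- function(spec, peak_a, peak_b, max_charge = 1L,
                    tolerance = "0.01Da") {
  stopifnot(inherits(spec, "spectrum"))
  np <- n_peaks(spec)
  if (peak_a < 1L || peak_a > np || peak_b < 1L || peak_b > np) {
    stop("peak index out of range", call. = FALSE)
  }
  if (max_charge < 1L) stop("max_charge must be >= 1", call. = FALSE)
  tol <- parse_tolerance(tolerance)
  dmz <- abs(spec$peaks$mz[peak_a] - spec$peaks$mz[peak_b])
  masses <- residue_masses()
  res <- lapply(seq_len(max_charge), function(z) {
    delta <- dmz * z
    win <- if (tol$unit == "ppm") tol$value * delta / 1e6 else tol$value
    hits <- names(masses)[delta > 0 & abs(masses - delta) <= win]
    data.frame(charge = z, mass_delta = delta,
               residues = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Re-annotate under a modified hypothesis, and revert
#'
#' `reannotate()` recomputes the annotation with a modified PSM (sequence,
#' modification positions or masses, cross-linker position, precursor
#' charge) and/or modified settings (ion types, tolerance, losses). The
#' snapshot of the first annotation is carried along so that [revert()]
#' always returns a result identical to the original annotation; the
#' original object is never mutated.
#'
#' @param ann an [annotate()]d spectrum.
#' @param psm replacement [xl_psm()] (default: keep current).
#' @param settings replacement [annotation_settings()] (default: keep).
#' @param sequences character vector of one or two sequence strings in the
#'   [parse_sequence()] grammar; rebuilds the PSM's peptides and link sites
#'   (the `#` symbol positions). Parse failure leaves `ann` untouched.
#' @param precursor_charge replacement precursor charge.
#' @param registry modification registry used to resolve `sequences`.
#' @return A new `annotated_spectrum`.
#' @export
reannotate <- function(ann, psm = NULL, settings = NULL, sequences = NULL,
                       precursor_charge = NULL,
                       registry = default_modifications()) {
  stopifnot(inherits(ann, "annotated_spectrum"))
  new_psm <- if (is.null(psm)) ann$psm else psm
  if (!is.null(sequences)) {
    parsed <- lapply(sequences, parse_sequence, registry = registry)
    new_psm$peptides <- lapply(parsed, `[[`, "peptide")
    new_psm$link_positions <- vapply(parsed, `[[`, integer(1),
                                     "link_position")
    if (length(new_psm$peptides) == 1L) new_psm$crosslinker_mass <- NA_real_
    new_psm$decoy_flags <- rep_len(new_psm$decoy_flags,
                                   length(new_psm$peptides))
  }
  if (!is.null(precursor_charge)) {
    new_psm$precursor_charge <- as.integer(precursor_charge)
  }
  new_settings <- if (is.null(settings)) ann$settings else settings
  out <- annotate(ann$spectrum, new_psm, new_settings)
  snapshot <- if (is.null(ann$original)) ann else ann$original
  out$original <- snapshot
  out
}

#' @rdname reannotate
#' @export
revert <- function(ann) {
  stopifnot(inherits(ann, "annotated_spectrum"))
  if (is.null(ann$original)) ann else ann$original
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  mono <- sum(x$matches$isotope_peak == 0L)
  cat("<annotated_spectrum> ", n_peaks(x$spectrum), " peaks, ",
      nrow(x$fragments), " theoretical fragments, ", mono,
      " matched (+", nrow(x$matches) - mono, " isotope peaks), tol ",
      x$settings$tolerance$value, x$settings$tolerance$unit, "\n", sep = "")
  invisible(x)
}
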