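#' Build a dataset from a peak-list file and an identification file
#'
#' Parses both inputs, resolves every PSM's spectrum reference against the
#' peak-list index and bundles spectra, PSMs and the modification registry
#' into one object that can be persisted as a single file with
#' [save_dataset()]. Scan resolution order: explicit `scanIndex`, then
#' `scanNumber` (matched against MGF `SCANS` / mzML nativeID), then MGF
#' `TITLE`.
#'
#' @param peaks_file MGF or mzML path (optionally compressed).
#' @param ids_file mzIdentML or CSV path.
#' @param identifier dataset identifier (defaults to the ids file name).
#' @param registry base modification registry; entries found in the
#'   identification file are merged on top.
#' @return Object of class `xl_dataset`: list with `identifier`, `spectra`
#'   (named list of [spectrum()]), `psms`, `modifications`, `provenance`.
#' @export
create_dataset <- function(peaks_file, ids_file, identifier = NULL,
                           registry = default_modifications()) {
  pk_fmt <- sniff_format(peaks_file)
  spectra <- switch(pk_fmt,
    mgf = read_mgf_spectra(peaks_file),
    mzml = read_mzml(peaks_file),
    stop("unsupported peak-list format for ", peaks_file,
         " (supported: mgf, mzml)", call. = FALSE)
  )
  id_fmt <- sniff_format(ids_file)
  ids <- switch(id_fmt,
    mzid = read_mzidentml(ids_file),
    csv = list(psms = read_csv_ids(ids_file, registry),
               modifications = modification_registry()),
    stop("unsupported identification format for ", ids_file,
         " (supported: mzid, csv)", call. = FALSE)
  )
  for (i in seq_len(nrow(ids$modifications))) {
    registry <- register_modification(
      registry, ids$modifications$name[i], ids$modifications$mass_delta[i],
      ids$modifications$specificity[i], "input-data")
  }
  ds <- structure(list(
    identifier = if (is.null(identifier)) basename(ids_file) else identifier,
    spectra = spectra,
    psms = ids$psms,
    modifications = registry,
    provenance = list(peaks_file = basename(peaks_file),
                      ids_file = basename(ids_file),
                      parsed_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "xl_dataset")
  for (p in ds$psms) .resolve_spectrum(ds, p) # every reference must resolve
  ds
}

# Locate the spectrum a PSM refers to; errors if unresolvable.
.resolve_spectrum <- function(dataset, psm) {
  sc <- psm$scan
  n <- length(dataset$spectra)
  idx <- sc$scan_index
  if (!is.null(idx) && length(idx) && !is.na(idx)) {
    if (idx >= 1L && idx <= n) return(dataset$spectra[[idx]])
    stop("PSM ", psm$id, ": scan index ", idx, " out of range",
         call. = FALSE)
  }
  num <- sc$scan_number
  if (!is.null(num) && length(num) && !is.na(num)) {
    for (s in dataset$spectra) {
      if (!is.null(s$source$scan) && !is.na(s$source$scan) &&
          as.character(s$source$scan) == as.character(num)) return(s)
    }
  }
  ttl <- sc$title
  if (!is.null(ttl) && length(ttl) && !is.na(ttl)) {
    for (s in dataset$spectra) {
      if (identical(s$source$title, ttl)) return(s)
    }
  }
  stop("PSM ", psm$id, ": spectrum reference does not resolve ",
       "(scan_number=", if (is.null(num)) NA else num, ")", call. = FALSE)
}

#' Fetch the spectrum for one PSM of a dataset
#' @param dataset an `xl_dataset`.
#' @param psm one of its [xl_psm()] entries.
#' @return A [spectrum()].
#' @export
dataset_spectrum <- function(dataset, psm) {
  stopifnot(inherits(dataset, "xl_dataset"))
  .resolve_spectrum(dataset, psm)
}

#' PSM table filter
#'
#' @param hide_decoys drop PSMs with any decoy peptide?
#' @param hide_below_threshold drop PSMs failing the search threshold?
#' @param hide_linear drop non-cross-linked PSMs?
#' @param text_query substring matched (fixed, case-insensitive) against
#'   peptide sequences and protein accessions; `""` matches everything.
#' @param order_by_score score name to order by, descending (`NA`: keep
#'   input order). The name must be present in at least one PSM.
#' @return Object of class `psm_filter`.
#' @export
psm_filter <- function(hide_decoys = FALSE, hide_below_threshold = FALSE,
                       hide_linear = FALSE, text_query = "",
                       order_by_score = NA_character_) {
  structure(list(
    hide_decoys = isTRUE(hide_decoys),
    hide_below_threshold = isTRUE(hide_below_threshold),
    hide_linear = isTRUE(hide_linear),
    text_query = as.character(text_query),
    order_by_score = as.character(order_by_score)
  ), class = "psm_filter")
}

#' List PSMs of a dataset, filtered and ordered
#'
#' Applies the decoy / threshold / linear toggles, a substring search over
#' peptide sequences and protein fields, and descending ordering by the
#' chosen score.
#'
#' @param dataset an `xl_dataset`.
#' @param filter a [psm_filter()].
#' @return List of [xl_psm()] objects.
#' @export
list_psms <- function(dataset, filter = psm_filter()) {
  stopifnot(inherits(dataset, "xl_dataset"), inherits(filter, "psm_filter"))
  psms <- dataset$psms
  if (!is.na(filter$order_by_score)) {
    present <- any(vapply(psms, function(p)
      filter$order_by_score %in% names(p$scores), logical(1)))
    if (!present) stop("unknown score name: '", filter$order_by_score, "'",
                       call. = FALSE)
  }
  keep <- vapply(psms, function(p) {
    if (filter$hide_decoys && any(p$decoy_flags)) return(FALSE)
    if (filter$hide_below_threshold && !p$pass_threshold) return(FALSE)
    if (filter$hide_linear && !is_crosslinked(p)) return(FALSE)
    if (nzchar(filter$text_query)) {
      hay <- c(vapply(p$peptides, function(q)
        paste(q$sequence, collapse = ""), character(1)),
        as.character(p$scan$proteins))
      if (!any(grepl(filter$text_query, hay, fixed = FALSE,
                     ignore.case = TRUE))) return(FALSE)
    }
    TRUE
  }, logical(1))
  psms <- psms[keep]
  if (!is.na(filter$order_by_score) && length(psms)) {
    sc <- vapply(psms, function(p) {
      v <- p$scores[[filter$order_by_score]]
      if (is.null(v)) -Inf else as.numeric(v)
    }, numeric(1))
    psms <- psms[order(sc, decreasing = TRUE)]
  }
  psms
}

# ---- single-file persistence -------------------------------------------

.psm_to_list <- function(p) {
  list(
    peptides = lapply(seq_along(p$peptides), function(k) {
      .peptide_to_list(p$peptides[[k]], p$link_positions[k])
    }),
    crosslinker_mass = if (is.na(p$crosslinker_mass)) NULL
                       else p$crosslinker_mass,
    precursor_charge = p$precursor_charge,
    precursor_mz = if (is.na(p$precursor_mz)) NULL else p$precursor_mz,
    scores = as.list(p$scores),
    decoy_flags = as.list(p$decoy_flags),
    pass_threshold = p$pass_threshold,
    rank = p$rank,
    id = p$id,
    scan = p$scan
  )
}

.psm_from_list <- function(x) {
  peps <- lapply(x$peptides, function(pp) {
    mods <- if (length(pp$mods)) do.call(rbind, lapply(pp$mods, function(m) {
      data.frame(position = as.integer(m$position), name = m$name,
                 mass_delta = as.numeric(m$mass_delta),
                 stringsAsFactors = FALSE)
    })) else NULL
    peptide(pp$sequence, mods)
  })
  links <- vapply(x$peptides, function(pp) {
    if (is.null(pp$link_position)) NA_integer_
    else as.integer(pp$link_position)
  }, integer(1))
  scan <- lapply(x$scan, unlist)
  xl_psm(
    peps, link_positions = links,
    crosslinker_mass = if (is.null(x$crosslinker_mass)) NA_real_
                       else x$crosslinker_mass,
    precursor_charge = x$precursor_charge,
    precursor_mz = if (is.null(x$precursor_mz)) NA_real_
                   else x$precursor_mz,
    scores = unlist(x$scores),
    decoy_flags = unlist(x$decoy_flags),
    pass_threshold = x$pass_threshold,
    rank = x$rank, id = x$id, scan = scan
  )
}

#' Save / load a dataset as a single file
#'
#' One self-contained JSON file per dataset: spectra (full peak lists),
#' PSMs, the modification registry snapshot and provenance. Loading
#' reconstructs an `xl_dataset` that annotates identically.
#'
#' @param dataset an `xl_dataset`.
#' @param path file path (conventionally `.fmds.json`).
#' @return [save_dataset()]: `path`, invisibly. [load_dataset()]: the
#'   `xl_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "xl_dataset"))
  doc <- list(
    format_version = .ANNOTATION_FORMAT_VERSION,
    identifier = dataset$identifier,
    provenance = dataset$provenance,
    modifications = as.data.frame(dataset$modifications),
    spectra = lapply(dataset$spectra, function(s) {
      list(peaks = s$peaks, source = s$source,
           precursor = s$precursor)
    }),
    psms = lapply(dataset$psms, .psm_to_list)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", null = "null",
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) || is.null(doc$psms) ||
      is.null(doc$spectra)) {
    stop("not a dataset file (schema validation failed): ", path,
         call. = FALSE)
  }
  mods <- doc$modifications
  registry <- modification_registry(unlist(mods$name),
                                    unlist(mods$mass_delta),
                                    unlist(mods$specificity),
                                    unlist(mods$origin))
  spectra <- lapply(doc$spectra, function(s) {
    prec <- s$precursor
    if (!is.null(prec)) {
      prec <- lapply(prec, function(v) if (is.null(v)) NA else unlist(v))
      if (is.null(prec$mz) || all(is.na(unlist(prec$mz)))) prec <- NULL
    }
    spectrum(unlist(s$peaks$mz), unlist(s$peaks$intensity),
             source = lapply(s$source, unlist), precursor = prec)
  })
  psms <- lapply(doc$psms, .psm_from_list)
  ds <- structure(list(
    identifier = doc$identifier,
    spectra = spectra,
    psms = psms,
    modifications = registry,
    provenance = doc$provenance
  ), class = "xl_dataset")
  for (p in ds$psms) .resolve_spectrum(ds, p)
  ds
}

#' @export
print.xl_dataset <- function(x, ...) {
  nxl <- sum(vapply(x$psms, is_crosslinked, logical(1)))
  cat("<xl_dataset> '", x$identifier, "': ", length(x$spectra),
      " spectra, ", length(x$psms), " PSMs (", nxl, " cross-linked)\n",
      sep = "")
  invisible(x)
}
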