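#' Construct a (possibly cross-linked) peptide-spectrum match
#'
#' A PSM assigns one (linear) or two (cross-linked) peptides to a spectrum.
#' For cross-linked PSMs both link positions and the cross-linker mass must
#' be given; fragments spanning a link site carry the linker plus the entire
#' partner peptide mass.
#'
#' @param peptides a single [peptide()] or list of one or two peptides
#'   (alpha, beta).
#' @param link_positions integer vector of per-peptide 1-based link sites
#'   (`NA`/absent for linear PSMs).
#' @param crosslinker_mass cross-linker mass in Da (required iff two
#'   peptides).
#' @param precursor_charge precursor charge state (integer >= 1).
#' @param precursor_mz optional observed precursor m/z (Th).
#' @param scores named numeric vector of search-engine scores.
#' @param decoy_flags logical vector, one per peptide.
#' @param pass_threshold did the identification pass the search software's
#'   threshold?
#' @param rank identification rank (1 = top match; >1 = alternative
#'   explanation).
#' @param id optional identifier.
#' @param scan list locating the spectrum: any of `scan_number`,
#'   `scan_index`, `peaklist_file`, `title`.
#' @return Object of class `xl_psm`.
#' @export
#' @examples
#' p <- parse_sequence("GK#")
#' xl_psm(list(p$peptide, p$peptide),
#'        link_positions = c(2, 2), crosslinker_mass = 138.06808,
#'        precursor_charge = 3)
xl_psm <- function(peptides, link_positions = NA_integer_,
                   crosslinker_mass = NA_real_, precursor_charge = 2L,
                   precursor_mz = NA_real_, scores = numeric(),
                   decoy_flags = NULL, pass_threshold = TRUE, rank = 1L,
                   id = NA_character_, scan = list()) {
  if (inherits(peptides, "peptide")) peptides <- list(peptides)
  stopifnot(length(peptides) %in% 1:2,
            all(vapply(peptides, inherits, logical(1), "peptide")))
  np <- length(peptides)
  link_positions <- rep_len(as.integer(link_positions), np)
  if (np == 2L) {
    if (any(is.na(link_positions)) || !is.finite(crosslinker_mass)) {
      stop("cross-linked PSM needs both link positions and a ",
           "crosslinker_mass", call. = FALSE)
    }
  }
  for (k in seq_len(np)) {
    if (!is.na(link_positions[k]) &&
        (link_positions[k] < 1L ||
         link_positions[k] > length(peptides[[k]]$sequence))) {
      stop("link position ", link_positions[k],
           " outside peptide ", k, call. = FALSE)
    }
  }
  if (precursor_charge < 1L) stop("precursor_charge must be >= 1",
                                  call. = FALSE)
  if (is.null(decoy_flags)) decoy_flags <- rep(FALSE, np)
  structure(list(
    peptides = peptides,
    link_positions = link_positions,
    crosslinker_mass = as.numeric(crosslinker_mass),
    precursor_charge = as.integer(precursor_charge),
    precursor_mz = as.numeric(precursor_mz),
    scores = scores,
    decoy_flags = rep_len(as.logical(decoy_flags), np),
    pass_threshold = isTRUE(pass_threshold),
    rank = as.integer(rank),
    id = as.character(id),
    scan = scan
  ), class = "xl_psm")
}

#' Is this PSM cross-linked?
#' @param psm an [xl_psm()].
#' @return Logical scalar.
#' @export
is_crosslinked <- function(psm) {
  stopifnot(inherits(psm, "xl_psm"))
  length(psm$peptides) == 2L
}

#' Parse a PSM from one or two sequence strings
#'
#' Convenience wrapper over [parse_sequence()] and [xl_psm()]: link sites are
#' taken from the `#` symbols in the strings.
#'
#' @param seq1,seq2 sequence strings in the [parse_sequence()] grammar;
#'   `seq2 = NA` gives a linear PSM.
#' @param crosslinker_mass linker mass in Da (cross-linked only).
#' @param precursor_charge charge state.
#' @param registry modification registry.
#' @param ... further arguments passed to [xl_psm()].
#' @return An `xl_psm`.
#' @export
#' @examples
#' psm_from_sequences("GK#", "GK#", crosslinker_mass = 138.06808,
#'                    precursor_charge = 3)
psm_from_sequences <- function(seq1, seq2 = NA_character_,
                               crosslinker_mass = NA_real_,
                               precursor_charge = 2L,
                               registry = default_modifications(), ...) {
  a <- parse_sequence(seq1, registry)
  if (is.na(seq2) || !nzchar(seq2)) {
    xl_psm(list(a$peptide),
           link_positions = a$link_position,
           precursor_charge = precursor_charge, ...)
  } else {
    b <- parse_sequence(seq2, registry)
    xl_psm(list(a$peptide, b$peptide),
           link_positions = c(a$link_position, b$link_position),
           crosslinker_mass = crosslinker_mass,
           precursor_charge = precursor_charge, ...)
  }
}

#' @export
print.xl_psm <- function(x, ...) {
  seqs <- vapply(seq_along(x$peptides), function(k) {
    render_sequence(x$peptides[[k]], x$link_positions[k])
  }, character(1))
  cat("<xl_psm> ", paste(seqs, collapse = " -- "),
      if (is_crosslinked(x)) sprintf("  linker %.5f Da", x$crosslinker_mass),
      sprintf("  z=%d rank=%d%s", x$precursor_charge, x$rank,
              if (any(x$decoy_flags)) " decoy" else ""), "\n", sep = "")
  invisible(x)
}
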