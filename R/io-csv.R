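#' Read PSMs from the CSV identification dialect
#'
#' A simple comma-separated format for non-standard search results, defined
#' by this package (see the README for the frozen column table). Recognised
#' columns: `id`, `scanNumber`, `scanIndex`, `peakListFileName`, `pepSeq1`,
#' `pepSeq2`, `linkPos1`, `linkPos2`, `crosslinkerModMass`, `charge`,
#' `score`, `protein1`, `protein2`, `decoy1`, `decoy2`, `passThreshold`,
#' `fragmentTolerance`, `ionTypes`, `rank`. Peptide sequences use the
#' [parse_sequence()] grammar (lowercase modification tokens, `#` cross-link
#' symbol; explicit `linkPos` columns override `#`). An empty `pepSeq2`
#' means a linear PSM. Unknown extra columns are preserved: numeric ones as
#' additional scores, others as opaque metadata.
#'
#' @param path CSV path (optionally `.gz`/`.zip`).
#' @param registry modification registry for sequence parsing.
#' @return List of [xl_psm()] objects.
#' @export
read_csv_ids <- function(path, registry = default_modifications()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(.maybe_decompress(path), stringsAsFactors = FALSE,
                         check.names = FALSE)
  cols <- names(tab)
  if (!"pepSeq1" %in% cols) stop("missing mandatory column: pepSeq1",
                                 call. = FALSE)
  if (!"charge" %in% cols) stop("missing mandatory column: charge",
                                call. = FALSE)
  if (!any(c("scanNumber", "scanIndex") %in% cols)) {
    stop("missing mandatory column: scanNumber or scanIndex", call. = FALSE)
  }
  known <- c("id", "scanNumber", "scanIndex", "peakListFileName", "pepSeq1",
             "pepSeq2", "linkPos1", "linkPos2", "crosslinkerModMass",
             "charge", "score", "protein1", "protein2", "decoy1", "decoy2",
             "passThreshold", "fragmentTolerance", "ionTypes", "rank")
  extra <- setdiff(cols, known)
  getcol <- function(row, name, default = NA) {
    if (name %in% cols) tab[row, name] else default
  }
  as_flag <- function(x, default = FALSE) {
    if (is.na(x) || !nzchar(as.character(x))) return(default)
    tolower(as.character(x)) %in% c("true", "1", "t", "yes")
  }
  lapply(seq_len(nrow(tab)), function(r) {
    seq1 <- as.character(getcol(r, "pepSeq1"))
    seq2 <- as.character(getcol(r, "pepSeq2", NA_character_))
    linear <- is.na(seq2) || !nzchar(seq2)
    a <- parse_sequence(seq1, registry)
    lp1 <- suppressWarnings(as.integer(getcol(r, "linkPos1")))
    if (is.na(lp1)) lp1 <- a$link_position
    xmass <- suppressWarnings(as.numeric(getcol(r, "crosslinkerModMass")))
    if (linear) {
      if (!is.na(lp1) && is.na(xmass)) {
        stop("row ", r, ": linkPos without pepSeq2 and without ",
             "crosslinkerModMass", call. = FALSE)
      }
      peptides <- list(a$peptide)
      links <- lp1
      # a link site with a crosslinker mass but no partner peptide is
      # treated as a mono-link style fixed modification
      if (!is.na(lp1) && !is.na(xmass)) {
        mods <- rbind(a$peptide$mods, data.frame(
          position = lp1, name = "xlmono", mass_delta = xmass,
          stringsAsFactors = FALSE))
        peptides <- list(peptide(a$peptide$sequence, mods))
        links <- NA_integer_
      }
      xmass_use <- NA_real_
    } else {
      b <- parse_sequence(seq2, registry)
      lp2 <- suppressWarnings(as.integer(getcol(r, "linkPos2")))
      if (is.na(lp2)) lp2 <- b$link_position
      peptides <- list(a$peptide, b$peptide)
      links <- c(lp1, lp2)
      xmass_use <- xmass
    }
    scores <- numeric(0)
    sc <- suppressWarnings(as.numeric(getcol(r, "score")))
    if (!is.na(sc)) scores <- c(scores, score = sc)
    meta <- list()
    for (e in extra) {
      v <- tab[r, e]
      nv <- suppressWarnings(as.numeric(v))
      if (!is.na(nv)) {
        scores[[e]] <- nv
      } else {
        meta[[e]] <- v
      }
    }
    rank <- suppressWarnings(as.integer(getcol(r, "rank")))
    xl_psm(
      peptides, link_positions = links, crosslinker_mass = xmass_use,
      precursor_charge = as.integer(getcol(r, "charge")),
      scores = scores,
      decoy_flags = c(as_flag(getcol(r, "decoy1")),
                      if (!linear) as_flag(getcol(r, "decoy2"))),
      pass_threshold = as_flag(getcol(r, "passThreshold"), TRUE),
      rank = if (is.na(rank)) 1L else rank,
      id = as.character(if (!is.na(getcol(r, "id"))) getcol(r, "id")
                        else r),
      scan = list(
        scan_number = suppressWarnings(
          as.integer(getcol(r, "scanNumber"))),
        scan_index = suppressWarnings(as.integer(getcol(r, "scanIndex"))),
        peaklist_file = as.character(getcol(r, "peakListFileName",
                                            NA_character_)),
        proteins = stats::na.omit(c(as.character(getcol(r, "protein1")),
                                    as.character(getcol(r, "protein2")))),
        fragment_tolerance = as.character(getcol(r, "fragmentTolerance",
                                                 NA_character_)),
        ion_types = as.character(getcol(r, "ionTypes", NA_character_)),
        metadata = meta
      )
    )
  })
}

#' Write PSMs to the CSV identification dialect
#'
#' @param psms list of [xl_psm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_ids <- function(psms, path) {
  rows <- lapply(seq_along(psms), function(k) {
    p <- psms[[k]]
    xl <- is_crosslinked(p)
    data.frame(
      id = p$id,
      scanNumber = if (!is.null(p$scan$scan_number)) p$scan$scan_number
                   else NA_integer_,
      scanIndex = if (!is.null(p$scan$scan_index)) p$scan$scan_index
                  else NA_integer_,
      peakListFileName = if (!is.null(p$scan$peaklist_file))
        p$scan$peaklist_file else NA_character_,
      pepSeq1 = render_sequence(p$peptides[[1L]], p$link_positions[1L]),
      pepSeq2 = if (xl) render_sequence(p$peptides[[2L]],
                                        p$link_positions[2L]) else "",
      linkPos1 = p$link_positions[1L],
      linkPos2 = if (xl) p$link_positions[2L] else NA_integer_,
      crosslinkerModMass = p$crosslinker_mass,
      charge = p$precursor_charge,
      score = if ("score" %in% names(p$scores)) p$scores[["score"]]
              else if (length(p$scores)) p$scores[[1L]] else NA_real_,
      protein1 = if (length(p$scan$proteins) >= 1L) p$scan$proteins[1L]
                 else NA_character_,
      protein2 = if (length(p$scan$proteins) >= 2L) p$scan$proteins[2L]
                 else NA_character_,
      decoy1 = p$decoy_flags[1L],
      decoy2 = if (xl) p$decoy_flags[2L] else NA,
      passThreshold = p$pass_threshold,
      rank = p$rank,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
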