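# Cross-link donor/acceptor cvParam accessions (PSI-MS, mzIdentML 1.2)
.XL_DONOR <- "MS:1002509"
.XL_ACCEPTOR <- "MS:1002510"

# Parse one mzIdentML <Peptide> element -> list(peptide, xl = NULL or
# list(role, value, position, mass_delta)).
.parse_mzid_peptide <- function(node) {
  seq_txt <- xml2::xml_text(xml2::xml_find_first(node, ".//PeptideSequence"))
  mods <- xml2::xml_find_all(node, ".//Modification")
  mod_rows <- list()
  xl <- NULL
  for (m in mods) {
    loc <- as.integer(xml2::xml_attr(m, "location"))
    delta <- as.numeric(xml2::xml_attr(m, "monoisotopicMassDelta"))
    cvs <- xml2::xml_find_all(m, ".//cvParam")
    acc <- xml2::xml_attr(cvs, "accession")
    if (.XL_DONOR %in% acc || .XL_ACCEPTOR %in% acc) {
      role <- if (.XL_DONOR %in% acc) "donor" else "acceptor"
      val <- xml2::xml_attr(cvs, "value")[match(
        if (role == "donor") .XL_DONOR else .XL_ACCEPTOR, acc)]
      xl <- list(role = role, value = val, position = loc,
                 mass_delta = delta)
    } else {
      nm <- xml2::xml_attr(cvs, "name")
      token <- if (length(nm) && !is.na(nm[1L])) {
        tolower(gsub("[^a-z0-9]", "", tolower(nm[1L])))
      } else "mod"
      if (!nzchar(token) || !grepl("^[a-z]", token)) token <- "mod"
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        position = loc, name = token, mass_delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  mods_df <- if (length(mod_rows)) do.call(rbind, mod_rows) else NULL
  list(peptide = peptide(seq_txt, mods_df), xl = xl)
}

#' Read PSMs from an mzIdentML (1.1/1.2) document
#'
#' `SpectrumIdentificationItem` elements become PSMs with ranks, scores,
#' decoy and threshold flags. Cross-linked identifications — pairs of items
#' whose peptides carry cross-link donor and acceptor `cvParam`s
#' (`MS:1002509`/`MS:1002510`) sharing a value — are fused into a single
#' cross-linked PSM; the donor's `monoisotopicMassDelta` supplies the
#' cross-linker mass.
#'
#' @param path path to an mzIdentML document (optionally `.gz`/`.zip`).
#' @return List with `psms` (list of [xl_psm()]) and `modifications`
#'   (a `mod_registry` of the distinct non-cross-link modifications seen).
#' @export
read_mzidentml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(.maybe_decompress(path))
  xml2::xml_ns_strip(doc)

  pep_nodes <- xml2::xml_find_all(doc, ".//SequenceCollection/Peptide")
  peps <- lapply(pep_nodes, .parse_mzid_peptide)
  names(peps) <- xml2::xml_attr(pep_nodes, "id")

  db_nodes <- xml2::xml_find_all(doc, ".//DBSequence")
  db_acc <- xml2::xml_attr(db_nodes, "accession")
  names(db_acc) <- xml2::xml_attr(db_nodes, "id")

  pe_nodes <- xml2::xml_find_all(doc, ".//PeptideEvidence")
  pe_decoy <- xml2::xml_attr(pe_nodes, "isDecoy") %in% c("true", "1")
  names(pe_decoy) <- xml2::xml_attr(pe_nodes, "id")
  pe_pep <- xml2::xml_attr(pe_nodes, "peptide_ref")
  db_ref <- xml2::xml_attr(pe_nodes, "dBSequence_ref")
  pe_protein <- ifelse(is.na(db_acc[db_ref]), db_ref, db_acc[db_ref])
  names(pe_protein) <- names(pe_decoy)

  results <- xml2::xml_find_all(doc, ".//SpectrumIdentificationResult")
  psms <- list()
  for (res in results) {
    spec_id <- xml2::xml_attr(res, "spectrumID")
    siis <- xml2::xml_find_all(res, ".//SpectrumIdentificationItem")
    info <- lapply(siis, function(sii) {
      pref <- xml2::xml_attr(sii, "peptide_ref")
      pev <- xml2::xml_attr(
        xml2::xml_find_all(sii, ".//PeptideEvidenceRef"),
        "peptideEvidence_ref")
      cvs <- xml2::xml_find_all(sii, ".//cvParam")
      acc <- xml2::xml_attr(cvs, "accession")
      vals <- xml2::xml_attr(cvs, "value")
      nms <- xml2::xml_attr(cvs, "name")
      score_i <- which(!is.na(vals) & nzchar(vals) &
                         suppressWarnings(!is.na(as.numeric(vals))))
      scores <- as.numeric(vals[score_i])
      names(scores) <- nms[score_i]
      list(
        pep = peps[[pref]],
        rank = as.integer(xml2::xml_attr(sii, "rank")),
        charge = as.integer(xml2::xml_attr(sii, "chargeState")),
        mz = as.numeric(xml2::xml_attr(sii, "experimentalMassToCharge")),
        pass = xml2::xml_attr(sii, "passThreshold") %in% c("true", "1"),
        decoy = any(pe_decoy[pev], na.rm = TRUE),
        proteins = unname(pe_protein[pev]),
        scores = scores,
        id = xml2::xml_attr(sii, "id")
      )
    })
    xlv <- vapply(info, function(x) {
      if (is.null(x$pep$xl)) NA_character_ else x$pep$xl$value
    }, character(1))
    consumed <- rep(FALSE, length(info))
    for (k in seq_along(info)) {
      if (consumed[k]) next
      it <- info[[k]]
      if (!is.null(it$pep$xl)) {
        mate <- which(!consumed & seq_along(info) != k & xlv == xlv[k])
        if (!length(mate)) {
          stop("cross-link ", it$pep$xl$role, " without matching partner ",
               "for value '", xlv[k], "' in spectrum ", spec_id,
               call. = FALSE)
        }
        mate <- mate[1L]
        consumed[c(k, mate)] <- TRUE
        donor <- if (it$pep$xl$role == "donor") it else info[[mate]]
        accept <- if (it$pep$xl$role == "donor") info[[mate]] else it
        psms[[length(psms) + 1L]] <- xl_psm(
          list(donor$pep$peptide, accept$pep$peptide),
          link_positions = c(donor$pep$xl$position,
                             accept$pep$xl$position),
          crosslinker_mass = donor$pep$xl$mass_delta,
          precursor_charge = donor$charge,
          precursor_mz = donor$mz,
          scores = donor$scores,
          decoy_flags = c(donor$decoy, accept$decoy),
          pass_threshold = donor$pass,
          rank = donor$rank,
          id = donor$id,
          scan = list(scan_number = spec_id, proteins = unique(
            c(donor$proteins, accept$proteins)))
        )
      } else {
        consumed[k] <- TRUE
        psms[[length(psms) + 1L]] <- xl_psm(
          list(it$pep$peptide),
          precursor_charge = it$charge,
          precursor_mz = it$mz,
          scores = it$scores,
          decoy_flags = it$decoy,
          pass_threshold = it$pass,
          rank = it$rank,
          id = it$id,
          scan = list(scan_number = spec_id, proteins = it$proteins)
        )
      }
    }
  }

  mod_tab <- unique(do.call(rbind, c(list(data.frame(
    name = character(), mass_delta = numeric(), stringsAsFactors = FALSE)),
    lapply(peps, function(p) {
      if (nrow(p$peptide$mods)) p$peptide$mods[, c("name", "mass_delta")]
      else NULL
    }))))
  registry <- modification_registry(mod_tab$name, mod_tab$mass_delta,
                                    origin = "input-data")
  list(psms = psms, modifications = registry)
}
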