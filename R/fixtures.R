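#' Specification for the synthetic fixture generator
#'
#' Describes a synthetic corpus of PSMs and spectra: random tryptic-like
#' peptides, a fraction cross-linked (BS3/DSS-style linker, 138.06808 Da,
#' preferring lysine link sites), spectra containing every b/y (and
#' cross-link-shifted) fragment peak with Gaussian ppm jitter plus
#' uniform-random noise peaks, and a ground-truth table recording which
#' peak is which fragment.
#'
#' @param n_psms number of PSMs to generate.
#' @param length_range integer range of peptide lengths.
#' @param crosslink_fraction fraction of PSMs that are cross-linked, in
#'   \[0,1\].
#' @param noise_peaks uniform-random noise peaks per spectrum.
#' @param jitter_ppm Gaussian sigma of the mass error applied to fragment
#'   peaks, in ppm.
#' @param decoy_fraction fraction of PSMs flagged as decoys, in \[0,1\].
#' @param seed integer seed fixing all randomness.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_psms = 50L, length_range = c(6L, 15L),
                         crosslink_fraction = 0.5, noise_peaks = 30L,
                         jitter_ppm = 5, decoy_fraction = 0.1,
                         seed = 1L) {
  stopifnot(n_psms >= 1L,
            crosslink_fraction >= 0, crosslink_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            jitter_ppm >= 0, noise_peaks >= 0L)
  structure(list(
    n_psms = as.integer(n_psms),
    length_range = as.integer(length_range),
    crosslink_fraction = crosslink_fraction,
    noise_peaks = as.integer(noise_peaks),
    jitter_ppm = jitter_ppm,
    decoy_fraction = decoy_fraction,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

.XL_LINKER_MASS <- 138.06808 # BS3/DSS residue-pair bridge

# Run code with a private RNG state under the given seed.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_peptide_string <- function(len) {
  aa <- names(residue_masses())
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

#' Generate synthetic MGF + CSV fixtures with ground truth
#'
#' For each synthetic PSM the spectrum contains one peak per theoretical
#' b/y fragment (cross-link-shifted where applicable, charges 1..2 capped
#' at the precursor charge) with ppm jitter drawn from
#' `N(0, jitter_ppm^2)`, plus uniform noise peaks. Outputs are
#' byte-deterministic for a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the three outputs.
#' @return List with paths `mgf`, `csv`, `truth` and the in-memory pieces:
#'   `psms`, `spectra`, `truth` (data frame: `psm_id`, `scan`,
#'   `peak_index`, `label`, `charge`, `theoretical_mz`).
#' @export
make_fixtures <- function(spec = fixture_spec(), dir = tempfile("fixtures"),
                          basename = "synthetic") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed, {
    psms <- list()
    spectra <- list()
    truth_rows <- list()
    set <- annotation_settings(tolerance = "20ppm", ion_types = c("b", "y"),
                               max_fragment_charge = 2L)
    for (k in seq_len(spec$n_psms)) {
      xl <- stats::runif(1) < spec$crosslink_fraction
      len1 <- sample(seq(spec$length_range[1L], spec$length_range[2L]), 1L)
      seq1 <- .random_peptide_string(len1)
      decoy <- stats::runif(1) < spec$decoy_fraction
      if (xl) {
        len2 <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                       1L)
        seq2 <- .random_peptide_string(len2)
        psm <- xl_psm(
          list(parse_sequence(seq1)$peptide, parse_sequence(seq2)$peptide),
          link_positions = c(sample(len1, 1L), sample(len2, 1L)),
          crosslinker_mass = .XL_LINKER_MASS,
          precursor_charge = sample(3:4, 1L),
          decoy_flags = c(decoy, decoy),
          pass_threshold = stats::runif(1) > 0.05,
          rank = 1L, id = paste0("psm", k),
          scan = list(scan_number = k)
        )
      } else {
        psm <- xl_psm(
          list(parse_sequence(seq1)$peptide),
          precursor_charge = sample(2:3, 1L),
          decoy_flags = decoy,
          pass_threshold = stats::runif(1) > 0.05,
          rank = 1L, id = paste0("psm", k),
          scan = list(scan_number = k)
        )
      }
      psm$scores <- c(score = round(stats::runif(1, 1, 100), 3))
      frags <- generate_fragments(psm, set)
      # one planted peak per distinct theoretical m/z: fragments with
      # identical mass (anagram prefixes, I/L) share a peak
      first_of <- match(frags$mz, frags$mz)
      uniq <- which(first_of == seq_len(nrow(frags)))
      jit <- stats::rnorm(length(uniq), 0, spec$jitter_ppm)
      frag_mz <- frags$mz[uniq] * (1 + jit * 1e-6)
      frag_int <- round(stats::runif(length(uniq), 100, 1000), 2)
      lo <- min(frags$mz) * 0.9
      hi <- max(frags$mz) * 1.1
      noise_mz <- stats::runif(spec$noise_peaks, lo, hi)
      noise_int <- round(stats::runif(spec$noise_peaks, 1, 80), 2)
      mz_all <- c(frag_mz, noise_mz)
      int_all <- c(frag_int, noise_int)
      ord <- order(mz_all)
      # planted-peak slot (position in `uniq`) of each sorted peak, NA
      # for noise
      is_frag <- c(seq_along(uniq), rep(NA_integer_,
                                        spec$noise_peaks))[ord]
      prec_mz <- mz_from_neutral(
        sum(vapply(psm$peptides, peptide_neutral_mass, numeric(1))) +
          if (is_crosslinked(psm)) psm$crosslinker_mass else 0,
        psm$precursor_charge)
      spectra[[k]] <- spectrum(
        mz_all[ord], int_all[ord],
        source = list(scan = as.character(k), index = k,
                      title = paste0("synthetic_scan_", k)),
        precursor = list(mz = prec_mz, charge = psm$precursor_charge))
      hit <- which(!is.na(is_frag))
      # expand: one truth row per (planted peak, fragment sharing its m/z)
      slot_of_peak <- is_frag[hit]                 # index into `uniq`
      truth_rows[[k]] <- do.call(rbind, lapply(seq_along(hit), function(h) {
        frows <- which(first_of == uniq[slot_of_peak[h]])
        data.frame(
          psm_id = psm$id, scan = k, peak_index = hit[h],
          label = frags$label[frows],
          charge = frags$charge[frows],
          fragment_row = frows,
          theoretical_mz = frags$mz[frows],
          stringsAsFactors = FALSE
        )
      }))
      psms[[k]] <- psm
    }
    mgf_path <- file.path(dir, paste0(basename, ".mgf"))
    csv_path <- file.path(dir, paste0(basename, ".csv"))
    truth_path <- file.path(dir, paste0(basename, "_truth.csv"))
    write_mgf(spectra, mgf_path)
    write_csv_ids(psms, csv_path)
    truth <- do.call(rbind, truth_rows)
    utils::write.csv(truth, truth_path, row.names = FALSE)
    list(mgf = mgf_path, csv = csv_path, truth_file = truth_path,
         psms = psms, spectra = spectra, truth = truth)
  })
}

#' Annotate fixtures and score planted-signal recovery
#'
#' Runs [annotate()] on every fixture PSM/spectrum pair and reports the
#' fraction of ground-truth fragment peaks that were matched by (at least
#' one of) the fragment ions planted on them.
#'
#' @param fx a [make_fixtures()] result.
#' @param settings an [annotation_settings()] (tolerance matters most).
#' @return List with `recovered`, `total` and `rate` (in \[0,1\]), counted
#'   over planted peaks.
#' @export
fixture_recovery <- function(fx, settings = annotation_settings(
                               "20ppm", c("b", "y"),
                               max_fragment_charge = 2L)) {
  recovered <- 0L
  total <- 0L
  for (k in seq_along(fx$psms)) {
    ann <- annotate(fx$spectra[[k]], fx$psms[[k]], settings)
    mono <- ann$matches[ann$matches$isotope_peak == 0L, , drop = FALSE]
    key_found <- paste(mono$fragment_index, mono$peak_index)
    tr <- fx$truth[fx$truth$scan == k, , drop = FALSE]
    for (pk in unique(tr$peak_index)) {
      total <- total + 1L
      sub <- tr[tr$peak_index == pk, , drop = FALSE]
      if (any(paste(sub$fragment_row, sub$peak_index) %in% key_found)) {
        recovered <- recovered + 1L
      }
    }
  }
  list(recovered = recovered, total = total,
       rate = if (total) recovered / total else NA_real_)
}
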