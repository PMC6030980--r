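Package: fragmatch
Title: Fragment-Ion Annotation of Linear and Cross-Linked Peptide-Spectrum
    Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates tandem mass spectra against linear and cross-linked
    peptide-spectrum matches. Computes theoretical fragment ions (precursor,
    b, c, y, z) with neutral losses and multiple charge states, matches them
    to observed peaks within a ppm or Dalton tolerance, extends matches over
    isotope clusters, and derives quality-control error statistics. Reads
    peak lists in MGF (byte-indexed) and mzML, identifications in mzIdentML
    1.1/1.2 (including cross-link donor/acceptor pairing) and a documented
    CSV dialect, with transparent gzip/zip decompression. Supports
    re-annotation under modified hypotheses (sequence, modifications,
    cross-link site, charge, tolerance, ion types) with revert, a
    peak-distance measuring tool with residue matching, a single-file
    dataset store with filtered queries, deterministic SVG export of the
    annotated spectrum, peptide fragmentation key and QC error plots, a
    synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
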