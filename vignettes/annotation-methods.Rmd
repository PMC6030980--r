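---
title: "Annotating linear and cross-linked peptide-spectrum matches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating linear and cross-linked peptide-spectrum matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmatch)
```

## The problem

An MS2 spectrum is a list of (m/z, intensity) peaks produced by
fragmenting a selected precursor ion. A peptide-spectrum match (PSM)
asserts that the precursor was a particular peptide — or, in
cross-linking mass spectrometry, a pair of peptides joined by a
cross-linker reagent of fixed mass. Judging such an assertion by eye
requires knowing which peaks the peptide explains: the theoretical
fragment masses, which observed peaks fall within the instrument's mass
accuracy of them, and how the residual errors behave. `fragmatch`
computes exactly that, for linear and cross-linked PSMs, and renders the
result in the three coordinated views used in the field (annotated
spectrum, fragmentation key, QC error plots).

## Mass model

Residue masses are monoisotopic: each of the 20 canonical residues is
stored as an elemental composition, and its mass is the
composition-weighted sum of lightest-isotope atomic masses (H
1.00782503207, C 12, N 14.0030740048, O 15.9949146196, S 31.97207100).
Constants that enter every equation — proton 1.00727646688 Da, water
18.0105646863 Da, ammonia 17.0265491015 Da, and the 13C–12C spacing
1.0033548378 Da — live in `physical_constants`. Ambiguity codes (B, Z, X)
are rejected rather than averaged, because annotation needs exact masses.

The sequence grammar is the one users type: uppercase residues, a
lowercase alphanumeric token naming a modification on the preceding
residue (`Mox` = oxidised Met), and `#` marking the cross-link site
(`GK#`). The modification registry ships with a documented starter set —
ox +15.99491 (M), cm +57.02146 (C), ph +79.96633 (S/T/Y), deam +0.98402
(N/Q), ac +42.01057 (K) — because the exact registry of any given search
pipeline varies; entries can be overridden or replaced wholesale
(`register_modification()`, `read_modifications()`), and registering an
existing token overwrites its mass, mirroring an editable modification
table. Modification positions are 1-based with 0 and length+1 reserved
for the termini, matching the mzIdentML location convention.

## Fragment generation

For each peptide and each cleavage site the package emits b/y (and
c = b + NH3, z = y − NH3) neutral masses, at every charge from 1 to
min(precursor charge, `max_fragment_charge`). Two conventions differ
between instruments and software for z ions; the default here is
classical z, and `z_radical = TRUE` adds one hydrogen for z-dot. The
precursor charge is treated as the physical ceiling on fragment charge.

The cross-link rule: a fragment whose residue range covers its peptide's
link site carries the cross-linker mass plus the *entire* neutral mass of
the partner peptide. This makes cross-linked annotation formally
equivalent to linear annotation with a user-defined modification of mass
(linker + partner) at the link residue — an equivalence tested
explicitly, and useful in practice for spot-checking against
linear-only tools. The precursor ion is the full assembly
(both peptides + linker); it belongs to both peptides, and is labelled
`alpha` because the fragment type admits only one owner.

Neutral losses are generated residue-dependently: a water loss when the
fragment's range contains S, T, E or D; an ammonia loss for R, K, N or Q.
Published descriptions of annotators often leave the loss rule
unspecified; the residue-dependent rule is this package's documented
choice, as is the restriction to a single loss per variant (no combined
−H2O−NH3), which keeps label space readable. For link-spanning fragments
only the fragment's own residue range is consulted — the attached partner
peptide does not contribute loss-prone residues — except for the
precursor, which consults both sequences.

## Peak matching and errors

For every theoretical fragment, the observed peak with the smallest
absolute m/z difference inside the tolerance window is matched. The
window is `tol * mz / 1e6` for ppm tolerances and a constant for Da
tolerances (`"10ppm"`, `"0.02Da"`, case-insensitive). Closest-peak — not
most-intense — selection is deliberate: the QC plots show per-fragment
error, and picking by intensity would bias them. Two deterministic
tie-break rules: if two peaks are equidistant, the lower-m/z peak wins;
if two fragments fall within tolerance of one peak, both annotations are
kept (multi-label peaks are normal in dense spectra). Errors are stored
signed, observed − theoretical, in Da and ppm; the sign convention must
be fixed for QC plots to be comparable across spectra.

Isotope clusters are grown from each monoisotopic match at spacings of
1.0033548/z Th, relative to the *observed* matched peak, stopping at the
first gap and capped at six peaks — bounded and deterministic. Cluster
members are recorded with their isotope index and do not generate QC
points (only monoisotopic matches do).

The implementation matches via a sorted-vector neighbour search
(`findInterval`); the test suite holds it equal, match for match, to an
independently written O(peaks × fragments) exhaustive matcher on
seeded synthetic spectra, and checks the standard invariants: enlarging
the tolerance never removes a match, shifting all peaks by +x ppm shifts
all errors by +x, and error_ppm ≡ error_Da/mz·1e6 on every match.

## Re-annotation and the measuring tool

`reannotate()` recomputes under a changed hypothesis — sequence,
modification position or mass, cross-link site (move the `#`), precursor
charge, ion types, tolerance — and carries a snapshot of the *first*
annotation so `revert()` returns it bit-identically no matter how long
the chain of edits; the original object is never mutated, and a sequence
that fails to parse raises an error before anything changes.

`measure()` converts the m/z distance between two chosen peaks into
neutral mass differences for charge states 1..z and reports residues
whose monoisotopic mass lies within tolerance — the quickest way to ask
"could this unexplained gap be a glycine?". Isobaric residues (I/L) are
both reported; a zero gap reports nothing.

## File formats and the dataset store

MGF files are read through a byte-offset index built in one pass;
fetching spectrum k re-reads only its block, so large files never need to
be held in memory. mzML binary arrays (64/32-bit little-endian floats,
zlib or uncompressed) are decoded directly; an unsupported compression
scheme is a named error, and a truncated payload is a decode error rather
than silent corruption. The mzML writer exists for fixtures and
interchange and emits genuine RFC1950 zlib streams, verified against an
independent ProteoWizard-based reader in the tests. mzIdentML 1.2
cross-links are paired by the shared value of their donor/acceptor
cvParams (MS:1002509/MS:1002510), the donor's mass delta supplying the
linker mass; an orphan donor is an error listing the value. The CSV
dialect is frozen in the README — the column set any search pipeline can
emit with a text editor. gzip and zip inputs are inflated transparently
to a temporary file so indexing and seeking still work.

A dataset (spectra + PSMs + modification registry + provenance) persists
as one self-contained JSON file per dataset. A single file per dataset
keeps storage, deletion and sharing trivial; JSON was chosen as the
container because the environment's R stack has no embedded relational
database driver, and for the dataset sizes this package targets
(hundreds of PSMs) a relational store buys nothing. Every PSM's spectrum
reference must resolve at build and load time (resolution order:
explicit scan index, then scan number, then MGF TITLE — MGF files often
lack SCANS). The annotation JSON is versioned and ships with a JSON
schema; validation uses a small in-package interpreter of the schema
subset actually used (type/required/properties/items/enum), because no
JSON-Schema validator package is available in the dependency set.

## SVG export

The three views are rendered as static SVG 1.1 by pure functions of
(annotation, style): the same input is byte-identical output, which the
tests assert. Matched peaks are coloured by peptide (default alpha red
`#d40000`, beta blue `#0044cc`), neutral-loss elements are lightened by
mixing toward white, unmatched peaks are gray, and loss labels can be
suppressed. Interactive affordances (zoom, drag-to-move labels, linked
highlighting) are out of scope; in their place crowded labels get a
deterministic greedy de-overlap — left to right, a label that would sit
within 30 px of its neighbour is raised and tethered to its peak with a
dashed leader line.

## The synthetic data generator

`make_fixtures()` emulates the data this tool is built for: random
peptides of 6–15 residues (uniform over the 20 canonical residues), half
of the PSMs cross-linked with a 138.06808 Da linker (the BS3/DSS bridge
ubiquitous in cross-linking work), precursor charges 2–3 (linear) or 3–4
(cross-linked), spectra containing every b/y and cross-link-shifted
fragment peak at charges 1–2 with Gaussian mass error (default sigma
5 ppm, a realistic Orbitrap-class accuracy), 30 uniform noise peaks per
spectrum, and a 10% decoy fraction. Fragments that share an exact
theoretical m/z (anagram prefixes, I/L) are planted as a single peak and
the ground truth lists all of them, so recovery accounting is exact. One
seed fixes everything; identical seeds give byte-identical MGF/CSV/truth
files.

What it does *not* emulate — isotope envelopes, correlated intensity
structure, co-eluting precursors, systematic (as opposed to Gaussian)
calibration error — bounds what passing tests show: they demonstrate the
matching, mass arithmetic and I/O contracts, not real-data
identification performance.

## Numerical choices and limitations

Tolerances are strictly positive; matching windows are half-open at
nothing (|Δ| ≤ tol). MGF printing uses 6 decimals for m/z and 4 for
intensity, so write/read round trips are identity at printed precision
and byte-stable from the second generation onward. Problem sizes in the
shipped checks — 500 peptides for the mass oracle, 200 for
complementarity, 100 spectra for matcher equivalence, 50 cross-linked
PSMs for the reduction property, 200 PSMs for jittered recovery — were
chosen to exercise the combinatorics thoroughly while keeping the whole
suite fast enough to run habitually.

Known limitations: a/x ions, internal fragments, immonium ions and
cleavable cross-linker stub fragments are not generated; spectra are not
deisotoped or charge-deconvoluted before matching (isotope clusters are
annotated, not collapsed); average (non-monoisotopic) masses are not
supported; PSM scoring/FDR is out of scope — decoy and threshold flags
are carried and filterable but never computed.
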