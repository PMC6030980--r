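# fragmatch

Fragment-ion annotation of tandem mass spectra against linear and
**cross-linked** peptide-spectrum matches (PSMs), in R.

Interpreting a peptide identification means being able to see, peak by
peak, which parts of an MS2 spectrum the assigned peptide explains. For
cross-linking mass spectrometry this is harder than for standard
proteomics: a cross-linked PSM assigns *two* peptides, joined by a
cross-linker of fixed mass, and every fragment that spans a link site
carries the linker plus the entire partner peptide. `fragmatch`
implements that computational core as a library plus command-line tool:

* a **mass model**: monoisotopic residue masses from elemental
  compositions, a peptide sequence grammar with lowercase modification
  tokens and the `#` cross-link symbol, and an editable modification
  registry;
* **fragment generation**: precursor, b, c, y and z ions at multiple
  charge states, H2O/NH3 neutral-loss variants, and the cross-link mass
  shift rule;
* **annotation**: closest-peak matching within a ppm or Da tolerance,
  isotope-cluster extension, signed error statistics for QC plots, a
  peak-distance measuring tool with amino-acid matching, and
  re-annotation under modified hypotheses with revert;
* **standard-format I/O**: byte-indexed MGF, mzML (zlib/plain, 32/64-bit),
  mzIdentML 1.1/1.2 with cross-link donor/acceptor pairing, a documented
  CSV dialect, gzip/zip archives, a versioned annotation JSON with shipped
  schema, and a single-file dataset store with filtered PSM queries;
* **SVG export** of the three coordinated views: annotated spectrum,
  peptide fragmentation key, and QC error plots;
* a **synthetic fixture generator** so everything is testable without
  downloading data.

## The arithmetic at the core

With monoisotopic residue masses $m(r)$, water $W$, ammonia $A$ and the
proton mass $p$, a peptide of residues $r_1 \dots r_n$ with modification
mass shifts $\delta_i$ has neutral mass

$$M = \sum_i m(r_i) + \sum_i \delta_i + W.$$

Backbone cleavage between $i$ and $i{+}1$ gives the prefix/suffix ions

$$b_i = \sum_{k \le i} m(r_k) + \delta_{k \le i}, \qquad
  y_j = \sum_{k > n-j} m(r_k) + \delta_{k > n-j} + W,$$

with $c_i = b_i + A$ and $z_j = y_j - A$ (an optional z-dot convention
adds one hydrogen). An ion of charge $z$ appears at
$m/z = (M_{\text{frag}} + z\,p)/z$. For a cross-linked PSM with linker
mass $L$, any fragment of peptide $\alpha$ whose residue range contains
the link site additionally carries $L + M_\beta$ (and symmetrically), so
cross-linked annotation reduces exactly to linear annotation with a
user-defined modification of mass $L + M_\beta$ at the link residue — a
property the test suite exploits. Match errors are recorded signed as
observed − theoretical, in both Da and ppm
($\mathrm{ppm} = \Delta/m_{\text{theo}} \times 10^6$); isotope clusters
are found at spacings of $1.0033548/z$ Th above a matched peak, stopping
at the first gap.

## Worked example

A small cross-linked PSM — peptide `GK` linked at K2 to peptide `LAKR`
linked at K3, with a BS3/DSS-style linker (138.06808 Da), precursor
charge 3 — annotated against a seven-peak spectrum:

```r
library(fragmatch)

psm <- psm_from_sequences("GK#", "LAK#R",
                          crosslinker_mass = 138.06808,
                          precursor_charge = 3)
st <- annotation_settings("10ppm", ion_types = c("precursor", "b", "y"),
                          max_fragment_charge = 2)

spec <- spectrum(
  mz = c(58.02891, 114.09151, 175.11930, 400.20000, 513.28406,
         715.44324, 771.50716),
  intensity = c(55, 120, 80, 560, 30, 410, 22))

ann <- annotate(spec, psm, st)
ann
#> <annotated_spectrum> 7 peaks, 18 theoretical fragments, 5 matched
#>   (+0 isotope peaks), tol 10ppm

qc_points(ann, "mz")
#>          x error_ppm peptide_id loss label peak_index
#> 1  58.0289       3.0      alpha none    b1          1
#> 2 771.5072      -2.0      alpha none    y1          6
#> 3 114.0915       1.5       beta none    b1          2
#> 4 715.4432      -4.0       beta none    y3          5
#> 5 175.1193       2.0       beta none    y1          3
```

The `y1` ion of the alpha peptide (K alone) sits at 771.51 Th, not
146 + proton: it spans the link site, so it carries the linker plus the
whole beta peptide. The QC table shows each match's signed ppm error,
ready for the error-vs-m/z and error-vs-intensity views. The two
unannotated peaks are 113.08 Th apart — the measuring tool explains the
gap as a leucine/isoleucine residue at charge 1:

```r
measure(spec, 4, 5, max_charge = 2, tolerance = "0.01Da")
#>   charge mass_delta residues
#> 1      1   113.0841      L,I
#> 2      2   226.1681
```

Export the three views and the machine-readable annotation:

```r
writeLines(spectrum_svg(ann), "spectrum.svg")
writeLines(fragkey_svg(ann), "key.svg")
writeLines(qc_svg(qc_points(ann, "mz"), "mz"), "qc.svg")
write_annotation_json(ann, "annotation.json")  # validates against
# system.file("extdata", "annotation-schema.json", package = "fragmatch")
```

Re-annotation under a modified hypothesis, and revert:

```r
ann2 <- reannotate(ann, sequences = c("G#K", "LAK#R"))  # move the link
original <- revert(ann2)                                # bit-identical
```

The same pipeline from the shell:

```sh
Rscript inst/scripts/fragmatch fixtures --out fx --n-psms 20 --seed 1
Rscript inst/scripts/fragmatch annotate --peaks fx/synthetic.mgf \
    --ids fx/synthetic.csv --tolerance 20ppm --ions b,y --out ann.json
Rscript inst/scripts/fragmatch render --annotation ann.json \
    --view spectrum --out spectrum.svg
```

## The CSV identification dialect

Header row required; recognised columns (others are kept as extra scores
or metadata):

| column | meaning |
|---|---|
| `id` | PSM identifier (optional; defaults to the row number) |
| `scanNumber` / `scanIndex` | spectrum reference (one required); index wins over number, which wins over MGF TITLE matching |
| `peakListFileName` | peak-list file the scan lives in (optional) |
| `pepSeq1`, `pepSeq2` | sequences in the grammar above (`Mox`, `GK#`...); empty `pepSeq2` = linear PSM |
| `linkPos1`, `linkPos2` | 1-based link sites; override `#` symbols |
| `crosslinkerModMass` | linker mass in Da (required for cross-links) |
| `charge` | precursor charge (required) |
| `score` | primary score (any numeric extra column becomes a named score) |
| `protein1`, `protein2` | protein accessions |
| `decoy1`, `decoy2` | per-peptide decoy flags (`true`/`false`, default false) |
| `passThreshold` | search-engine threshold flag (default true) |
| `fragmentTolerance`, `ionTypes`, `rank` | optional annotation hints |

Modification tokens in `pepSeq*` must be registered
(see `default_modifications()`, `register_modification()`,
`read_modifications()`).

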