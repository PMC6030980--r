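test_that("annotation of an empty spectrum yields zero matches and an exact
           peak matches with zero error", {
  psm <- psm_from_sequences("PEPTIDE")
  st <- annotation_settings("10ppm", c("b", "y"), 1)
  empty <- annotate(spectrum(), psm, st)
  expect_identical(nrow(empty$matches), 0L)

  fr <- generate_fragments(psm, st)
  b2 <- fr$mz[fr$label == "b2"]
  one <- annotate(spectrum(b2, 100), psm, st)
  mono <- one$matches[one$matches$isotope_peak == 0, ]
  expect_identical(nrow(mono), 1L)
  expect_identical(mono$error_ppm, 0)
  expect_identical(mono$error_Da, 0)
})

test_that("annotate() reproduces the brute-force all-pairs matcher on
           synthetic spectra", {
  set.seed(31)
  st <- annotation_settings("20ppm", c("b", "y"), 2)
  for (i in 1:30) {
    psm <- psm_from_sequences(random_peptide(sample(6:15, 1)),
                              precursor_charge = 2)
    fr <- generate_fragments(psm, st)
    # plant jittered fragment peaks and noise
    keep <- runif(nrow(fr)) < 0.7
    planted <- fr$mz[keep] * (1 + rnorm(sum(keep), 0, 8) * 1e-6)
    noise <- runif(30, min(fr$mz) * 0.9, max(fr$mz) * 1.1)
    mz <- sort(c(planted, noise))
    spec <- spectrum(mz, rep(1, length(mz)))
    ann <- annotate(spec, psm, st)
    mono <- ann$matches[ann$matches$isotope_peak == 0, ]
    got <- rep(NA_integer_, nrow(fr))
    got[mono$fragment_index] <- mono$peak_index
    expected <- oracle_match(spec$peaks$mz, fr$mz, 20, "ppm")
    expect_identical(got, expected)
  }
})

test_that("matching works in Da tolerance units too", {
  set.seed(32)
  psm <- psm_from_sequences("PEPTIDEK", precursor_charge = 2)
  st <- annotation_settings("0.02Da", c("b", "y"), 1)
  fr <- generate_fragments(psm, st)
  mz <- sort(c(fr$mz + runif(nrow(fr), -0.03, 0.03), runif(20, 100, 900)))
  ann <- annotate(spectrum(mz, rep(1, length(mz))), psm, st)
  mono <- ann$matches[ann$matches$isotope_peak == 0, ]
  got <- rep(NA_integer_, nrow(fr))
  got[mono$fragment_index] <- mono$peak_index
  expect_identical(got, oracle_match(mz, fr$mz, 0.02, "da"))
  expect_true(all(abs(mono$error_Da) <= 0.02))
})

test_that("isotope clusters extend at 1.0033548/z spacing and stop at the
           first gap", {
  psm <- psm_from_sequences("PEPTIDEK", precursor_charge = 2)
  st <- annotation_settings("10ppm", c("b", "y"), 2)
  fr <- generate_fragments(psm, st)
  target <- fr[fr$charge == 2, ][1, ]
  spacing <- 1.0033548378 / 2
  # k = 0,1 present; gap at k = 2; k = 3 present but unreachable
  mz <- c(target$mz, target$mz + spacing, target$mz + 3 * spacing)
  ann <- annotate(spectrum(sort(mz), c(10, 5, 2)), psm, st)
  cl <- ann$matches[ann$matches$fragment_index == as.integer(
    rownames(target)), ]
  expect_setequal(cl$isotope_peak, c(0L, 1L))

  # contiguous cluster of three
  mz2 <- c(target$mz, target$mz + spacing, target$mz + 2 * spacing)
  ann2 <- annotate(spectrum(sort(mz2), c(10, 5, 2)), psm, st)
  cl2 <- ann2$matches[ann2$matches$fragment_index == as.integer(
    rownames(target)), ]
  expect_setequal(cl2$isotope_peak, c(0L, 1L, 2L))
})

test_that("QC points report signed ppm errors per monoisotopic match, with
           an absolute-value option", {
  psm <- psm_from_sequences("PEPTIDE")
  st <- annotation_settings("15ppm", c("b", "y"), 1)
  fr <- generate_fragments(psm, st)
  b2 <- fr$mz[fr$label == "b2"]
  shifted <- b2 * (1 + 10e-6) # +10 ppm
  ann <- annotate(spectrum(shifted, 50), psm, st)
  pts <- qc_points(ann, "mz")
  expect_identical(nrow(pts), 1L)
  expect_lt(abs(pts$error_ppm - 10), 1e-6)
  expect_identical(pts$x, shifted)
  pts_int <- qc_points(ann, "intensity")
  expect_identical(pts_int$x, 50)
  # absolute folds the sign
  ann2 <- annotate(spectrum(b2 * (1 - 10e-6), 50), psm, st)
  expect_lt(qc_points(ann2, "mz")$error_ppm, 0)
  expect_gt(qc_points(ann2, "mz", absolute = TRUE)$error_ppm, 0)
  # no matches -> empty
  expect_identical(nrow(qc_points(annotate(spectrum(), psm, st))), 0L)
})

test_that("every match satisfies the ppm/Da consistency identity", {
  set.seed(33)
  st <- annotation_settings("20ppm", c("b", "y"), 2)
  psm <- psm_from_sequences(random_peptide(12), precursor_charge = 2)
  fr <- generate_fragments(psm, st)
  mz <- sort(fr$mz * (1 + rnorm(nrow(fr), 0, 6) * 1e-6))
  ann <- annotate(spectrum(mz, rep(1, length(mz))), psm, st)
  m <- ann$matches[ann$matches$isotope_peak == 0, ]
  theo <- ann$fragments$mz[m$fragment_index]
  expect_true(all(abs(m$error_ppm - m$error_Da / theo * 1e6) <=
                    1e-9 * pmax(abs(m$error_ppm), 1)))
})

test_that("enlarging the tolerance never removes a match and a uniform ppm
           shift moves every error by that amount", {
  set.seed(34)
  psm <- psm_from_sequences(random_peptide(12), precursor_charge = 2)
  base <- annotation_settings("10ppm", c("b", "y"), 2)
  wide <- annotation_settings("25ppm", c("b", "y"), 2)
  fr <- generate_fragments(psm, base)
  mz <- sort(c(fr$mz * (1 + rnorm(nrow(fr), 0, 7) * 1e-6),
               runif(25, 200, 1200)))
  spec <- spectrum(mz, rep(1, length(mz)))
  m1 <- annotate(spec, psm, base)$matches
  m2 <- annotate(spec, psm, wide)$matches
  k1 <- paste(m1$fragment_index, m1$peak_index, m1$isotope_peak)
  k2 <- paste(m2$fragment_index, m2$peak_index, m2$isotope_peak)
  expect_true(all(k1[m1$isotope_peak == 0] %in% k2))

  shift <- 4 # ppm
  spec_shift <- spectrum(spec$peaks$mz * (1 + shift * 1e-6),
                         spec$peaks$intensity)
  a0 <- annotate(spec, psm, wide)$matches
  a1 <- annotate(spec_shift, psm, wide)$matches
  m0 <- a0[a0$isotope_peak == 0, ]
  m1s <- a1[a1$isotope_peak == 0, ]
  common <- intersect(m0$fragment_index, m1s$fragment_index)
  d <- m1s$error_ppm[match(common, m1s$fragment_index)] -
    m0$error_ppm[match(common, m0$fragment_index)]
  expect_true(all(abs(d - shift) < shift * 1e-4 + 1e-6))
})

test_that("measure converts peak distances to residue matches across
           charges", {
  s <- spectrum(c(200.0, 228.51073, 257.02146), c(1, 1, 1))
  r1 <- measure(s, 1, 3, max_charge = 1, tolerance = "0.005Da")
  expect_lt(abs(r1$mass_delta - 57.02146), 1e-5)
  expect_identical(r1$residues, "G")
  r2 <- measure(s, 1, 2, max_charge = 2, tolerance = "0.005Da")
  expect_identical(r2$residues[2], "G")
  # zero distance: no residue match at any charge
  r0 <- measure(s, 2, 2, max_charge = 3, tolerance = "0.005Da")
  expect_true(all(r0$mass_delta == 0))
  expect_true(all(r0$residues == ""))
  # I and L are isobaric: both reported
  s2 <- spectrum(c(300, 300 + 113.08406), c(1, 1))
  expect_identical(measure(s2, 1, 2, 1, "0.005Da")$residues, "L,I")
  expect_error(measure(s, 0, 2, 1), "out of range")
})

test_that("reannotate recomputes under modified hypotheses and revert
           restores the first annotation exactly", {
  set.seed(35)
  seqstr <- "KMAPMSTR"
  psm <- psm_from_sequences(paste0("KM", "ox", "APMSTR"),
                            precursor_charge = 2)
  st <- annotation_settings("20ppm", c("b", "y"), 1)
  fr <- generate_fragments(psm, st)
  mz <- sort(c(fr$mz, runif(20, 150, 1000)))
  spec <- spectrum(mz, rep(1, length(mz)))
  ann <- annotate(spec, psm, st)

  # identical inputs -> identical result
  re_same <- reannotate(ann)
  expect_equal(re_same$matches, ann$matches)
  expect_equal(as.data.frame(re_same$fragments), as.data.frame(ann$fragments))

  # move ox from M2 to M5: only fragments whose range separates 2 and 5
  # change mass
  re_moved <- reannotate(ann, sequences = "KMAPMoxSTR")
  f0 <- ann$fragments
  f1 <- re_moved$fragments
  expect_identical(nrow(f0), nrow(f1))
  changed <- abs(f0$mz - f1$mz) > 1e-9
  separates <- (f0$series == "b" & f0$index >= 2 & f0$index < 5) |
    (f0$series == "y" & f0$index >= nchar(seqstr) - 5 + 1 &
       f0$index < nchar(seqstr) - 2 + 1)
  expect_identical(changed, separates)

  # a failed parse leaves the annotation untouched
  expect_error(reannotate(ann, sequences = "KM!X"), "unexpected character")

  # revert after a chain of re-annotations restores the original exactly
  re2 <- reannotate(re_moved, settings = annotation_settings("5ppm", "b", 1))
  back <- revert(re2)
  expect_identical(back$matches, ann$matches)
  expect_identical(back$settings, ann$settings)
  expect_identical(as.data.frame(back$fragments),
                   as.data.frame(ann$fragments))
  # the original object itself is unchanged
  expect_null(ann$original)
})
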