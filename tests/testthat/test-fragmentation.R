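test_that("b/y fragment masses match the composition oracle on PEPTIDE", {
  psm <- psm_from_sequences("PEPTIDE")
  fr <- generate_fragments(psm, annotation_settings("10ppm", c("b", "y"), 1))
  b2 <- fr$mz[fr$label == "b2"]
  y1 <- fr$mz[fr$label == "y1"]
  expect_lt(abs(b2 - 227.1026334), 1e-5)
  expect_lt(abs(y1 - 148.0604342), 1e-5)
  expect_lt(abs(b2 - oracle_mz(oracle_b("PEPTIDE", 2), 1)), 1e-6)
  expect_lt(abs(y1 - oracle_mz(oracle_y("PEPTIDE", 1), 1)), 1e-6)
})

test_that("a single-residue peptide has no b/c/y/z fragments and an empty
           ion-type set yields an empty table", {
  psm <- psm_from_sequences("K")
  fr <- generate_fragments(psm, annotation_settings("10ppm",
                                                    c("b", "c", "y", "z")))
  expect_identical(nrow(fr), 0L)
  fr2 <- generate_fragments(psm_from_sequences("PEPTIDE"),
                            annotation_settings("10ppm", character(0)))
  expect_identical(nrow(fr2), 0L)
})

test_that("b/y and c/z complementarity holds at every cleavage site of
           random peptides", {
  set.seed(7)
  st <- annotation_settings("10ppm", c("b", "c", "y", "z"), 1)
  for (i in 1:40) {
    seq <- random_peptide(sample(5:25, 1))
    psm <- psm_from_sequences(seq)
    total <- peptide_neutral_mass(psm$peptides[[1]])
    fr <- generate_fragments(psm, st)
    n <- nchar(seq)
    for (k in 1:(n - 1)) {
      b <- fr$neutral_mass[fr$series == "b" & fr$index == k]
      y <- fr$neutral_mass[fr$series == "y" & fr$index == n - k]
      cc <- fr$neutral_mass[fr$series == "c" & fr$index == k]
      zz <- fr$neutral_mass[fr$series == "z" & fr$index == n - k]
      expect_lt(abs(b + y - total), 1e-6)
      expect_lt(abs(cc + zz - total), 1e-6)
    }
  }
})

test_that("within a series at fixed charge m/z increases strictly with
           index", {
  set.seed(8)
  st <- annotation_settings("10ppm", c("b", "c", "y", "z"), 3)
  for (i in 1:10) {
    psm <- psm_from_sequences(random_peptide(sample(6:20, 1)),
                              precursor_charge = 3)
    fr <- generate_fragments(psm, st)
    for (s in c("b", "c", "y", "z")) {
      for (z in 1:3) {
        sub <- fr[fr$series == s & fr$charge == z, ]
        sub <- sub[order(sub$index), ]
        expect_true(all(diff(sub$mz) > 0))
      }
    }
  }
})

test_that("link-spanning fragments carry linker plus whole partner peptide
           (worked cross-link example)", {
  psm <- psm_from_sequences("GK#", "GK#", crosslinker_mass = 138.06808,
                            precursor_charge = 3)
  fr <- generate_fragments(psm, annotation_settings("10ppm", c("b", "y"), 1))
  y1a <- fr[fr$label == "y1" & fr$peptide_id == "alpha", ]
  expect_true(y1a$contains_link)
  expect_lt(abs(y1a$mz - 488.3078756), 1e-4)
  # b1 = G does not span the link at K2
  b1a <- fr[fr$label == "b1" & fr$peptide_id == "alpha", ]
  expect_false(b1a$contains_link)
  expect_lt(abs(b1a$mz - oracle_mz(ORACLE_RESIDUE_MASS[["G"]], 1)), 1e-6)
})

test_that("cross-linked fragments reduce to the linear peptide carrying a
           linker+partner modification at the link site", {
  set.seed(21)
  st <- annotation_settings("10ppm", c("precursor", "b", "c", "y", "z"), 2)
  for (i in 1:15) {
    la <- sample(4:12, 1)
    lb <- sample(4:12, 1)
    seqa <- random_peptide(la)
    seqb <- random_peptide(lb)
    pa <- sample(la, 1)
    pb <- sample(lb, 1)
    linker <- 138.06808
    xpsm <- xl_psm(list(peptide(seqa), peptide(seqb)),
                   link_positions = c(pa, pb), crosslinker_mass = linker,
                   precursor_charge = 3)
    xfr <- generate_fragments(xpsm, st)
    alpha_mz <- sort(xfr$mz[xfr$peptide_id == "alpha" |
                              xfr$series == "precursor"])
    partner_mass <- linker + peptide_neutral_mass(peptide(seqb))
    lpep <- peptide(seqa, data.frame(position = pa, name = "xlmod",
                                     mass_delta = partner_mass))
    lpsm <- xl_psm(list(lpep), precursor_charge = 3)
    lfr <- generate_fragments(lpsm, st)
    lin_mz <- sort(lfr$mz)
    expect_identical(length(alpha_mz), length(lin_mz))
    expect_true(all(abs(alpha_mz - lin_mz) / lin_mz < 1e-9))
  }
})

test_that("neutral losses are residue-dependent, single-loss, and a no-op
           when disabled", {
  psm <- psm_from_sequences("PEGG")
  st <- annotation_settings("10ppm", c("b", "y"), 1)
  fr <- generate_fragments(psm, st)
  aug <- apply_neutral_losses(fr, enabled = TRUE)
  # b2 = PE contains E -> water loss at -H2O exactly
  b2 <- aug[aug$series == "b" & aug$index == 2 & aug$loss == "none", ]
  b2w <- aug[aug$series == "b" & aug$index == 2 & aug$loss == "H2O", ]
  expect_identical(nrow(b2w), 1L)
  expect_lt(abs((b2$neutral_mass - b2w$neutral_mass) - 18.0105646837), 1e-6)
  # y2 = GG: no loss-prone residue, no variants
  expect_identical(nrow(aug[aug$series == "y" & aug$index == 2 &
                              aug$loss != "none", ]), 0L)
  # no combined double losses, base fragments retained
  expect_true(all(aug$loss %in% c("none", "H2O", "NH3")))
  expect_identical(nrow(aug[aug$loss == "none", ]), nrow(fr))
  # disabled = identity
  expect_identical(as.data.frame(apply_neutral_losses(fr, FALSE)),
                   as.data.frame(fr))
  # NH3 loss requires R/K/N/Q
  frk <- generate_fragments(psm_from_sequences("PKGG"), st)
  augk <- apply_neutral_losses(frk, TRUE)
  b2k <- augk[augk$series == "b" & augk$index == 2 & augk$loss == "NH3", ]
  expect_identical(nrow(b2k), 1L)
  expect_lt(abs((frk$neutral_mass[frk$label == "b2"] - b2k$neutral_mass) -
                  17.0265491010), 1e-6)
})

test_that("the z-radical convention shifts z ions by one hydrogen", {
  psm <- psm_from_sequences("PEPTIDE")
  z_cl <- generate_fragments(psm, annotation_settings("10ppm", "z", 1,
                                                      z_radical = FALSE))
  z_rad <- generate_fragments(psm, annotation_settings("10ppm", "z", 1,
                                                       z_radical = TRUE))
  expect_true(all(abs((z_rad$neutral_mass - z_cl$neutral_mass) -
                        ORACLE_H) < 1e-5))
})

test_that("precursor ion mass covers both peptides plus the linker", {
  psm <- psm_from_sequences("GK#", "GK#", crosslinker_mass = 138.06808,
                            precursor_charge = 3)
  fr <- generate_fragments(psm, annotation_settings("10ppm", "precursor", 3))
  expect_identical(nrow(fr), 3L) # charges 1..3
  expected <- 2 * oracle_peptide_mass("GK") + 138.06808
  expect_true(all(abs(fr$neutral_mass - expected) < 1e-4))
})
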