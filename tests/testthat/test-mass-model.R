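test_that("residue table covers the 20 canonical residues with masses that
           agree with the independent oracle", {
  masses <- residue_masses()
  expect_setequal(names(masses), names(ORACLE_RESIDUE_MASS))
  expect_true(all(abs(masses[names(ORACLE_RESIDUE_MASS)] -
                        ORACLE_RESIDUE_MASS) < 1e-6))
  # composition-weighted sums reproduce the stored masses
  comps <- residue_compositions()
  atomic <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
              O = 15.9949146196, S = 31.97207100)
  for (r in names(comps)) {
    expect_lt(abs(sum(atomic[names(comps[[r]])] * comps[[r]]) - masses[[r]]),
              1e-6)
  }
})

test_that("sequence grammar parses residues, modification tokens and the
           cross-link symbol", {
  p <- parse_sequence("PEPTIDE")
  expect_identical(paste(p$peptide$sequence, collapse = ""), "PEPTIDE")
  expect_identical(nrow(p$peptide$mods), 0L)
  expect_true(is.na(p$link_position))

  m <- parse_sequence("Mox")
  expect_identical(m$peptide$sequence, "M")
  expect_identical(m$peptide$mods$position, 1L)
  expect_identical(m$peptide$mods$name, "ox")

  g <- parse_sequence("GK#")
  expect_identical(g$link_position, 2L)

  expect_error(parse_sequence("G#K#"), "multiple cross-link")
  expect_error(parse_sequence("PEBTIDE"), "position 3")
  expect_error(parse_sequence("Mfoo"), "unknown modification token")
  expect_error(parse_sequence(""), "non-empty")
  expect_error(parse_sequence("oxM"), "precedes any residue")
})

test_that("parse/render round-trips canonical strings", {
  set.seed(11)
  reg <- default_modifications()
  for (i in 1:50) {
    seq <- random_peptide(sample(5:20, 1))
    chars <- strsplit(seq, "")[[1]]
    # sprinkle applicable modification tokens
    for (tok in c("ox", "ph", "deam")) {
      spots <- switch(tok, ox = which(chars == "M"),
                      ph = which(chars %in% c("S", "T", "Y")),
                      deam = which(chars %in% c("N", "Q")))
      if (length(spots)) {
        at <- spots[1]
        chars[at] <- paste0(chars[at], tok)
      }
    }
    link <- sample(seq_along(chars), 1)
    chars[link] <- paste0(chars[link], "#")
    text <- paste(chars, collapse = "")
    parsed <- parse_sequence(text, reg)
    expect_identical(render_sequence(parsed$peptide, parsed$link_position),
                     text)
  }
})

test_that("peptide neutral mass equals the composition oracle on the worked
           examples and on random modified peptides", {
  expect_lt(abs(peptide_neutral_mass(peptide("G")) - 75.0320284), 1e-5)
  expect_lt(abs(peptide_neutral_mass(peptide("PEPTIDE")) - 799.3599640),
            1e-5)
  mox <- parse_sequence("Mox")$peptide
  expect_lt(abs(peptide_neutral_mass(mox) - 165.0459596), 1e-5)

  set.seed(42)
  reg <- default_modifications()
  for (i in 1:100) {
    seq <- random_peptide(sample(5:30, 1))
    nmod <- sample(0:3, 1)
    deltas <- numeric(0)
    pep <- peptide(seq)
    if (nmod > 0) {
      pos <- sample(nchar(seq), nmod)
      rows <- reg[sample(nrow(reg), nmod, replace = TRUE), ]
      pep <- peptide(seq, data.frame(position = pos, name = rows$name,
                                     mass_delta = rows$mass_delta))
      deltas <- rows$mass_delta
    }
    expect_lt(abs(peptide_neutral_mass(pep) -
                    oracle_peptide_mass(seq, deltas)), 1e-4)
  }
})

test_that("m/z arithmetic: proton identity, worked examples, and inverse
           round trip over charges 1-8", {
  expect_equal(mz_from_neutral(0, 1), 1.00727646688, tolerance = 1e-12)
  expect_lt(abs(mz_from_neutral(799.35997, 1) - 800.36725), 1e-5)
  expect_lt(abs(mz_from_neutral(799.35997, 2) - 400.68726), 1e-5)
  expect_error(mz_from_neutral(100, 0), "positive integer")
  set.seed(5)
  for (z in 1:8) {
    m <- runif(20, 100, 5000)
    expect_true(all(abs(neutral_from_mz(mz_from_neutral(m, z), z) - m) <
                      1e-9))
  }
})

test_that("modification registry: registration, overwrite, zero-mass
           identity and file round trip", {
  reg <- modification_registry()
  expect_error(parse_sequence("Mox", reg), "unknown modification")
  reg <- register_modification(reg, "ox", 15.99491, "M")
  expect_identical(parse_sequence("Mox", reg)$peptide$mods$mass_delta,
                   15.99491)
  # overwrite changes the mass
  reg <- register_modification(reg, "ox", 1.5)
  expect_identical(lookup_modification(reg, "ox")$mass_delta, 1.5)
  expect_error(register_modification(reg, "Ox", 1), "invalid modification")
  expect_error(register_modification(reg, "ox", Inf), "finite")

  # a zero-mass modification annotates identically to no modification
  reg0 <- register_modification(default_modifications(), "nil", 0, "*")
  psm_plain <- psm_from_sequences("PEPTIDEK", registry = reg0)
  psm_nil <- psm_from_sequences("PEPTnilIDEK", registry = reg0)
  st <- annotation_settings("10ppm", c("b", "y"), 1)
  spec <- spectrum(c(227.10263, 400.5, 616.2), c(5, 10, 2))
  expect_equal(annotate(spec, psm_nil, st)$matches,
               annotate(spec, psm_plain, st)$matches)

  tf <- tempfile(fileext = ".tsv")
  write_modifications(default_modifications(), tf)
  back <- read_modifications(tf)
  expect_equal(back$name, default_modifications()$name)
  expect_equal(back$mass_delta, default_modifications()$mass_delta)
})
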