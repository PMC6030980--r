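count_nodes <- function(svg, xpath) {
  doc <- xml2::read_xml(svg)
  xml2::xml_ns_strip(doc)
  length(xml2::xml_find_all(doc, xpath))
}

test_that("spectrum view draws one peak line per peak with the matched
           class on matched peaks, and renders axes for empty spectra", {
  psm <- psm_from_sequences("PEPTIDE")
  st <- annotation_settings("10ppm", c("b", "y"), 1)
  fr <- generate_fragments(psm, st)
  # 5 peaks, 2 of them exact fragment masses
  mz <- sort(c(fr$mz[fr$label == "b2"], fr$mz[fr$label == "y1"],
               333.3, 444.4, 555.5))
  ann <- annotate(spectrum(mz, c(5, 10, 20, 30, 40)), psm, st)
  svg <- spectrum_svg(ann)
  expect_identical(count_nodes(svg, "//line[contains(@class,'peak')]"), 5L)
  expect_identical(count_nodes(svg, "//line[contains(@class,'matched')]"),
                   2L)
  empty <- spectrum_svg(annotate(spectrum(), psm, st))
  expect_identical(count_nodes(empty,
                               "//line[contains(@class,'peak')]"), 0L)
  expect_gt(count_nodes(empty, "//line[contains(@class,'axis')]"), 0L)
})

test_that("rendering is deterministic: the same input yields byte-identical
           SVG for all three views", {
  fx <- make_fixtures(fixture_spec(n_psms = 2, seed = 44))
  st <- annotation_settings("20ppm", c("b", "y"), 2,
                            losses_enabled = TRUE)
  ann <- annotate(fx$spectra[[1]], fx$psms[[1]], st)
  expect_identical(spectrum_svg(ann), spectrum_svg(ann))
  expect_identical(fragkey_svg(ann), fragkey_svg(ann))
  pts <- qc_points(ann, "intensity")
  expect_identical(qc_svg(pts, "intensity"), qc_svg(pts, "intensity"))
})

test_that("all three views are well-formed XML with the SVG 1.1 namespace", {
  fx <- make_fixtures(fixture_spec(n_psms = 2, seed = 45))
  st <- annotation_settings("20ppm", c("b", "y"), 2)
  ann <- annotate(fx$spectra[[2]], fx$psms[[2]], st)
  for (svg in list(spectrum_svg(ann), fragkey_svg(ann),
                   qc_svg(qc_points(ann, "mz"), "mz"))) {
    doc <- xml2::read_xml(svg) # errors on malformed XML
    expect_identical(xml2::xml_name(doc), "svg")
    expect_identical(xml2::xml_attr(doc, "version"), "1.1")
  }
})

test_that("fragmentation key shows len-1 prefix ticks when every b ion is
           matched and a connector for cross-linked PSMs", {
  psm <- psm_from_sequences("PEPTIDE")
  st <- annotation_settings("10ppm", "b", 1)
  fr <- generate_fragments(psm, st)
  ann <- annotate(spectrum(sort(fr$mz), rep(1, nrow(fr))), psm, st)
  svg <- fragkey_svg(ann)
  expect_identical(
    count_nodes(svg, "//path[contains(@class,'prefix')]"), 6L)
  expect_identical(
    count_nodes(svg, "//path[contains(@class,'suffix')]"), 0L)
  expect_identical(count_nodes(svg, "//text[contains(@class,'residue')]"),
                   7L)
  # no matches: sequence row only
  bare <- fragkey_svg(annotate(spectrum(), psm, st))
  expect_identical(count_nodes(bare, "//path[contains(@class,'cleavage')]"),
                   0L)
  # cross-linked: two residue rows plus one connector
  xpsm <- psm_from_sequences("GK#", "GKGK#", crosslinker_mass = 138.06808,
                             precursor_charge = 3)
  xsvg <- fragkey_svg(annotate(spectrum(), xpsm, st))
  expect_identical(
    count_nodes(xsvg, "//line[contains(@class,'crosslink')]"), 1L)
  expect_identical(count_nodes(xsvg, "//text[contains(@class,'alpha')]"),
                   2L)
  expect_identical(count_nodes(xsvg, "//text[contains(@class,'beta')]"),
                   4L)
})

test_that("QC view draws one circle per point, none below zero in absolute
           mode, and axes only when empty", {
  fx <- make_fixtures(fixture_spec(n_psms = 2, seed = 46))
  st <- annotation_settings("20ppm", c("b", "y"), 2)
  ann <- annotate(fx$spectra[[1]], fx$psms[[1]], st)
  pts <- qc_points(ann, "intensity")
  svg <- qc_svg(pts, "intensity")
  expect_identical(count_nodes(svg, "//circle"), nrow(pts))
  apts <- qc_points(ann, "mz", absolute = TRUE)
  expect_true(all(apts$error_ppm >= 0))
  empty <- qc_svg(qc_points(annotate(spectrum(), fx$psms[[1]], st)),
                  "mz")
  expect_identical(count_nodes(empty, "//circle"), 0L)
  expect_gt(count_nodes(empty, "//line[contains(@class,'axis')]"), 0L)
})

test_that("styles validate their inputs and drive colors", {
  expect_error(render_style(color_alpha = "red"), "grepl")
  st <- render_style(color_alpha = "#00ff00", width = 100, height = 50)
  psm <- psm_from_sequences("PEPTIDE")
  aset <- annotation_settings("10ppm", "b", 1)
  fr <- generate_fragments(psm, aset)
  ann <- annotate(spectrum(fr$mz[1], 10), psm, aset)
  expect_match(spectrum_svg(ann, st), "#00ff00")
  expect_match(spectrum_svg(ann, st), 'width="100"')
})
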