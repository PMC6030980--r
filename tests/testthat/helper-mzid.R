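# Handcrafted mzIdentML fixtures built in code (kept tiny and readable).

mzid_header <- function(body) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.2" ',
    'version="1.2.0" id="fixture">\n', body, "\n</MzIdentML>\n")
}

# Linear fixture: one spectrum, two ranked identifications (rank 2 = the
# alternative explanation), second peptide carries an oxidation, and the
# second PeptideEvidence is a decoy.
write_mzid_linear_fixture <- function(path) {
  body <- paste0(
    '<SequenceCollection>\n',
    ' <DBSequence id="db1" accession="PROT1"/>\n',
    ' <DBSequence id="db2" accession="PROT2"/>\n',
    ' <Peptide id="pep1"><PeptideSequence>PEPTIDEK</PeptideSequence></Peptide>\n',
    ' <Peptide id="pep2"><PeptideSequence>MKPEPTIDK</PeptideSequence>\n',
    '  <Modification location="1" monoisotopicMassDelta="15.99491">\n',
    '   <cvParam cvRef="UNIMOD" accession="UNIMOD:35" name="Oxidation"/>\n',
    '  </Modification>\n',
    ' </Peptide>\n',
    ' <PeptideEvidence id="pe1" peptide_ref="pep1" dBSequence_ref="db1" isDecoy="false"/>\n',
    ' <PeptideEvidence id="pe2" peptide_ref="pep2" dBSequence_ref="db2" isDecoy="true"/>\n',
    '</SequenceCollection>\n',
    '<AnalysisData><SpectrumIdentificationList id="sil1">\n',
    ' <SpectrumIdentificationResult id="sir1" spectrumID="index=0" spectraData_ref="sd1">\n',
    '  <SpectrumIdentificationItem id="sii1" rank="1" chargeState="2" ',
    'experimentalMassToCharge="464.75" passThreshold="true" peptide_ref="pep1">\n',
    '   <PeptideEvidenceRef peptideEvidence_ref="pe1"/>\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1001171" name="search score" value="55.2"/>\n',
    '  </SpectrumIdentificationItem>\n',
    '  <SpectrumIdentificationItem id="sii2" rank="2" chargeState="2" ',
    'experimentalMassToCharge="523.78" passThreshold="false" peptide_ref="pep2">\n',
    '   <PeptideEvidenceRef peptideEvidence_ref="pe2"/>\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1001171" name="search score" value="12.9"/>\n',
    '  </SpectrumIdentificationItem>\n',
    ' </SpectrumIdentificationResult>\n',
    '</SpectrumIdentificationList></AnalysisData>')
  writeLines(mzid_header(body), path)
  path
}

# Cross-link fixture: one spectrum, donor/acceptor Modification pair with
# shared value "1.0" fused into one cross-linked PSM (GKGK pos 2 --
# 138.06808 Da -- LKEK pos 4).
write_mzid_crosslink_fixture <- function(path, orphan_donor = FALSE) {
  acceptor <- if (orphan_donor) "" else paste0(
    ' <Peptide id="pepB"><PeptideSequence>LKEK</PeptideSequence>\n',
    '  <Modification location="4" monoisotopicMassDelta="0">\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1002510" ',
    'name="cross-link acceptor" value="1.0"/>\n',
    '  </Modification>\n',
    ' </Peptide>\n',
    ' <PeptideEvidence id="peB" peptide_ref="pepB" dBSequence_ref="db2" isDecoy="false"/>\n')
  acceptor_sii <- if (orphan_donor) "" else paste0(
    '  <SpectrumIdentificationItem id="siiB" rank="1" chargeState="3" ',
    'experimentalMassToCharge="388.22" passThreshold="true" peptide_ref="pepB">\n',
    '   <PeptideEvidenceRef peptideEvidence_ref="peB"/>\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1001171" name="search score" value="31.5"/>\n',
    '  </SpectrumIdentificationItem>\n')
  body <- paste0(
    '<SequenceCollection>\n',
    ' <DBSequence id="db1" accession="PROTA"/>\n',
    ' <DBSequence id="db2" accession="PROTB"/>\n',
    ' <Peptide id="pepA"><PeptideSequence>GKGK</PeptideSequence>\n',
    '  <Modification location="2" monoisotopicMassDelta="138.06808">\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1002509" ',
    'name="cross-link donor" value="1.0"/>\n',
    '  </Modification>\n',
    ' </Peptide>\n',
    ' <PeptideEvidence id="peA" peptide_ref="pepA" dBSequence_ref="db1" isDecoy="false"/>\n',
    acceptor,
    '</SequenceCollection>\n',
    '<AnalysisData><SpectrumIdentificationList id="sil1">\n',
    ' <SpectrumIdentificationResult id="sir1" spectrumID="index=0" spectraData_ref="sd1">\n',
    '  <SpectrumIdentificationItem id="siiA" rank="1" chargeState="3" ',
    'experimentalMassToCharge="388.22" passThreshold="true" peptide_ref="pepA">\n',
    '   <PeptideEvidenceRef peptideEvidence_ref="peA"/>\n',
    '   <cvParam cvRef="PSI-MS" accession="MS:1001171" name="search score" value="31.5"/>\n',
    '  </SpectrumIdentificationItem>\n',
    acceptor_sii,
    ' </SpectrumIdentificationResult>\n',
    '</SpectrumIdentificationList></AnalysisData>')
  writeLines(mzid_header(body), path)
  path
}
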