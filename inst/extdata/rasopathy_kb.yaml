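# RASopathy gene knowledge base -- curated, replaceable defaults.
#
# PM1 domain coordinates and PM5_Strong hotspot residues are PROVISIONAL
# curated values (the expert panel's authoritative appendix coordinates are
# not reproduced here); edit this file to substitute panel-curated data.
# Alignments are synthetic: column structure encodes published residue
# correspondences only. Thresholds are Grpmax filtering allele frequencies
# (fractions). Assay mechanisms (AD/AR) drive the LZTR1 functional-data
# routing branch.
defaults:
  ba1: 0.0005
  bs1: 0.00025
  pm2: 0.0000025

alignments:
  RAS: alignments/ras_family_synthetic.fasta
  RAF: alignments/raf_family_synthetic.fasta
  MAP2K: alignments/map2k_family_synthetic.fasta
  SOS: alignments/sos_family_synthetic.fasta

transcripts:
  LZTR1: lztr1_transcript_synthetic.tsv

genes:
  PTPN11:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pp2_applicable: true
    pm1_domains:
      - {name: N-SH2, start: 3, end: 104}
    pm5_strong_hotspots: [61, 63, 72, 76, 279, 308, 501, 510]
    approved_assays:
      - {id: phosphatase_activity, mechanism: AD}
      - {id: p_erk, mechanism: AD}
    paralog_family: none
  BRAF:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pp2_applicable: true
    pm1_domains:
      - {name: CR3-kinase, start: 457, end: 717}
    pm5_strong_hotspots: [241, 257, 262, 469, 581, 600]
    approved_assays:
      - {id: kinase_activity, mechanism: AD}
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAF
  RAF1:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: CR2, start: 251, end: 266}
    pm5_strong_hotspots: []
    approved_assays:
      - {id: kinase_activity, mechanism: AD}
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAF
  SOS1:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains: []
    pm5_strong_hotspots: [266, 269]
    approved_assays:
      - {id: p_erk, mechanism: AD}
    paralog_family: SOS
  SOS2:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains: []
    pm5_strong_hotspots: []
    approved_assays:
      - {id: p_erk, mechanism: AD}
    paralog_family: SOS
  KRAS:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 10, end: 17}
      - {name: SW1, start: 30, end: 40}
      - {name: SW2, start: 59, end: 76}
      - {name: SAK, start: 145, end: 147}
    pm5_strong_hotspots: [12, 13, 60, 61]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
      - {id: gtp_hydrolysis, mechanism: AD}
    paralog_family: RAS
  HRAS:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 10, end: 17}
      - {name: SW1, start: 30, end: 40}
      - {name: SW2, start: 59, end: 76}
      - {name: SAK, start: 145, end: 147}
    pm5_strong_hotspots: [12, 13, 61, 117]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
      - {id: gtp_hydrolysis, mechanism: AD}
    paralog_family: RAS
  NRAS:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 10, end: 17}
      - {name: SW1, start: 30, end: 40}
      - {name: SW2, start: 59, end: 76}
      - {name: SAK, start: 145, end: 147}
    pm5_strong_hotspots: [12, 13, 61]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAS
  MRAS:
    validity: {AD: Moderate}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 20, end: 27}
      - {name: SW1, start: 40, end: 50}
      - {name: SW2, start: 69, end: 86}
    pm5_strong_hotspots: [22, 23, 68]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAS
  RIT1:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 29, end: 36}
      - {name: SW1, start: 49, end: 59}
      - {name: SW2, start: 78, end: 95}
    pm5_strong_hotspots: [57, 82, 90]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAS
  RRAS2:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: P-Loop, start: 21, end: 28}
      - {name: SW1, start: 41, end: 51}
      - {name: SW2, start: 70, end: 87}
    pm5_strong_hotspots: [72]
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: RAS
  MAP2K1:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pp2_applicable: true
    pm1_domains:
      - {name: kinase, start: 68, end: 361}
    pm5_strong_hotspots: []
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: MAP2K
  MAP2K2:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains:
      - {name: kinase, start: 72, end: 365}
    pm5_strong_hotspots: []
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
    paralog_family: MAP2K
  SHOC2:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pm1_domains: []
    pm5_strong_hotspots: []
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: membrane_localization, mechanism: AD}
    paralog_family: none
  LZTR1:
    validity: {AD: Definitive, AR: Definitive}
    inheritance_modes: [AD, AR]
    pvs1_applicable: true
    pm3_applicable: true
    pm1_domains: []
    pm5_strong_hotspots: []
    thresholds: {pm2: 0.000025, pm2_ar: 0.000025}
    approved_assays:
      - {id: p_erk, mechanism: AD}
      - {id: p_mek, mechanism: AD}
      - {id: protein_stability, mechanism: AR}
      - {id: subcellular_localization, mechanism: AR}
    paralog_family: none
  PPP1CB:
    validity: {AD: Definitive}
    inheritance_modes: [AD]
    pp2_applicable: true
    pm1_domains: []
    pm5_strong_hotspots: []
    approved_assays: []
    paralog_family: none
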