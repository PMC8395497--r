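# Default promoter motif catalog (IUPAC consensus strings, literature
# consensus for each element). max_mismatches applies per window; strands
# says whether the reverse strand is scanned as well.
motifs:
  - name: MRE
    pattern: TGCRCNC
    max_mismatches: 0
    strands: both
  - name: HRE
    pattern: RCGTG
    max_mismatches: 0
    strands: both
  - name: HAS
    pattern: CASAG
    max_mismatches: 0
    strands: both
  - name: TATA
    pattern: TATAWAWR
    max_mismatches: 0
    strands: both
  - name: Inr
    pattern: YYANWYY
    max_mismatches: 0
    strands: both
  - name: DPE
    pattern: RGWYVT
    max_mismatches: 0
    strands: both
  - name: GCbox
    pattern: KRGGCGKRRY
    max_mismatches: 0
    strands: both
  - name: NFkB
    pattern: GGGRNNYYCC
    max_mismatches: 0
    strands: both
  - name: NRF1
    pattern: RCGCRTGCGY
    max_mismatches: 0
    strands: both
  - name: CsMBE
    pattern: TGACNNNGC
    max_mismatches: 0
    strands: both
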