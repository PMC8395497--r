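# Functional-domain residues of the human ferritin heavy chain (HuHF),
# in conventional HuHF numbering (starting after the initial methionine).
# Literature-standard residue sets; the three lists must stay disjoint so
# that every replacement is attributed to exactly one domain. E61, which
# some sources list in both the ferroxidase center and the nucleation
# site, is assigned here to the ferroxidase center.
# NOTE: residue letters are quoted ("Y", "N" are YAML booleans otherwise).
ferroxidase_center:
  "E": [27, 61, 62, 107]
  "Y": [34]
  "H": [65]
  "Q": [141]
iron_ion_channel:
  "D": [131]
  "E": [134]
nucleation_site:
  "E": [64, 67]
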