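# Annotation config for complexes written by make_toy_tcr_pmhc()
# (and the conventional chain lettering of class I TCR-pMHC entries).
roles:
  A: mhc_heavy
  B: b2m
  C: peptide
  D: tcr_alpha
  E: tcr_beta
cys_pairs:
  tcr_alpha: [23, 104]
  tcr_beta: [23, 104]
# cdr_ranges and helix_ranges fall back to the package defaults
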