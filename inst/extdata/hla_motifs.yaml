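# HLA class I anchor-motif conventions used to assign peptide restriction.
# Anchors are position 2 and the C-terminus; residue sets follow the commonly
# used binding-motif summaries for each allele. This file is configuration,
# not code: edit or extend it to cover further alleles or antibodies.
alleles:
  "A*02:01":
    p2: [L, M, I, V, A, T, Q]
    cterm: [V, L, I, A]
  "A*03:01":
    p2: [L, V, I, M, A, T, S]
    cterm: [K, R, Y]
  "B*07:02":
    p2: [P, A]
    cterm: [L, F, M, I]
antibodies:
  "BB7.2": ["A*02:01"]          # HLA-A*02-specific
  "GAP-A3": ["A*03:01"]         # HLA-A*03-specific
  "W6/32": pan                  # pan HLA class I
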