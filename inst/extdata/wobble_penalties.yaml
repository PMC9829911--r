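# Codon:anticodon pairing penalties at codon position 3 / anticodon
# position 34.  `pairing` maps the effective base at position 34 (after
# `modifications` are applied) to the codon-3 bases it can read, with the
# selective penalty s in [0,1]; a decoder contributes (1 - s) times its
# abundance.  Watson-Crick pairs must have s = 0.  Constants are the
# classical tRNA-adaptation-index wobble penalties (dos Reis et al. 2004).
# I = inosine (deaminated A34), L = lysidine (modified C34 of the
# bacterial Ile AUA decoder).  DNA alphabet: U is written T.
pairing:
  A: {T: 0}
  C: {G: 0}
  G: {C: 0, T: 0.41}
  T: {A: 0, G: 0.68}
  I: {T: 0, C: 0.28, A: 0.9999}
  L: {A: 0.89}
modifications:
  - {anticodon: CAT, isotype: I, effective: L}
  - {base34: A, effective: I}
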