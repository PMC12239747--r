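# Small complete screen: 12 source plates (one full pooling block) fully
# occupied by 1,152 M2 lines over a synthetic 3-gene target.
seed: 1
population:
  n_lines: 1152
  mu: 2.43e-6
  canonical_mass: 0.8
genes:
  n_genes: 3
pooling:
  n_plates: 12
poolseq:
  depth: 2000
  error_rate: 0.001
  min_alt_reads: 3
  min_af: 0.00520833
decoding:
  max_pool_hits: 3
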