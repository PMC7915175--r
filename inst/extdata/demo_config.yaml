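# demo simulation: two TE families and a microsatellite on a 60 kb background
genome_length: 60000
gc_fraction: 0.44
families:
  - label: DNA/hAT-Ac
    n_copies: 8
    K: 0.08
    consensus_length: 400
  - label: LTR/Gypsy
    n_copies: 5
    K: 0.18
    consensus_length: 500
ssrs:
  - motif: AC
    copies: 9
    n_loci: 3
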