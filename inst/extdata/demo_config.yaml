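# Demo evaluation: synthetic reference set with defects chosen to mirror
# known weak spots of the packaged primer pairs (terminal 3' mismatches of
# 68f in Bacteroidetes/Chlorobi, of 341f in Armatimonadetes, and the
# Alphaproteobacteria internal length polymorphism between the 341f and
# 785r sites).
primers: default
pairs:
  - [341f, 785r]
  - [68f, 518r]
reference:
  synthetic:
    seed: 20170328
    length_range: [1200, 1600]
    deletion_start: 454
    taxa:
      - {taxon: Alphaproteobacteria, n_records: 8, defect: deletion, defect_frac: 0.5, deletion_len: 21}
      - {taxon: Bacteroidetes, n_records: 8, defect: terminal_mismatch, defect_frac: 0.25, defect_primer: 68f}
      - {taxon: Chlorobi, n_records: 8, defect: terminal_mismatch, defect_frac: 0.4, defect_primer: 68f}
      - {taxon: Actinobacteria, n_records: 8}
      - {taxon: Armatimonadetes, n_records: 8, defect: terminal_mismatch, defect_frac: 0.5, defect_primer: 341f}
ranks: [domain, phylum]
method: both
threshold: 1.0
three_prime_len: 5
max_gaps: 2
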