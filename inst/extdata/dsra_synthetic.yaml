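# Designed synthetic stand-in for the cold-shock sRNA DsrA (87 nt here).
# Same caveat as ryhb_synthetic.yaml: coordinate anchors (three stem-loops,
# rpoS seed in the 5' region, hns seed in the middle, terminator + poly-U)
# on a designed Watson-Crick-consistent sequence, not the published one.
name: DsrA_synthetic
sequence: AACGCACUGAAUCGAAUAACAGUGCAUAAUGGACUCAACGAUAAAUGAGUCCAAUUAAGCCGCUCUUCGUAAAGAGCGGCUUUUUUU
structure: "...((((((..........)))))).....((((((..........))))))......(((((((........)))))))......."
stem_loops:
  - name: SL1
    start: 4
    end: 25
  - name: SL2
    start: 31
    end: 52
  - name: SL3
    start: 59
    end: 80
regions:
  start: [1, 27]
  middle: [28, 60]
  end: [61, 87]
targets:
  - name: hns
    mode: repressed
    mrna_site: GGAGAAUACAUUUAUCGUUAUGAGCGAAG
    srna_seed_interval: [37, 45]
    mrna_site_interval: [11, 19]
  - name: rpoS
    mode: activated
    mrna_site: ACUGGAUAUUCGAUUGGAUCACGAAAGGA
    srna_seed_interval: [10, 18]
    mrna_site_interval: [7, 15]
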