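# Designed synthetic stand-in for the 94-nt iron-stress sRNA RyhB.
# The published sequence/structure (RNase-probing derived) is not packaged;
# this reference reproduces its coordinate anchors -- three stem-loops 5'->3',
# SL1 closed by A30, seed region 38-46 carrying A38, SL2 ending at U55,
# a GC-rich terminator stem-loop SL3 and a 3' poly-U tail -- on a designed
# sequence whose annotated pairs are Watson-Crick consistent. Override with
# your own config to analyse real data.
name: RyhB_synthetic
sequence: AGCACUGCACCGCAAUGAUAAAGCGGUGCAACAUUAGACGUCACAAGAAUCGUCUAUUGCUCAUGGCCGCUCUUCGAAGAGCGGCCUUUUUUUU
structure: ".....((((((((.........)))))))).....(((((..........))))).........((((((((......))))))))........"
stem_loops:
  - name: SL1
    start: 6
    end: 30
  - name: SL2
    start: 36
    end: 55
  - name: SL3
    start: 65
    end: 86
regions:
  start: [1, 35]
  middle: [36, 67]
  end: [68, 94]
targets:
  - name: sodB
    mode: repressed
    mrna_site: AAGGAGAUAUUUGUGACGUAUGAGCAAAC
    srna_seed_interval: [38, 46]
    mrna_site_interval: [11, 19]
  - name: shiA
    mode: activated
    mrna_site: GCACAUAGCUUGUGACGGAAAGGAAACAG
    srna_seed_interval: [39, 47]
    mrna_site_interval: [9, 17]
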