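Package: qsortseq
Title: Quantitative Sort-Seq Analysis of Small-RNA Sequence-Function Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative sort-seq (FACS-seq) analysis of bacterial
    small regulatory RNA (sRNA) mutant libraries. Simulates mutagenesis-PCR
    libraries sorted into log-spaced fluorescence gates and sequenced per bin;
    infers per-variant mean fluorescence from binned read counts by maximum
    likelihood and converts it to fold-change regulatory efficiency; fits an
    additive position-weight energy model and a six-parameter heuristic model
    built on stem-loop folding and seed-target hybridization free energies;
    and maps intramolecular epistasis, including compensatory-pair and
    structural-looseness enrichment statistics. Includes a self-contained
    nearest-neighbour RNA folding backend with an optional ViennaRNA adapter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
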