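---
title: "Methods: quantitative sort-seq analysis of sRNA sequence-function maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative sort-seq analysis of sRNA sequence-function maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsortseq)
```

# The measurement model

Quantitative sort-seq (qSortSeq) measures the regulatory efficiency of
thousands of small-RNA (sRNA) sequence variants at once. A mutagenized
library of an sRNA gene is expressed in cells carrying a GFP target-reporter
for one of the sRNA's mRNA targets; cells are sorted by fluorescence into
4-6 gates spaced evenly on a log scale over a range containing about 90% of
the library, and the sRNA amplicon is sequenced separately from each gate.
Each variant's read counts across gates form a coarse histogram from which
its mean fluorescence — and hence the fold-change it imposes on its target —
is inferred.

## Single-cell fluorescence

Clonal populations show considerable cytometric noise. We model single-cell
log10 fluorescence of a variant as Normal(mu, sigma) with a *shared* sigma
across variants: at 50-70 cells per variant a per-variant sigma is not
identifiable, while clonal control rows (wild type and the empty-vector,
no-sRNA control, carried in every table under the reserved keys `WT` and
`NOSRNA`) pin the shared value well. `estimate_sigma()` maximizes the joint
likelihood of all control rows, profiling out one free mean per control.
The log-normal form is a modelling choice (log-scale cytometry histograms
of clonal strains are approximately symmetric); the generator keeps it
pluggable in the sense that every downstream step consumes only bin
probabilities, which can be re-derived for another law.

## Maximum-likelihood mean inference

For gates with boundaries $g_1 < \dots < g_{K+1}$, the probability that a
*sorted* cell of a variant with mean $\mu$ lands in bin $b$ is

$$p_b(\mu) = \frac{\Phi\!\left(\frac{g_{b+1}-\mu}{\sigma}\right) -
\Phi\!\left(\frac{g_b-\mu}{\sigma}\right)}{Z(\mu)},$$

where $Z$ is the probability of the whole gated range: the likelihood
conditions on the cell being sorted, because roughly 10% of cells fall
outside the gates and are never observed (`bin_probabilities()`, with an
unconditioned variant behind a flag). `infer_mean_fluorescence()` maximizes
$\sum_b w_b n_b \log p_b(\mu)$ over $\mu$, with per-bin weights $w_b$
converting read counts to estimated cell proportions.

Two layers of sampling stand between $\mu$ and the read counts: cells into
bins, then reads from each bin's cell pool. Reads are deep but not
infinite, so we use the quasi-multinomial weight
$w_b = \frac{c_b/r_b}{1 + c_b/r_b}$ (with $c_b$ cells sorted and $r_b$
reads sequenced in bin $b$): the numerator rescales reads to cells, the
denominator discounts the information lost to read resampling. Without the
discount, standard errors are understated by several percent at typical
depth and the downstream interaction z-scores become anticonservative.

Standard errors come from the observed information at the maximum and
confidence intervals from the profile likelihood. Two censoring rules mark
variants the assay cannot quantify: (i) all weighted counts in a single
extreme bin — the likelihood increases monotonically toward the gate edge,
so the estimate is pinned at the outer boundary with a one-sided interval;
(ii) an interior maximum that falls outside the gated range — such a
variant's cells are observed only through the truncated tail of its
distribution, and its point estimate is unstable. Censored records carry
their flag through every table and are excluded from model fitting.

## Efficiency and the two-state energy scale

The *efficiency* $f$ of a variant is the fold-change it imposes on its
target: mean control fluorescence divided by variant fluorescence for
repressed targets, and the reciprocal for activated ones. Relative
expression $u = 1/f$ maps onto a two-state energy through the logistic
relation

$$u = \frac{1}{1 + e^{-S}}, \qquad S = \ln\frac{u}{1-u},$$

the form that arises when the sRNA-target pair alternates between an active
and a repressed state. $u$ is clamped into $(\epsilon, 1-\epsilon)$ with
$\epsilon = 10^{-3}$ before taking the logit; clamped records are flagged
(`clamped`) but retained — their energy is pinned at the dynamic-range
boundary, which is information, unlike a censored fluorescence estimate,
which is not. The standard error of $S$ follows by the delta method,
$\mathrm{se}_S = \ln(10)\,\mathrm{se}_\mu/(1-u)$.

# The additive position-weight model

Each single-mutant record $v$ (position $j$ substituted to base
$\sigma$) contributes an energy change $\Delta S_{j\sigma} = S_v -
S_{\mathrm{WT}}$, zero at the wild-type base. The additive model predicts a
multi-mutant's energy as
$S_{\mathrm{add}} = S_{\mathrm{WT}} + \sum_j \Delta S_{j\sigma_j}$.
At full single-mutant coverage of an $L$-nt molecule this model has
$3L + 1$ free parameters — 283 for the packaged 94-nt reference. Entries
with no measured single mutant are *masked*: predictions that need them
fail loudly rather than imputing zero (imputation sits behind an explicit
flag for scoring distant homolog sequences, where silent zeros are the
lesser evil and the user has opted in).

# Free-energy models

## The reference energy backend

`energy_backend("reference")` is a self-contained minimum-free-energy
folder: a Zuker-style dynamic program over nested structures scored with a
simplified nearest-neighbour model — stacking bonuses for Watson-Crick and
GU stacks (`-(0.5 + 0.4(s_1+s_2))` kcal/mol with pair strengths GC = 3,
AU = 2, GU = 1), a logarithmic hairpin-loop penalty
($4.5 + 1.1\ln(l/3)$, minimum loop 3), affine bulge and internal-loop
penalties, and an affine multiloop term. The tables are deliberately simple
constants, not measured thermodynamic parameters: the package's claims rest
on *differences* (ddG) within one backend, and the backend itself is pinned
by an exhaustive oracle — for sequences up to 12 nt, every nested structure
is enumerated and scored by an independent loop-decomposition scorer
(`enumerate_structures()`, `structure_energy()`), and the dynamic program
must match the minimum exactly. Bulge/internal loops are capped at 30 nt
(the usual convention; irrelevant below 14 nt, where the oracle applies).

Hybridization (`duplex_energy`) scans all antiparallel registers between
the sRNA seed and the target site, allows at most one single-nucleotide
bulge on either strand, and scores duplex initiation plus stacking over
runs of consecutive WC/GU pairs. Seed regions here are short and
contiguous, which keeps this register model adequate.

`energy_backend("vienna")` adapts the RNAfold/RNAcofold executables where
available. Numbers are *not* comparable across backends; every analysis
records which backend produced its energies.

## The six-parameter heuristic model

The additive model needs near-complete single-mutant coverage. The
heuristic model instead predicts efficiency from three computed
free-energy changes — self-folding of the two target-independent stem-loops
(SL1, SL3) and seed-target hybridization — using six parameters, a weight
and an offset per term:

$$S(v) = S_{\mathrm{WT}} + \sum_{k} w_k\left[\mathrm{softplus}(\Delta\Delta
G_k - b_k) - \mathrm{softplus}(-b_k)\right].$$

The saturating softplus captures the observed response shape (small
destabilizations cost little; large ones plateau at complete loss), and the
centring term makes the wild type ($\Delta\Delta G = 0$) map exactly onto
the measured $S_{\mathrm{WT}}$, which is taken from the wild-type record
rather than fitted — so exactly six parameters are free. The exact
functional composition of the published model is not available to us; this
form is the package's own choice, kept behind the `heuristic_model`
interface so an alternative composition can replace it. Fitting is least
squares on the $S$ scale (the model's linear scale, unlike $f$), by BFGS
from a deterministic multi-start schedule (8 restarts; the first start is
slope-matched to the data, the rest draw from wide uniform ranges under the
session RNG). Weights are constrained non-negative: a destabilizing energy
change cannot strengthen regulation in this model class.

Single-feature relations are summarized by `fit_energy_response()`, a
three-parameter decaying logistic of log fold-change against ddG
(plateau, midpoint, slope), fitted by Nelder-Mead with a BFGS polish.

# Interaction (epistasis) analysis

For every variant with *exactly two* mutations (pairs inside higher-order
variants are not pooled — background mutations would confound them), the
interaction strength is

$$\mathrm{IS} = \ln\frac{f_{\mathrm{obs}}}{f_{\mathrm{add}}},$$

positive when the double mutant is stronger than the additive prediction
(synergistic), negative when weaker (antagonistic). The standard error
propagates all four contributing measurements — the double mutant, both
single mutants and the wild type — through the chain
$\mathrm{se}_{\ln f} = (1-u)\,\mathrm{se}_S$. Records are called
synergistic/antagonistic at $|z| \ge 3$ by default, with Benjamini-Hochberg
FDR reported alongside; ranked lists (`top_interactions()`) order by $|z|$
with a deterministic tie-break (|IS| descending, then variant key).

A pair is *compensatory* when its positions are paired in the wild-type
structure, each mutation alone breaks the pairing, and the double restores
a strict Watson-Crick pair. A single mutation that converts a WC pair into
a GU wobble counts as *retaining* pairing — functional seeds tolerate a
single GU wobble — so such pairs are not compensatory; the full 9-case
policy for a C-G pair is pinned in the test suite.

Enrichment of same-stem-loop membership among the top interactions, and of
"loose" seed-stem-loop structure (ddG_fold(SL2) > 0) among efficient
variants, use one-sided Fisher exact tests (the hypergeometric tail) in the
enrichment direction; two-sided versions are available. The looseness curve
compares, at each threshold $t$, variants with $f \ge t$ against $f < t$
(not against the whole library — the disjoint split keeps the table's
margins honest), and reports the overall loose fraction as the baseline the
curve reverts to at low thresholds.

# The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
with defaults fixed at the study conditions:

| parameter | default | rationale |
|---|---|---|
| substitutions/variant | Poisson, mean 2.5 | libraries average 2-3 changes |
| substitution spectrum | transition:transversion 3:1 | mutagenesis PCR strongly prefers transitions; exact bias is a config knob |
| cells per variant | Poisson, mean 60 | midpoint of the 50-70 design range |
| cell noise sigma | 0.4 log10 units | clonal-control scale noise |
| gates | 6 bins, 90% coverage | log-even gates over the central 90% of cells |
| reads per bin | 50,000 per 1000-variant library | ~50 reads per variant and bin; experiments scale depth with library size to hold per-variant depth fixed |
| wild-type fold-change | 20 | strong but unsaturated repression |
| empty-vector mean | 3.5 log10 units | top of the dynamic range |

Two truth models generate efficiencies: an additive truth (per-mutation
energy table plus optional planted pairwise epistasis, used for calibration
and recovery experiments) and a heuristic truth built from the energy
backend, so that stem-loop stability and seed-binding effects are present
in the synthetic data; an optional bonus strengthens repression when the
seed stem-loop is loose, emulating the relaxed-specificity phenomenon.

Deliberately **not** emulated: PCR jackpotting (one multinomial per bin
ignores amplification variance), sequencing errors, plasmid copy-number
variation, and growth competition. Passing tests therefore demonstrate
that the estimators are correct *under the stated sampling model* — on real
data, jackpotting inflates read-count dispersion beyond the
quasi-multinomial correction, and sequencing errors add spurious
low-frequency variants that the equal-length Hamming caller will assign to
phantom singles. Both effects bias real analyses and neither is detectable
by these tests.

# Numerical choices

* Mean optimization over $[g_1 - 6\sigma, g_{K+1} + 6\sigma]$ with
  `stats::optimize` at tolerance $10^{-7}$; a finite floor of $-10^{12}$
  replaces $-\infty$ log-likelihoods where bin masses underflow.
* Profile-likelihood intervals by `uniroot` at the $\chi^2_1$ cutoff;
  standard errors from a central second difference with $h = 10^{-3}$.
* Sigma estimation over $[0.02, 2]$ log10 units.
* The heuristic optimizer restarts 8 times; non-convergent starts are
  dropped, and an error is raised only if every start fails.
* Clamping $\epsilon = 10^{-3}$; flagged wherever applied.
* Ties in ranked interactions break deterministically, so outputs are
  byte-stable under a fixed seed.
* Degenerate inputs error loudly: all-zero counts, single-occupied-bin
  controls, constant gate samples, empty threshold grids, inverted
  rescue cutoffs.

Problem sizes in the test suite and acceptance script are chosen so the
whole suite runs in about a minute of CPU: 500-variant libraries for
estimator recovery, ~6,000 double mutants for interaction calibration
(binomial noise on a 1% tail rate needs thousands of pairs to resolve a
±0.5% band), 200 sequences for the folding oracle, 1,500-variant libraries
for heuristic recovery.

# Packaged references

The packaged configs (`ryhb_synthetic.yaml`, `dsra_synthetic.yaml`) are
*designed stand-ins*, marked as such in their filenames and headers: the
published sequences and probing-derived structures are not redistributed
here, so we designed sequences that reproduce the published coordinate
anchors — a 94-nt three-stem-loop molecule with the SL1-closing adenine at
position 30, the seed at 38-46 carrying A38, SL2 ending at U55, a GC-rich
terminator stem-loop and a 3' poly-U tail, with the start/middle/end region
split at 35/67 — and whose annotated pairs are Watson-Crick consistent.
Analyses of real data should supply their own config; every structural
claim the package makes is relative to the supplied annotation.

# Known limitations

* Indels are rejected at the variant-calling stage, never aligned.
* The two-state logistic map compresses extreme efficiencies; energies of
  clamped records sit at the boundary by construction.
* The reference energy tables are ordinal, not thermodynamic: use the
  ViennaRNA adapter where absolute energies matter, and never mix backends
  within one analysis.
* The heuristic model's composition is a declared substitute for the
  original's unpublished form.
* Under the heuristic truth the additive model's predictive power is
  intrinsically limited (the truth saturates); its R^2 there is not
  comparable to values obtained on near-additive experimental maps.
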