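---
title: "Methods: comparative genomic context analysis of EF-P modification genes"
author: "EFPcontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomic context analysis of EF-P modification genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

EFPcontext reimplements, as a tested pipeline, the comparative-genomics
argument that the YjeA (truncated lysyl-tRNA synthetase paralog) and YjeK
(truncated lysine 2,3-aminomutase, LAM) families modify the conserved
Lys34 of bacterial elongation factor P. The argument rests on three
mutually reinforcing observations, each of which is one pipeline stage:
physical clustering of *efp*/*yjeA*/*yjeK* on the chromosome, strict
co-occurrence of *yjeA* and *yjeK* across genomes together with the
conservation of the anchored lysine exactly in that stratum, and a
phylogenetic split of the LAM superfamily into an efp-associated and a
lysine-catabolism-associated subfamily. The package makes every step
explicit, parameterized and testable against synthetic genomes with known
ground truth.

# Family assignment

Genes are assigned by Smith–Waterman local alignment (affine gaps, a gap
of length $L$ costing $\mathrm{open} + \mathrm{ext}\cdot L$) against one
reference sequence per family. Defaults are the community conventions
BLOSUM62, open 11, extend 1. A reference passes for a gene when identity
over aligned columns is at least 0.30 **and** query coverage is at least
0.70; the gene receives the family of its best-scoring passing reference.

* The identity floor of 0.30 reflects the reported 31–33% identities
  between genuine homolog pairs in this system (YjeA vs. LysRS2, YjeK vs.
  LAM): true family members can be this diverged.
* The coverage floor of 0.70 is the operational proxy for the
  "truncation" criterion — YjeA lacks the anticodon-binding domain and
  YjeK the C-terminal multimerization domain, so a full-length relative
  aligning only over the shared catalytic core of a truncated reference
  fails coverage. How the original database annotations drew this line is
  not recorded anywhere, so the thresholds are explicit arguments echoed
  in every output.
* Ties on score across families break to the alphabetically first family
  and are flagged `family-tie`; determinism was preferred over biological
  nuance.
* `X` residues score zero against everything.

Within the LAM superfamily, sequence alone is not trusted: a superfamily
gene whose neighborhood contains *efp* is relabeled *yjeK*, one whose
neighborhood contains *ablB* (β-lysine acetyltransferase, lysine
catabolism) is relabeled *ablA*. Genes with neither context keep their
sequence-based label flagged `context-unresolved`; both contexts at once
flag `conflicting-context` without relabeling.

The alignment kernel is compiled code (score-only rolling-array pass for
screening, full traceback only for threshold evaluation of the top
candidates). Its correctness is pinned two independent ways in the test
suite: exhaustive enumeration of all monotone residue matchings with
minimal affine gap arrangement on short sequences, and agreement with
`Biostrings::pairwiseAlignment` on longer random pairs.

# Physical clustering

Two genes are *clustered* when they lie on the same replicon with at most
`max_intervening = 5` genes between them; circular replicons wrap across
the origin. An *operon* additionally requires co-orientation,
consecutiveness (no intervening genes) and every intergenic gap at most
`operon_max_gap = 100` bp — deliberately a simple criterion, not a
transcription-unit model. The per-genome category is assigned with the
precedence operon > pairwise > none, making the three categories mutually
exclusive as in the survey's 31/60/9 split; genomes missing any of the
three families are `incomplete`. With paralogs, the genome is scored on
its best-clustering combination of copies, and the reported pair is the
one with the fewest intervening genes (ties break by pair name, then
position). Genomes where two distinct family pairs cluster separately are
flagged `multi-pair` rather than double-counted. The underlying database
criterion of the original neighborhood browsing is unstated, so
`max_intervening` is configurable and echoed in all outputs.

# Profiles and summary statistics

Presence is genome-level (any copy counts). Co-occurrence summaries keep
raw counts, and fractions are rounded only at reporting time; percentages
are printed to one decimal. No formal association test is computed — the
inference style being emulated argues from co-occurrence and clustering,
not from p-values.

# Motif-anchored conservation

The original analysis aligned full EF-P sequences and cut a 9-residue
window around position 34. This package anchors directly on the conserved
`PGKG` motif instead, which is justified because the motif itself defines
the focal position: an exact match wins (leftmost first), and otherwise
every window of motif length is scored with the focal position free and
the flanks scored by BLOSUM62 against the motif, accepting the leftmost
best window with flank score at least 12 (three near-identical flank
residues; P+G+G at identity scores 19). The free focal position is what
lets Arg/Met/Asn/Gln replacements anchor. Sequences with no qualifying
window are excluded and counted.

Residue percentages are computed per sequence by default — paralogs
contribute one observation each — with a per-genome mode (any copy
carrying the reference residue) available, since the survey's exceptions
are all paralog cases. Logo information content per column is
$R = \log_2 20 - (H + e_n)$ with Shannon entropy $H$ in bits and the
small-sample correction $e_n = 19/(2\ln 2\, n)$, clamped at zero; only
standard residues enter a column's $n$.

# Distances, trees, supports

Pairwise distances maximize the likelihood
$\sum_{\text{sites}} \log\left(\pi_{a}\, P_t(a\!\to\! b)\right)$ under the
Jones–Taylor–Thornton model, with the rate matrix built from the published
exchangeability counts and stationary frequencies, normalized to one
expected substitution per site per unit branch length. The transition
matrix is computed by eigendecomposition of the symmetrized generator,
which also gives detailed balance to machine precision. Gap handling is
pairwise deletion. The optimum is located by golden-section search on
$[10^{-6}, 10]$ to a tolerance of $10^{-6}$; an optimum at the upper bound
is flagged `saturated`. The estimator is validated against a dense grid
evaluation of the same likelihood, against an independent implementation
(`phangorn::dist.ml`), and by parameter recovery on sequences simulated at
known distances.

Trees are built with neighbor-joining (Studier–Keppler criterion, via
`ape::nj`); negative branch-length estimates are clamped to zero with the
originals retained in an attribute. Column bootstrap resamples alignment
columns with replacement to the original width and repeats distance + NJ;
supports are reported as counts of replicates containing each bipartition
(the classical style, e.g. "923 of 1000"), not percentages, with the
majority-rule consensus available on request.

The subfamily split partitions taxa at the tree's longest internal edge —
the structural deep split — and, within each side, takes the largest
clade uniform for the side's dominant genomic-context label. Labeled taxa
disagreeing with their side's clade are reported as placement conflicts;
unlabeled taxa inside a kept clade are `imputed`. This two-sided design
targets the two-subfamily question; a radiation into three or more
context groups would require recursive splitting, which is out of scope.
The conserved active-site region (e.g. 118 columns) is accepted as an
input column slice, never inferred.

# The synthetic-genome generator

The generator is first-class, tested code. Its defaults are the emulated
survey's conditions: 725 genomes; 200/725 with both *yjeA* and *yjeK*
(plus 2/725 carrying *yjeA* alone, mirroring the two known symbiont
exceptions); arrangements 31/60/9 among the with-both genomes; 97% of
with-both genomes carrying a single lysine EF-P, the remainder a paralog
pair (one Lys copy, one Ala/His); and a 70/24.1/3.4/2.2/0.3 K/R/M/N/Q mix
in the without stratum.

Because the emulated survey is a *fixed cohort* — a supplement listing
exactly which genome has what — these compositions are planted exactly
(largest-remainder quotas interleaved over genome indices, deterministic
given the cohort size) rather than drawn independently per genome.
Randomness is reserved for what varies biologically: gene layout, decoy
content, and sequence evolution, each driven by an RNG stream derived
from (seed, genome index) so runs are reproducible end to end. Per-genome
realism choices, made once: 20–60 decoy genes of 120–400 residues drawn
from the JTT stationary distribution (so they fail the coverage/identity
thresholds); planted members evolved from the family references by a JTT
process at distance 0.3 substitutions/site; operon gaps 20–80 bp, other
intergenic gaps 200–1500 bp; planted blocks separated by at least 6
decoys so they can never cluster across blocks under the default
threshold; an ablA/ablB pair planted in 25% of genomes (the survey does
not quantify this; it only needs to be common enough to exercise the
context split). EF-P sequences keep the 9-residue anchor window fixed to
the reference apart from the planted focal residue.

What the generator does **not** emulate: real gene-content heterogeneity,
intergenic sequence, codon structure, rate variation across sites,
horizontal transfer, or annotation error. Passing closed-loop tests
therefore demonstrates that the pipeline recovers planted signal of the
survey's strength and shape, not that it is robust to every artifact of
real annotation pipelines.

The family references shipped with the package are synthetic stand-ins
generated from the JTT stationary distribution (documented as such), with
the structural relationships that matter built in: the efp reference
carries `PGKG` at positions 32–35, and the yjeK/ablA references share a
diverged N-terminal core with ablA carrying an extra C-terminal domain.

# Numerical and testing choices

* Alignment scores are exact dynamic programming; no heuristics.
* `jttTransition(0)` returns the exact identity matrix; tiny negative
  eigen-reconstruction entries are clamped to zero.
* NJ tie-breaks follow `ape::nj`'s deterministic scan order.
* Bootstrap and simulation never touch the caller's RNG state.
* Problem sizes used by the shipped checks, chosen to exercise every
  stage at the survey's scale while staying desk-sized: 725 simulated
  genomes for the headline statistics, 1000 genomes for
  parameter-recovery bounds (±4 percentage points on the arrangement
  split, binomial 99% CIs on residue percentages), 24-taxon ×
  118-column alignments with 1000 bootstrap replicates for the
  deep-split supports, 1000 random short-sequence pairs against the
  exhaustive alignment oracle, and 100 random additive matrices for NJ
  exactness (patristic error < 1e-9).

# Known limitations

* One reference per family: sensitivity to deeply diverged family members
  depends on that single anchor; profile methods would do better on real
  data.
* The operon model knows nothing of promoters or terminators.
* The subfamily split assumes exactly two context groups.
* The anchoring fallback can, rarely, latch onto a spurious motif-like
  window upstream of the true one; with the default floor this affects
  well under 1% of sequences in simulation.
* Distances assume rate homogeneity across sites (no gamma), matching the
  classical distance-program default being emulated.
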