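# EFPcontext

Comparative-genomics tools for predicting the post-translational
modification partners of bacterial elongation factor P (EF-P).

## The problem

EF-P is strictly conserved in bacteria and carries, in *E. coli*, a
spermidine-derived modification on Lys34 — the residue homologous to the
hypusinylated lysine of eukaryotic/archaeal eIF5A. The enzymes installing
the bacterial modification were long unknown. Two families of unknown
function are strong candidates: **YjeA**, a truncated class II
lysyl-tRNA-synthetase paralog lacking the anticodon-binding domain, and
**YjeK**, a truncated lysine 2,3-aminomutase (LAM) lacking the C-terminal
multimerization domain. The evidence is purely comparative-genomic, and
this package implements that style of inference as a tested, reusable
pipeline:

1. **Family assignment** — genes are assigned to the five tracked families
   (*efp*, *yjeA*, *yjeK*, *ablA*/LAM, *ablB*) by Smith–Waterman local
   alignment against reference sequences (BLOSUM62, affine gaps
   11/1, identity ≥ 0.30 over aligned columns, query coverage ≥ 0.70 — the
   coverage bound is what separates the truncated families from their
   full-length relatives).
2. **Physical clustering** — each genome is classified as
   `three_gene_operon` (the efp/yjeA/yjeK triple co-oriented, consecutive,
   intergenic gaps ≤ 100 bp), `pairwise_cluster` (two of the three within
   ≤ 5 intervening genes), `no_cluster`, or `incomplete`.
3. **Phyletic profiles** — genome × family presence/absence with
   co-occurrence counts and the clustering breakdown restricted to genomes
   carrying both *yjeA* and *yjeK*.
4. **Motif-anchored conservation** — the residue homologous to EF-P Lys34
   is located through the conserved `PGKG` motif (degenerate fallback with
   the focal position free for Arg/Met/Asn/Gln replacements), giving
   per-stratum residue distributions and sequence-logo information content
   `R = log2(20) − (H + 19/(2·ln2·n))` in bits.
5. **Subfamily phylogenetics** — maximum-likelihood pairwise distances
   under the Jones–Taylor–Thornton model, neighbor-joining
   (Studier–Keppler), column bootstrap with supports reported as counts of
   replicates, and a genomic-context split of the LAM superfamily into the
   efp-associated (YjeK) and ablB-associated (canonical LAM) clades.
6. **Synthetic data** — an annotated-genome generator with exact planted
   compositions and a JTT sequence evolver, so every stage closes the loop
   against known truth without downloads.

## Worked example

```r
library(EFPcontext)

sim <- simulateGenomes(simulationConfig(n_genomes = 30), seed = 7)
res <- runPipeline(sim$genomes, n_reps = 10, seed = 3)
cat(reportSummary(res), sep = "\n")
```

```
EF-P modification-gene context report
parameters: max_intervening=5 operon_max_gap=100 bp, motif=PGKG, identity>=0.30 coverage>=0.70, n_reps=10, seed=3
genomes analyzed: 30
yjeA+yjeK co-occurrence: 8/30 genomes (26.7%); yjeA only 0, yjeK only 0, neither 22
clustering among with-both genomes (n=8): operon 25.0%, pairwise 62.5%, none 12.5%
anchored residue, genomes with yjeA+yjeK (n=8 anchored, 0 excluded): K 100.0%
anchored residue, genomes without yjeA+yjeK (n=22 anchored, 0 excluded): K 68.2%, R 22.7%, M 4.5%, N 4.5%
```

Reading this: 8 of the 30 simulated genomes carry both *yjeA* and *yjeK*;
among those, the three genes form an operon in 25% and a two-gene cluster
in 62.5%. Every EF-P from a with-both genome keeps the anchored lysine at
this small n, while in the without stratum the lysine is frequently
replaced (here by Arg/Met/Asn). At survey scale
(n = 725) these statistics settle at the generator's planted conditions —
28% co-occurrence, a 31/60/9 arrangement split, 97% vs 70% lysine
conservation.

The tree stage runs when an aligned FASTA is supplied:

```r
tr   <- twoCladeTree(12, intra = 0.15, deep = 1.0)
aln  <- evolveAlignment(tr, region_length = 118, seed = 11)
main <- consensusSupport(njTree(jttDistanceMatrix(aln)),
                         bootstrapTrees(aln, n_reps = 1000, seed = 5))
ctx  <- setNames(lapply(names(aln), function(t)
  if (startsWith(t, "lam")) "ablB" else "efp"), names(aln))
splitSubfamilies(main, ctx)$clades
#>   clade context  n support
#> 1     1     efp 12    1000
#> 2     2    ablB 12    1000
```

A thin command-line front end over the same functions is installed at
`inst/scripts/efp-context-pipeline.R` (subcommands `simulate` and `run`).

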