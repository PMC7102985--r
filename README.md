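# pathNE

Pathway archaeology for the genetic code: counts enzymatic reaction steps
(*N*<sub>E</sub>) from a common metabolic origin — fructose-6-phosphate
(F6P), where all twenty amino-acid biosynthesis routes branch — to each
amino acid, and uses the result as a proxy timescale for the appearance of
amino acids and of their aminoacyl-tRNA synthetases (aaRSs).

For whom: researchers interested in the coevolution of metabolism and the
genetic code, and anyone needing a small, validated, fully reproducible
pipeline for enzyme-step counting on a declared-route pathway graph.

## The model

Under a constant per-enzyme appearance lag *D*, a pathway of
*N*<sub>E</sub> enzymes forms in time *T* = *N*<sub>E</sub> × *D*, so
*N*<sub>E</sub> = Σ<sub>s</sub> Δ*N*<sub>E,s</sub> (summed over route
segments, spontaneous reactions excluded) orders amino-acid appearance.
Multi-circuit machinery costs extra: a compensation Δ*N*<sub>A</sub>
(20 for His via the completed pentose-phosphate core, 10 for Phe/Tyr/Trp
which branch off before core completion, 0 elsewhere) is added to give
compensated values. The package then checks the 4:4 / 4:4 / 2:2 aaRS
class equi-partition within the three pathway groups (GA glycolytic,
GB citric-acid-cycle derived, GC aromatic) and quantifies the Pearson
correlation between compensated *N*<sub>E</sub> and side-chain
heavy-atom count *N*<sub>SA</sub>, with analytic and permutation
p-values.

## Worked example

```r
library(pathNE)
g   <- canonical_pathway_graph()
tab <- canonical_aa_table()

compute_ne(g, tab[tab$aa == "Thr", ])
#> N_E(Thr): net 9, compensation 0, compensated 9
#>   [F6P-G3P-Ser-Gly-Thr] = 4+3+1+1

nt <- ne_table(g, tab)
partition_counts(tab)
#> aaRS class partition by pathway group
#>      class
#> group I II
#>    GA 4  4
#>    GB 4  4
#>    GC 2  2
#> overall I:II = 10:10; equi-partitioned: TRUE

rank_appearance(nt, tab)$ordered$aa[1:3]
#> [1] "Ser" "Ala" "Gly"

correlate_ne_nsa(nt, tab)
#> N_E vs N_SA correlation (n = 20)
#>   CC = 0.83, R^2 = 0.69, p = 6.5e-06
#>   per class: I 0.90, II 0.87
```

Reading: serine (7 enzymes from F6P) heads the appearance ranking;
histidine closes it at a compensated 39. Each pathway group splits its
aaRSs exactly evenly between the two structural classes, and compensated
*N*<sub>E</sub> tracks side-chain size with CC = 0.83 overall (0.90 /
0.87 within class I / II) — the pattern consistent with class-paired aaRS
appearance along the metabolic timescale.

## Command line

```sh
inst/exec/pathNE run-all --graph inst/extdata/pathway_graph_f6p.json \
  --table inst/extdata/amino_acids.tsv --out-dir out --permute 9999 --seed 1
```

Subcommands `compute-ne`, `partition`, `correlate`, `simulate`, `run-all`;
artifacts are `ne.tsv`, `partition.json`, `corr.json`, `scatter.tsv` and a
`run.log` with input checksums. Re-runs with a fixed configuration and
seed are byte-identical.

## Synthetic data

`generate_pathway_graph()` plants routes with known ground-truth
*N*<sub>E</sub> (plus decoy bypass edges); `generate_correlated_table()`
draws (*N*<sub>E</sub>, *N*<sub>SA</sub>) pairs with controlled linear
structure. Both are seed-deterministic and power the property-based test
suite.
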