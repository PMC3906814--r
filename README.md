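# metalca

Reconstruction of the last-common-ancestor (LCA) gene content of two closely
related bacterial genomes, validated in situ with a metagenome.

## The problem

When two genomes from the same species (ANI ≈ 98%, a "genetic subspecies"
pair) both carry a recently acquired trait — for example a xenobiotic
degradation pathway riding on transposons — the question is which genes were
inherited from their immediate common ancestor and which arrived later by
lateral transfer. `metalca` implements a three-evidence decision rule for
each gene *g* on genome A:

*g* is **ancestral** iff

1. *g* lies inside an orthologous (syntenic) segment shared with genome B —
   collinear blocks chained from spaced-seed anchors (seed weight 30,
   length 40);
2. *g* overlaps no metagenomic island (MGI: a region with < 25% read identity
   or < 25% covered fraction in the recruitment track) and no
   compositionally foreign region (codon-usage log-odds scan, sensitivity
   0.7) on either genome (genome-B intervals are lifted to A through the
   segment map); and
3. the environmental metagenome supports *g* at mean identity > 90% and mean
   depth ≥ 8×.

Around that rule the package provides the full toolkit the analysis needs:
fragment-based ANI (1020-bp fragments, 30%/70% retention), TETRA-style
tetranucleotide z-score profiles and tetra + %GC contig binning (R² ≥ 0.9),
metagenomic read recruitment with windowed coverage/identity tracks,
Nei–Gojobori (NG86) dN/dS — pairwise and pooled across recruited reads — and
de-novo mobile-element discovery by read-overlap-graph clustering (40%
overlap / 80% identity), marker annotation, metagenome validation (≥ 8×) and
tracing onto genomes at ≥ 97% identity.

Because the original study's inputs are multi-gigabase accessions, the
package ships a synthetic-evolution simulator that reproduces the study
conditions at desk scale: an ancestor genome with planted genes, two
descendants at ~2% pairwise divergence carrying composition-distinct genomic
islands and multicopy marker-carrying transposons, and a mixed-community
metagenome — all with truth tables, so every stage is scored by parameter
recovery.

## Worked example

```r
library(metalca)

run <- run_pipeline(default_config(seed = 1))
print(run$evaluation)
#> evaluation vs truth table
#>   ancestral precision: 1.000  recall: 0.988 (TP 79 / FP 0 / FN 1)
#>   marker-gene exclusion: 100%
#>   island base-pair Jaccard: 0.971
#>   transposon elements recovered: 2
#>   ANI estimate: 98.10%

print(run$ani)
#> ANI = 98.10% (directed 98.10 / 98.09; 192 fragments, aligned fraction 0.60)

head(run$calls[run$calls$verdict == "excluded",
               c("gene_id", "exclusion_causes")], 3)
#>      gene_id                                             exclusion_causes
#> 18 isl01_g01                        not_in_ortholog,in_mgi_a,low_coverage
#> 19 isl01_g02 not_in_ortholog,in_mgi_a,foreign_a,low_identity,low_coverage
#> 20 isl01_g03           not_in_ortholog,in_mgi_a,low_identity,low_coverage
```

Reading the report: of the 80 genes the simulated ancestor bequeathed to
genome A, 79 are recovered as ancestral and none of the island or
transposon-marker genes leak in (precision 1.0); all five planted lin-like
marker genes are excluded, the synthetic analogue of laterally acquired
catabolic genes being absent from the LCA. The three planted islands are
recovered with base-pair Jaccard 0.97 at the 25%/25% MGI rule, and the
descendant pair's ANI estimate lands at ~98.1%, matching the simulated 1%
per-lineage substitution rate (expected 100·(1−0.01)² ≈ 98.0). The excluded
island genes show the rule's redundancy: each is caught by several detectors
at once (no ortholog, inside a called MGI, anomalous composition, no
metagenome support). The aligned fraction of 0.60 in the ANI report reflects
genome A's island content, which finds no counterpart in genome B.

Individual stages are ordinary functions: `simulate_ancestor()`,
`evolve_descendant()`, `simulate_metagenome()`, `tetra_zscores()`,
`compute_ani()`, `recruit()` / `build_track()` / `call_mgis()` /
`call_conserved()`, `find_anchors()` / `chain_anchors()`, `find_orfs()` /
`infer_ancestral()` / `map_genotype()`, `ng86_dnds()` / `read_dnds()`,
`build_overlap_graph()` / `cluster_graph()` / `validate_and_trace()`.
See the methods vignette (`vignettes/metalca-methods.Rmd`) for the models,
parameter choices and limitations.

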