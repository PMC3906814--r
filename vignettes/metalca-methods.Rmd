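---
title: "Ancestral gene-content reconstruction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral gene-content reconstruction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metalca` reconstructs the gene content of the last common ancestor (LCA) of
two closely related bacterial genomes and validates the reconstruction
against an environmental metagenome. This vignette is the package's own
account of the science: the decision rule and its assumptions, the model
behind every stage, the tunable parameters with their defaults and
rationale, what the bundled simulator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The decision rule

For each gene $g$ on genome A, with genome B the second descendant and a
metagenome recruited onto both:

$$
\text{ancestral}(g) \iff
\underbrace{g \in \text{orthologous segment}}_{\text{vertical descent}}
\;\wedge\;
\underbrace{\neg(\text{MGI}_A \vee \text{MGI}_B \vee \text{foreign}_A \vee \text{foreign}_B)}_{\text{no recent-acquisition signal}}
\;\wedge\;
\underbrace{\bar{I}_g > 90\% \wedge \bar{D}_g \ge 8}_{\text{in-situ support}}
$$

where $\bar I_g$ and $\bar D_g$ are the length-weighted mean identity and
depth of the recruitment-track windows overlapping $g$. The three clauses
are deliberately redundant: a laterally acquired island is typically caught
by all of (i) absence from the partner genome's syntenic segments, (ii) a
recruitment hole (the surrounding community does not carry it), and (iii)
anomalous composition. The redundancy is what makes the rule robust to any
single detector's blind spots.

Assumptions worth stating: the metagenome must actually contain close
relatives of the two genomes (here, at ANI ≥ 97% to the references);
orthologous-segment membership assumes rearrangements have not shuffled the
genomes below the chaining scale; and "ancestral" means *present in the
immediate common ancestor*, with no claim about deeper history.

## Stage models and parameters

### Tetranucleotide profiles and binning

`tetra_zscores()` compares each 4-mer's observed count (over both strands)
with its maximal-order Markov expectation from the embedded 3- and 2-mers:
$E = n_{123}\,n_{234}/n_{23}$,
$\mathrm{var} = E\,(n_{23}-n_{123})(n_{23}-n_{234})/n_{23}^2$,
$z = (n_{1234}-E)/\sqrt{\mathrm{var}}$. Cells with a zero denominator or
non-positive variance are set to $z = 0$ — the degenerate-count behaviour is
unspecified in the literature, and 0 is the value that carries no signal.
Profiles of multi-replicon inputs sum counts before z-scoring, so the
profile of a genome equals the profile of its concatenated replicons up to
junction windows. Binning (`bin_contigs()`) assigns a contig to the
reference with the highest squared Pearson correlation when $R^2 \ge 0.9$
and the absolute GC difference is at most `gc_tolerance = 0.05`; the squared
correlation follows the published notation of the cutoff, and the GC
tolerance is this package's choice since no number is published. Contigs
under 1 kb are flagged rather than binned; in practice 4-mer z-scores on the
synthetic genomes need ≥ 20–30 kb of contig for a confident assignment, so
the pipeline bins scaffold-sized pieces, and population contigs at 2%
divergence from the reference often (correctly, given the conservative
cutoff) remain unbinned.

### Foreign-gene scan

The published analysis used a sensitivity-0.7 codon-usage HMM restricted to
MGI-free regions. Here the Viterbi machinery is replaced by a per-gene
log-odds scan that keeps the same signal and the same single knob: each
gene's codons are scored under the genome's pooled (native) usage versus the
best of a set of bundled donor usage tables (GC-tilted at 30/40/50% plus
uniform), normalized to nats/codon. Because the pooled table is itself
contaminated by whatever foreign genes are present, the native usage is
re-estimated once from the genes the first pass considers native. The
calling threshold is `min(0, quantile(scores, 1 - sensitivity))`: a gene is
only callable when a donor model genuinely fits better than the native one
(score < 0), and the quantile tightens the threshold when a large foreign
fraction drags the score distribution down. Calls are smoothed along the
genome — runs of ≥ 2 adjacent sub-threshold genes stand, isolated singletons
need an extra 0.05 nats/codon — mirroring the island-scale prior of the
original method. Genes under 30 codons are scored 0 and flagged: their
likelihoods are too noisy to call.

### ANI

`compute_ani()` follows the classical fragment protocol: 1020-bp fragments,
each aligned to the other genome by seed-and-extend ungapped local alignment
(k = 13 seed, match +1 / mismatch −2 maximal-subarray trimming), retained
iff identity ≥ 30% over ≥ 70% of the fragment; directed ANI is the mean
identity of retained fragments and the reported ANI averages the two
directions, since a single number per pair is the convention. Self-ANI is
exactly 100. The local trimming means unalignable fragments simply fail the
70% coverage test rather than dragging identity down — the same behaviour a
search-tool-based protocol gets from its aligner.

### Recruitment, MGIs, conserved regions

`recruit()` keeps one best hit per read (most matching bases; ties to the
leftmost coordinate, then lexicographic replicon), computes identity over
all aligned columns, and discards hits under 25% identity or covering less
than half the read — bare seed matches from unrelated community reads carry
no positional information. Tracks (`build_track()`) tile the reference with
non-overlapping 1-kb windows (the window size is a knob; nothing in the
source analysis pins it) and report depth, covered fraction and
overlap-weighted mean identity. `call_mgis()` flags windows with identity
< 25% or covered fraction < 25% (strict inequalities: boundary equality is
not an island) and merges adjacent flags; `call_conserved()` takes maximal
runs with identity > 90% and depth ≥ 8, the published thresholds for
ancestor-genotype prediction. With default thresholds the two calls are
disjoint by construction on any track where depth ≥ 8 implies coverage
≥ 25%.

### Synteny

Anchors are spaced-seed matches (weight 30, length 40; ones at both pattern
ends, don't-cares spread evenly — adaptive pattern generation is out of
scope) merged along diagonals into maximal runs, scored by matching bases.
Chaining replaces the original black-box Markov-model segmenter with sparse
dynamic programming under an affine gap penalty
$\;30 + 0.01\,\max(g_A,g_B) + 0.5\,|g_A-g_B|$: the diagonal-drift term is
essential — without it, chains absorb off-diagonal anchor pairs between
repeat copies and stitch across large insertions, which would hand
transposon-borne genes an ortholog certificate. Chains are extracted
greedily by score with a floor of `min_segment_score = 2000` (≈ 2 kb of
anchored sequence — the original tool's minimum segment size is unpublished,
so this is the package's knob), and segment ends are padded by one seed
length with clipping against neighbours: a 40-bp seed window cannot straddle
a breakpoint, so raw outermost anchors systematically stop up to one seed
length short of the true homology boundary. Within a segment, A↔B
coordinates map by monotone piecewise-linear interpolation through the
anchors. A gene counts as in-ortholog only if it is fully inside a segment
*and* overlaps at least one anchor: genes sitting wholly in a chain gap
(an insertion the chain jumped across) have no anchored homology at all.

### Gene calling and the reconstructed genotype

`find_orfs()` is a deliberately simple longest-ORF caller (first ATG after
the previous in-frame stop, both strands, ≥ 90 bp, same-strand overlaps
resolved to the longer ORF) standing in for a trained gene finder; users
with real genomes should supply their own gene models, and the pipeline
accepts them. The reconstructed genotype is computed on genome A's models;
the B-side complement is reachable by swapping the genomes.

### dN/dS

The original analysis used a maximum-likelihood codon model; this package
deliberately uses Nei–Gojobori (1986) counting instead, because NG86 admits
an exhaustive small-case oracle (every shortest substitution pathway of a
≤ 5-codon alignment can be enumerated by hand) and the tests exploit that.
Estimates therefore differ from ML when the transition/transversion ratio
is far from 1. Site counting enumerates mutation fates per codon; mutations
to stop codons are excluded from the fate space and the synonymous fraction
rescaled to 3 sites per codon, so $S + N = 3 n_{\text{codons}}$ exactly and
the site space matches the mutation space in which coding sequences actually
evolve (stop-creating changes are purged by selection — and the simulator
never proposes them, so any other convention would bias $\omega$ at
neutrality). Differences average all shortest pathways with equal weight,
skipping pathways through stops unless all are blocked. Proportions are
Jukes–Cantor corrected; $p \ge 3/4$ and $dS = 0$ are flagged rather than
silently dropped. The read-based variant pools codon comparisons across all
reads covering a reference codon at depth ≥ 4, without attempting haplotype
phasing — a reconstruction of the cited read-level methodology, which is not
described in enough detail to copy.

### Repeat discovery

Reads overlap when an ungapped alignment at the best shared-k-mer diagonal
spans ≥ 40% of the shorter read at ≥ 80% identity (the published clustering
thresholds; "40% of the length" is read as 40% of the shorter read).
Clusters are connected components; an optional degree-core filter
(`min_degree_factor`) drops reads whose overlap degree is below a multiple
of the median before taking components — a read's degree grows with local
copy number, so this separates repeat cores from the single-copy flank
paths that would otherwise conflate neighbouring elements. Each cluster gets
a greedy consensus: backbone at the best-connected read, extension by the
longest overhang among well-anchored overhanging reads (≥ 40 aligned bases
at ≥ 90%, with up to 2 bp of terminal consensus error overwritable so one
bad end base cannot stall extension), then a per-position majority-vote
polish and an ends-only trim back to positions with both supported depth
and ≥ 80% vote agreement — beyond a repeat's boundary the copies' distinct
flanks disagree, so agreement collapses exactly at the element edge.
Clusters whose consensi align at the 40%/80% thresholds, or that carry the
same marker annotation, are merged (fragments of one element recovered
separately); merging is idempotent. Validation requires metagenome coverage
of the consensus ≥ 8×, and validated consensi are traced onto each genome
by merging nearby ≥ 97%-identity local segments into loci that must jointly
cover ≥ 80% of the consensus — merging matters because a 1–2 bp consensus
indel splits an ungapped alignment into adjacent diagonal pieces.
A repetitive flag marks components whose read density (read bases per
consensus base) exceeds `repeat_depth_factor = 3` times the median — the
published criterion separating repetitive from single-copy clusters is
unstated, so the factor is a knob.

## The simulator: what it emulates and what it does not

`simulate_ancestor()` builds a genome whose intergenic background comes from
one genome-wide order-3 Markov model (context-biased with multiplicative
noise, `context_sd = 1.2`) and whose genes are drawn from a GC-matched,
strongly biased codon usage (`jitter = 1.0`). Order 3 matters: tetra
z-scores measure exactly the 4-mer structure that 3-mer counts cannot
explain, so any lower-order background would carry no signature at all. The
bias strengths are chosen once so that desk-scale sequences reproduce the
compositional regimes the method relies on in real genomes — descendants at
2% divergence correlate at $r \ge 0.99$, a 40%-GC donor island correlates
far below the 0.9 binning cutoff, and scaffold-sized self-contigs bin at
$R^2 \ge 0.9$. Realized GC is pinned to the target by adjusting intergenic
bases only. Each planted gene carries an adjacent in-frame upstream stop, so
the ORF caller can recover exact coordinates; that guard is a testing
convenience, not a claim about real gene starts.

`evolve_descendant()` applies i.i.d. per-site substitutions — the simplest
model that realizes a target ANI, justified because the inference uses
identity thresholds, not model-based distances — and inserts islands
(independent Markov composition and donor codon usage, so both the
recruitment and the composition detectors fire) and near-identical
transposon copies (0.2% per-copy mutation) at intergenic points kept
≥ 400 bp apart, so that insertion junctions are resolvable at short-read
length. Expected pairwise ANI of two descendants at rate $r$ is
$100\,(1-r)^2$; the default $r = 0.01$ puts the pair at ≈ 98%, the genetic
subspecies regime. `simulate_metagenome()` draws reads multinomially by
abundance with i.i.d. substitution errors; headers carry ground-truth labels
that only evaluation code may read. `simulate_codon_pairs()` evolves two
lineages from a uniform-codon root, rejecting stop-creating proposals and
accepting nonsynonymous changes with relative probability $\omega$.

Not modeled: indels and rearrangements outside planted insertions, rate
heterogeneity, platform-specific error profiles (e.g. flow-space
homopolymer errors), GC-coverage bias, and within-population diversity
beyond a single clonal population genome. Passing tests therefore
demonstrate that the *inference machinery* recovers planted structure under
clean conditions; they do not certify performance on real data with
assembly artefacts, strain mixtures or uneven coverage.

### Desk-scale study conditions

The default pipeline configuration is the desk-scale analogue of the
original study: a 100-kb ancestor with 80 genes at 63% GC, two descendants
at 1% substitution each, three islands (12/18/25 kb, GC 0.38–0.42) on A and
two on B, two marker-carrying transposons (3 and 2 copies), and a
50,000-read metagenome (150 bp, 1% error) in which a descendant-like
population at 20% abundance yields ~12× coverage over a Markov background
community. The real study had the population at under 1% of 20 M reads with
the same ~8× effective coverage; at 50 k reads those two numbers cannot both
hold, and the coverage regime is what the thresholds act on, so coverage is
preserved and abundance scaled up (the abundance arithmetic itself is
unit-tested separately at realistic 1% minority fractions). Problem sizes
throughout — 100–150 kb genomes, 50 k reads, 100 dN/dS replicates — are the
package's chosen defaults for a complete run in minutes on one CPU.

The repeat-recovery scenario plants 8 distinct marker-carrying elements
(0.9–1.15 kb, 3 copies each) in a 150-kb genome, clusters 5× genome reads
with the degree-core filter, and validates against a 12× population
metagenome — the synthetic counterpart of recovering a fixed number of
complete transposase clusters and tracing them back at 97% identity.

## Numerical and degenerate-input choices

* Alignment identity = matches / aligned columns; the aligner is ungapped
  with local (maximal-subarray) trimming, so "gaps count as mismatches" is
  moot within a hit and small indels surface as split hits, which locus
  tracing re-merges.
* z-score denominator zero ⇒ z = 0; all-N input to `gc_content()` is an
  error; empty gene lists, empty tracks and empty graphs return typed empty
  results rather than failing.
* Ties in recruitment are broken deterministically (most matches, leftmost
  coordinate, lexicographic replicon id), so results are invariant to read
  order.
* All simulator entry points take a `seed` and run on a private RNG stream,
  restoring the caller's state; fixed seeds give byte-identical FASTA/FASTQ.
* `evaluate()` scores gene verdicts only for gene ids present in the truth
  table; it errors on a wholesale id mismatch instead of silently scoring
  nothing.

## Interfaces

Every stage is an exported R function and the pipeline is
`run_pipeline(default_config(seed))`; stage outputs are written as
FASTA/FASTQ (via Biostrings), GFF3 (1-based, inclusive), BED-style 0-based
half-open TSVs and a JSON checksum manifest when an output directory is
given. The package's command-line surface is `scripts/acceptance.R`, a thin
Rscript over these functions; R users are the intended audience, so no
separate shell tool is shipped.

## Known limitations

* The ungapped aligner underestimates identity across indel-rich divergence;
  at the ≤ 2% substitution-only regime the simulator produces, this is
  exact, but real diverged pairs with indels would lose alignable fraction.
* Tetra binning at the synthetic signal strength needs scaffold-sized
  contigs (≥ ~20–30 kb) to clear $R^2 \ge 0.9$; short-contig binning recall
  is intentionally sacrificed to the published, conservative cutoff.
* NG86 differs from ML codon models when transition/transversion bias is
  strong; read-based dN/dS pools substitutions without phasing and is a
  per-gene screen, not an estimator of population parameters.
* The repeat consensus builder is a greedy single-path assembler; elements
  sharing long internal repeats with each other would be merged or split
  rather than resolved.
* With the degree-core filter off and coverage high, connected components
  conflate repeats with their single-copy flanks; the filter is the
  supported way to run repeat discovery at ≥ 4–5× read depth.
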