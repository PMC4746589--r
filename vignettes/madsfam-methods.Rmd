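---
title: "madsfam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{madsfam: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind each
stage: the models used, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where the underlying workflow left a choice open. Nothing stated here
goes beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## Family mining

**Model.** Family membership is detected with a log-odds position-specific
scoring matrix (PSSM) built from a seed alignment of the ~58-residue
MADS domain:

$$S(i,a) = \log_2 \frac{(c_{ia} + \kappa b_a)/(n + \kappa)}{b_a},$$

with counts $c_{ia}$, $n$ sequences, pseudocount mass $\kappa = 1$ and
background $b_a$ (uniform 1/20 by default — the simplest null that still
separates planted domains at the divergences of interest). A full
match/insert/delete profile HMM is deliberately not implemented: the
pipeline treats domain search as a thresholded detector, and the PSSM
preserves that contract (best-window score, e-value cutoff) at desk scale
while remaining fully testable against closed forms. Viterbi-style profile
HMMs are an extension point, not a requirement.

**Significance.** E-values are empirical: each protein is shuffled
`n_decoys = 200` times and
$e = (1 + \#\{\text{decoy windows} \ge S\}) / (1 + \#\text{decoy windows})$.
For 300-residue proteins this resolves e-values down to about $2\cdot
10^{-5}$, comfortably below the `1e-4` retention threshold. Because 200
decoys resolve the threshold only coarsely, confirmation additionally
requires a bit-score floor: 0.25 × the weakest seed-sequence self-score.
The factor was chosen from the score geometry of the model itself:
background and decoy best windows score strongly negative under the
log-odds model (around −100 bits for uniform-background proteins), while
genuine domain copies stay above roughly +70 bits out to 20–25% divergence,
so a floor near +55 bits sits in the wide empty region between the two
populations. Two independent scan rounds (fresh decoy seeds) mirror the
usual search-then-confirm domain annotation design; the confirmed set is by
construction a subset of the first-stage hits.

**Orthology.** Local alignment is Smith–Waterman with affine gaps via
Biostrings (`BLOSUM62`, gap open 10, extend 4; a gap of length $k$ costs
$10 + 4k$). Percent similarity counts substitution-matrix-positive matched
columns over all alignment columns — the BLASTP "positives" convention,
which is what a ">50% similarity" report field means — and query coverage
is the aligned query span over query length. The "regular" flag is strict
(`> 50`, not `≥`), so a pair at exactly 50.0 is non-regular. Ties between
equally scoring subjects break on lexicographic subject id.

**Naming.** Members are sorted by (chromosome order, start coordinate) and
named `<prefix>001..N`; unlocated members are appended in input order.
Naming is a bijection and invariant under input permutation.

## Genome organization

**Homolog pairs.** All-vs-all alignment is made tractable with a
shared-5-mer prefilter (≥ 3 distinct shared words), the standard
seed-and-extend heuristic: unrelated 200–400-residue random proteins share
a given 5-mer with probability $\approx 20^{-5}$, so essentially only true
homologs are aligned. Significance uses a Karlin–Altschul-style e-value
$E = Kmn e^{-\lambda S}$ with gapped-BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$); the inclusion threshold `1e-10` and the
5-subjects-per-query cap are kept from the conventional all-vs-all setup.

**Collinearity.** Anchors (homolog pairs mapped to gene-order ranks) are
chained per chromosome pair by dynamic programming: +1 per anchor, penalty
`0.01` per skipped rank, per-step gap ≤ `max_gap = 25` intervening ranks,
both orientations, blocks reported at ≥ `min_block = 5` anchors, greedy
best-chain extraction. Rank gaps (not base pairs) drive chaining — robust
to gene-length variation. Ties in the DP break deterministically on the
earliest anchor in (rank~a~, rank~b~) sort order. The chaining is verified
against exhaustive enumeration of all valid chains for anchor sets of
size ≤ 8.

**Duplication modes.** Precedence segmental (block anchor) > tandem
(homolog at adjacent rank) > proximal (homolog within
`proximal_window = 20` ranks) > dispersed > singleton, mirroring the
standard duplicate-gene-classifier convention so the four percentages are
well defined; modes partition the family exactly.

**Clusters.** The clustering criterion is not standardized anywhere, so the
package uses a common tandem-array convention: consecutive family genes
join a cluster when separated by ≤ 5 intervening genes *and* ≤ 250 kb; both
knobs are arguments. Cluster detection is invariant under reversing a
chromosome's coordinate direction (ranks recomputed).

## Phylogenetics

**Distances.** p-distance or Poisson correction $d = -\ln(1-p)$ with
pairwise deletion of gap columns. Poisson-corrected protein distance is the
default, matching the common default of desktop NJ tools; saturation
($p = 1$) raises an error naming the offending pair rather than returning
infinity.

**Neighbor joining** is implemented from scratch (Saitou–Nei
Q-minimization with the standard branch-length formulas) so that an
independent implementation (`ape::nj`) can serve as a second-opinion oracle
in the tests — the two are never collapsed into one code path. Ties in Q
break on the smallest (i, j) pair in cluster-creation order. Negative
estimated branch lengths are clamped to zero with the deficit transferred
to the sibling branch of the same join (their sum, the joined distance, is
preserved); the final three-point resolution clamps at zero. On additive
inputs the tree reproduces every pairwise distance to < 1e-9 (floating
point only).

**Bootstrap.** Columns are resampled with replacement; support for each
internal edge of the original tree is the percentage of replicate trees
containing its bipartition (supports attach to the original tree;
majority-rule consensus is out of scope). Taxa are canonically sorted
before resampling, making supports invariant to input order under a fixed
seed.

**Clade calls.** Each query takes the label of the smallest edge-bounded
subtree containing it and ≥ 1 reference, provided those references are
label-pure; mixed references leave the query unassigned. Functional
DAM/FLC-like calls additionally require a functional anchor inside that
subtree and the assigned label to equal the MIKC^C^ subfamily (functional
calls are a MIKC^C^ phenomenon). References always receive their own label
(a pendant edge bounds the singleton subtree). Anchor sets are user
supplied: the exact reference panels of any given study are not
reconstructable in general, so they are data, not code.

## Expression

`log2(FPKM + 1)` is the working transform (pseudocount 1 keeps zeros at
zero); the expressed call is FPKM ≥ 1 in at least one sample, boundary
inclusive — the threshold is an argument because "very low expression" has
no canonical definition. Reciprocity of a repressor/activator pair is the
Pearson (or Spearman) correlation of the transformed profiles over the
10-stage dormant-bud-to-full-bloom window (3 apical bud + 5 spur bud + 2
early flower stages), flagged at ≤ −0.5; the window and cutoff are
arguments since reciprocity is otherwise qualitative. ΔΔCt fold changes are
the exact closed form $2^{-\Delta\Delta Ct}$ with a reference-gene
normalization per sample; FPKM–qPCR concordance is a Pearson correlation
over matched log2 fold changes.

## Regulatory analysis

Upstream regions are `[start − w, start)` for + strand genes and the
reverse complement of `(end, end + w]` for − strand genes (0-based
half-open genome coordinates; GFF3 1-based inclusive is converted on
ingestion, BED is native), truncated and flagged at chromosome edges.
Windows: 2000 bp for target search, 1500 bp for LTRE-style element
counting.

Motif scanning is exact degenerate IUPAC matching at every offset;
overlapping occurrences all count; reverse-strand hits are found by
scanning the pattern's reverse complement and reported in forward
coordinates. Both strands are scanned by default (a flag disables it,
since single-strand conventions exist). The scanner is deliberately
hand-written — degenerate scanning is one of the primitives this package
exists to make transparent — and is property-tested against a naive
all-offsets oracle.

Phase filtering retains a pattern iff it matches wholly inside ≥ 1 ChIP
peak (the peak is the evidence unit; boundary-spanning matches do not
count, which falls out of scanning the extracted peak sequences). A target
is any gene with ≥ 1 retained-motif hit in its upstream region; "unique
motifs present" counts distinct patterns with ≥ 1 hit anywhere in the
region set. Default LTRE patterns are the CCGAC core and the RCCGAC
CBF/DRE variant; the pattern set is an argument because element names, not
strings, are what surveys typically report.

The target network keeps every interactome edge with ≥ 1 endpoint in the
mapped seed set, merges duplicate edges, drops self-loops and removes
isolated seeds. Hubs are the top-k nodes of the largest connected
component by degree (ties on node id), k = 5 by default, with the hub
fraction of the component reported; a quantile rule can be emulated by
choosing k from the component size. The degree distribution gets a
discrete maximum-likelihood power-law fit at `xmin = 1` (zeta
normalization via `pracma::zeta`, optimized to 1e-10 tolerance and
verified against staged grid search to 1e-6), a Kolmogorov–Smirnov
distance on the discrete support, and a log–log least-squares slope/R² as
a purely descriptive secondary summary. GO enrichment is the upper-tail
hypergeometric test with Benjamini–Hochberg correction across tested
terms, significant at FDR < 0.05; annotations are taken as a flat table
(no ontology-graph propagation).

## The synthetic-data generators

The generators define the study conditions under which every stage is
verified; their defaults are fixed once and are not tuned per test.

- `sim_proteome`: 58-residue consensus domain planted once per family
  protein at per-site substitution divergence (default 0.1; recovery is
  exercised at 0.15), uniform-background proteins of length 300, plus a
  10-sequence seed alignment at 5% divergence for profile building.
- `sim_genome_layout`: sequential non-overlapping gene models with random
  lengths (0.6–3 kb) and intergenic gaps (0.5–2 kb); events place
  near-identical protein pairs (2% divergence) at adjacent ranks (tandem),
  within 20 ranks (proximal), as ≥ 5 consecutive cross-chromosome pairs
  (segmental), or at unrelated positions (dispersed). Planted events are
  spaced for identifiability: intra-chromosome events sit ≥ 28 ranks apart
  and dispersed pairs never share a chromosome pair with a segmental
  block — otherwise unrelated planted pairs can legitimately chain into a
  collinear block under the 25-rank gap rule and the planted labels stop
  being recoverable even in principle. Infeasible placements raise an
  error; nothing is silently truncated.
- `sim_alignment`: Poisson substitution events per site per branch
  (uniform replacement among the other residues), gap-free, column count
  equal to the root length. Indels are intentionally not simulated.
- `sim_expression`: the 3+5+6+7 phenological stage design; repressor and
  activator archetypes are exact mirrored linear ramps (8 → 0 and 0 → 8
  log2 units) across the bud-to-bloom window, so a noise-free pair has
  correlation exactly −1; multiplicative log-normal noise (σ = 0.2 by
  default) models heavy-tailed FPKM dispersion; silent genes stay below
  0.9 × the expressed threshold in every sample by construction.
- `sim_promoters`: exact planted motif counts on random strands with all
  accidental occurrences of any library pattern removed by iterative
  rejection (mutating free background bases, redrawing realizations when a
  hit falls wholly inside a planted window). This requires the library to
  contain no strand-symmetric (reverse-complement palindromic) pattern and
  no pattern nested in another's realizations; the shipped 8-pattern
  default library was chosen to satisfy both, which is why its CArG-like
  entry is `CCWWWWWWAG` rather than the palindromic canonical CArG box.
- `sim_interactome`: node degrees drawn i.i.d. from a zeta distribution
  with the target exponent and realized by a configuration model
  (`igraph::sample_degseq`) followed by simplification. Linear
  preferential attachment was rejected because it fixes the exponent at 3
  regardless of parameters; the configuration route makes "generate at
  exponent α, recover α by MLE" a meaningful contract. The top-degree
  nodes are designated hubs; one GO term annotates 60% of a designated
  target set against a 5% background rate (fraction 0 disables the
  signal for type-I studies).

What the generators do *not* emulate: sequencing reads and library-size
effects, assembly artifacts, indels, genome-scale gene counts,
position-specific motif instances (patterns are consensus strings), or the
ontology DAG. Passing tests therefore demonstrate algorithmic correctness
and recovery of planted signal under the stated noise models — not
robustness to every artifact of real survey data.

## Numerical choices and degenerate inputs

- Branch lengths are serialized at 17 significant digits; additive
  recovery is asserted at 1e-9.
- Distance saturation, ragged alignments, unknown residues/IUPAC symbols,
  negative FPKM, constant expression profiles, gene sets outside the
  universe, empty interactomes and k larger than the component all raise
  informative errors rather than propagating NA.
- Proteins shorter than the profile yield no hit (not an error).
- The power-law fit refuses degenerate (single-valued) degree
  distributions and fewer than 10 usable nodes.
- Deterministic tie-breaks throughout: lexicographic subject ids
  (orthologs), smallest index pair (NJ), earliest-sorted anchor (chaining),
  node id (hubs).

## Problem sizes

The verification suite runs at sizes chosen to make every property
measurable in minutes on one core: 200 random trees of ≤ 8 taxa and 50
random 7-taxon matrices for NJ; 200 bootstrap replicates on a 10-taxon
two-clade alignment; a 550-protein proteome with 200 decoys per protein
for domain mining; a 10 × 80-gene genome with 40 planted events; 1000
random cases each for the chaining and motif-scan oracles; 1000 null
simulations for enrichment type-I control; twenty 1000-node interactomes
for exponent recovery. `scripts/acceptance.R` reproduces all of these from
a single `--seed`.

## Known limitations

- The PSSM detector does not model insertions/deletions within the domain;
  at divergences well beyond ~25% its recall degrades before a true
  profile HMM's would.
- Karlin–Altschul constants are used as published for gapped BLOSUM62
  scoring rather than re-estimated for the exact gap parameters; e-values
  are therefore calibrated up to a monotone transform, which the 1e-10
  threshold absorbs at the score separations involved.
- Bootstrap supports attach to the original topology only; no consensus
  tree is built.
- The clade-assignment rule is purely topological; it does not use branch
  lengths or supports to qualify calls.
- `filter_phase_motifs` treats each peak as a bag of sequence; motif
  position within the peak (e.g. summit proximity) is ignored.
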