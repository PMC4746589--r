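# madsfam

Desk-scale, fully verifiable re-implementation of the genome-wide MADS-box
transcription-factor family workflow used in apple (*Malus × domestica*)
phenology studies: family mining, genome organization, phylogeny,
stage-structured expression profiling, and regulatory-network analysis of
SVP/DAM target predictions.

## Who this is for

Plant comparative genomicists who want the individual computational steps of
a classic TF-family survey — normally a chain of external black boxes
(hmmsearch/PfamScan, BLASTP, MCScanX, MEGA, pattern matchers, network tools)
— as small, tested, scriptable R functions whose behavior can be verified
against planted ground truth. Every input the pipeline consumes can be
simulated with known truth, so each stage is testable end to end without any
genome download.

## What the package computes

- **Family mining** (`build_profile`, `scan_profile`, `confirm_members`,
  `call_orthologs`, `assign_names`): a log-odds PSSM
  `S(i,a) = log2(((c_ia + κ·b_a)/(n + κ))/b_a)` built from a seed alignment;
  best-window scanning with empirical e-values from shuffled decoys,
  `e = (1 + #{decoy windows ≥ S}) / (1 + #decoy windows)`, thresholded at
  `e ≤ 1e-4` over two independent confirmation rounds; best-hit ortholog
  calls with the strict >50% similarity / >50% query-coverage "regular"
  rule; positional `MdMADS001..N` naming along chromosomes.
- **Genome organization** (`build_homolog_pairs`, `chain_collinear`,
  `classify_duplications`, `detect_clusters`): homolog pairs at
  `E ≤ 1e-10` (≤ 5 subjects/query); dynamic-programming chaining of anchors
  into collinear blocks (≥ 5 anchors, per-step rank gap ≤ 25); duplication
  modes under the precedence segmental > tandem > proximal > dispersed >
  singleton; gene clusters (≤ 5 intervening genes and ≤ 250 kb).
- **Phylogenetics** (`aln_distance`, `nj_tree`, `bootstrap_support`,
  `assign_clades`): Poisson-corrected protein distances `d = −ln(1 − p)`;
  Saitou–Nei neighbor joining written from scratch (negative branch
  lengths clamped with the deficit moved to the sibling branch); bootstrap
  bipartition support from column resampling; subfamily and DAM/FLC-like
  calls by smallest label-pure reference-anchored subtree.
- **Expression** (`log_transform`, `call_expressed`, `reciprocal_score`,
  `ddct_fold`, `concordance`): `log2(FPKM + 1)` transform; expressed ⇔
  FPKM ≥ 1 in ≥ 1 sample; repressor/activator reciprocity as Pearson
  correlation ≤ −0.5 over the 10-stage dormant-bud→full-bloom window;
  qPCR fold changes `2^(−ΔΔCt)`.
- **Regulatory** (`extract_upstream`, `scan_motifs`, `filter_phase_motifs`,
  `predict_targets`, `build_target_network`, `degree_powerlaw`,
  `find_hubs`, `go_enrichment`): strand-aware IUPAC motif scanning; ChIP
  peak phase filtering (match must lie wholly inside a peak); 2-kb upstream
  target prediction; interactome sub-network construction (single edges, no
  self-loops, isolated seeds dropped); discrete power-law MLE with KS
  distance; top-k hubs of the largest component; upper-tail hypergeometric
  GO enrichment with Benjamini–Hochberg FDR.
- **Synthetic data** (`sim_proteome`, `sim_genome_layout`, `sim_alignment`,
  `sim_expression`, `sim_promoters`, `sim_interactome`,
  `validate_simulation`): generators for every input above with
  machine-readable ground truth (planted domains, duplication events,
  trees, expression archetypes, exact motif counts, hubs, one enriched GO
  term).

## Worked example

```r
library(madsfam)

# simulate a proteome with 50 planted MADS-like domains among 500 background
pr   <- sim_proteome(n_family = 50, n_background = 500,
                     domain_divergence = 0.15, seed = 106)
prof <- build_profile(pr$seed_alignment)
conf <- confirm_members(pr$proteins, prof, n_decoys = 200)
fam  <- names(pr$truth$family_membership)[pr$truth$family_membership]
c(recall = length(intersect(conf, fam)) / length(fam),
  fdr    = length(setdiff(conf, fam)) / max(1, length(conf)))
#> recall    fdr
#>   0.98      0

# promoter LTRE counting: plant 2 and 7 CCGAC copies in 1.5-kb promoters
lib <- default_motif_library()
cnt <- matrix(0L, 2, nrow(lib), dimnames = list(c("gA", "gB"), lib$id))
cnt["gA", "LTRE"] <- 2L; cnt["gB", "LTRE"] <- 7L
pp <- sim_promoters(region_length = 1500, planted_counts = cnt,
                    peak_subset = "LTRE", seed = 110)
count_motifs(pp$upstream, c(LTRE = "CCGAC"))[, "LTRE"]
#> gA gB
#>  2  7
```

The first block reports the domain-mining operating point on a synthetic
proteome at 15% domain divergence: 49 of 50 planted members confirmed
(recall 0.98) with no false positives. The second recovers planted
low-temperature-responsive elements exactly — the same scan used to count
LTREs upstream of dormancy-associated genes.

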