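---
title: "Mining hgcAB mercury-methylation markers from assembled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hgcAB mercury-methylation markers from assembled metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcminer)
```

## The problem

Methylation of inorganic mercury to neurotoxic methylmercury is carried out
by anaerobic bacteria and archaea carrying the *hgcA* (corrinoid protein)
and *hgcB* (ferredoxin) genes, which usually sit side by side as a small
operon. In an assembled metagenome the evidence for a methylator is
therefore (i) a protein similar to known HgcA/HgcB, (ii) the conserved
degenerate motifs — the cap-helix motif `NVWCA(A/G/S)GK` in HgcA and the
ferredoxin motif `C(M/I)EC(G/S)(A/G)C` in HgcB — and (iii) the two genes
co-located on one contig. `hgcminer` turns that screening protocol for
brackish water-column surveys into tested, reusable functions: candidate
screening, motif verification, contig-aware locus classification,
redox-stratified relative abundance, filter-fraction enrichment,
rarefaction, and distance-based taxonomic placement.

## Screening and verification

The decisive filter in this protocol is the motif check; the screen only
needs to reduce millions of predicted proteins to a tractable candidate
list. Two screen sources are supported:

* **External domain table** (`screen_source = "domain_table"`): the
  per-domain tabular output of a profile-HMM search run elsewhere. Rows
  with full-sequence E-value at or below `1e-3` are kept; the boundary is
  inclusive because the protocol defines significance as *E* ≤ 10⁻³.
* **Internal profile screen**: a position-specific log-odds profile built
  from a reference alignment (`build_profile()`), scored by the best
  ungapped sliding window. This is deliberately *not* a full profile HMM
  with insert/delete states — at desk scale the screen only has to
  separate profile-similar sequences from random background, and the
  ungapped scorer has closed-form, testable behaviour. Columns with more
  than 50% gaps are dropped; counts are Laplace-smoothed with pseudocount
  α = 0.1 per residue; scores are log₂ odds against a uniform background.
  The default acceptance threshold is 0.5 bits per profile column: true
  homologs score ≈ 3–4 bits/column, random-composition proteins score
  negative, so the threshold sits in a wide margin between the two modes
  rather than on a fitted boundary.

`verify_candidates()` then keeps exactly the candidates whose sequence
contains the target's degenerate motif. `X` residues match nothing
(ambiguity never verifies a motif), and when several windows match, the
leftmost is recorded, for determinism.

## Locus classification

"Side by side" is operationalised as: adjacent gene ranks along the contig
(`max_gene_gap = 1`), intergenic distance at most 500 bp, equal strands.
The protocol never quantifies adjacency, so these are explicit, config-exposed
choices; 500 bp is a generous bound for intergenic spacers within
prokaryotic operons. Pairing is greedy by ascending intergenic distance
with each gene used at most once — this resolves one hgcA flanked by two
hgcB candidates deterministically and matches operon biology. Remaining
hgcA genes become `hgcA_only` loci with an edge-truncation flag (an
unpaired hgcA at a contig extremity most plausibly lost its hgcB to the
assembly break, which is why truncation is worth recording), and remaining
hgcB genes become `hgcB_only` loci with a centrality flag. hgcB orientation
relative to hgcA is recorded but never used as a pairing filter, since the
protocol does not constrain it. Loci are named ordinally — paired clusters
first, then lone hgcA, then lone hgcB, each sorted by contig and position —
so naming is invariant to input order.

## Relative abundance, redox zones, fractions, rarefaction

The abundance statistic is deliberately plain: reads mapped to a locus's
member genes divided by the sample's total annotated reads, expressed as a
percentage and displayed in 1 × 10⁻³ % units. No gene-length normalisation
is applied by default, so the statistic reproduces the survey convention
exactly; a per-kilobase mode exists for sensitivity analysis only.

Samples are classified by oxygen: normoxic when detected O₂ ≥ 2 mL L⁻¹
(boundary inclusive), hypoxic when detected but lower, anoxic when no O₂
was detected. Non-detection is an explicit boolean column and never
inferred from a numeric 0.0 — detection limits differ between instruments,
and "no detectable O₂" is a different claim from "O₂ = 0". Zone summaries
report n, mean, sd (n − 1 denominator; the convention is not stated by the
survey protocol, so the sample sd was chosen), min and max; single-sample
zones report sd 0 with a degenerate-n flag.

Filter-fraction enrichment compares particle-associated samples (3 µm
capture, no pre-filter) with free-living samples (0.2 µm capture after a
3 µm pre-filter) matched exactly on station, date and depth. A zero
free-living abundance flags the ratio undefined rather than infinite.

Rarefaction subsamples the gene count vector without replacement (a
multivariate hypergeometric draw). Raw reads are unavailable at this layer,
but the detection expectation is identical: the probability a gene with
*k* of *N* reads is missed at depth *d* is C(N−k, d)/C(N, d), and the test
suite checks the simulated curves against this closed form.

## Taxonomic placement

The reference workflow for taxonomy is an externally computed
maximum-likelihood tree; `assign_taxonomy()` accepts any `ape::phylo`, so
that route stays open via `ape::read.tree()`. The built-in route is
self-contained and testable instead: pairwise global alignment (BLOSUM62,
affine gap open 10 / extend 1) giving Poisson-corrected distances
d = −ln(1 − p) capped at 5, then neighbor joining with lexicographic
tie-breaks and negative-branch clamping (the deficit moves to the sibling,
preserving the pair's path length). On additive matrices NJ recovers the
generating topology and path lengths to machine precision, which the suite
checks against an exhaustive-topology oracle. Bootstrap support, when
requested, resamples alignment columns with replacement under a fixed
seed.

Assignment: the nearest reference by patristic distance; a lineage built
from the smallest query-containing split holding at least two references,
keeping ranks from domain downward while ≥ 75% of those references agree
(truncated at the first disagreement, `unidentified` when even the domain
disagrees); and a long-branch caution flag when the query's terminal
branch exceeds the 0.95 quantile of reference terminal branches, in which
case the lineage is suffixed `-like` — operationalising the qualitative
"related, but on a very long branch" caveat. A query at numerically zero
distance from a reference simply inherits that reference's full lineage;
clade consensus would pointlessly truncate an exact match. Lone hgcA loci
are placed against hgcA references, lone hgcB against hgcB references,
paired clusters against concatenated hgcA+hgcB references, mirroring the
separate reference pools a practitioner would use.

## The synthetic survey generator

`build_locus_catalog()` emits a deterministic catalog reproducing the
canonical locus census of the survey this package emulates: 9 paired
same-strand clusters (two carrying NVWCASGK + CIECGAC, one NVWCAAGK +
CIECGAC, the rest the common NVWCAAGK + CMECGAC), 13 lone edge-truncated
hgcA genes, 3 lone central hgcB genes, plus 100 profile-similar
motif-broken decoys and 100 random background proteins. Decoys differ from
true positives by exactly one broken motif position plus background
mutation, so they pass the profile screen and must be removed by
verification — the hardest case for the pipeline. Mutation never touches
the motif columns of true positives, which keeps ground truth well-defined:
verification is exactly the motif test.

`simulate_survey()` adds sample metadata and counts. Defaults are the
emulated survey's conditions: 65 normoxic / 9 hypoxic / 7 anoxic
free-living samples; expected summed hgc abundance per zone of 0.05, 1.0
and 2.1 × 10⁻³ % (the published zone means, with "< 0.1" for normoxic
taken as 0.05); six matched particle/free-living pairs; a particle
enrichment factor of 5 (the reported contrasts span 3- to 14-fold; 5 sits
near their geometric middle); negative-binomial counts with size 5
(metagenomic counts are overdispersed; Poisson would understate replicate
variance); and 10⁶ annotated reads per sample — a desk-scale stand-in for
the ~13 million of a real survey that keeps expected hgc counts (~21 reads
per anoxic sample) realistic while the whole survey simulates in under a
second. Counts are drawn so the summed abundance matches the zone effect
in expectation; O₂ values are drawn consistently with each sample's zone.

What the generator does *not* emulate: real profile-HMM score
distributions, sequencing error, chimeric contigs, strain-level variation,
compositional correlations between taxa, and gene-length variation within
a role. Passing recovery tests therefore demonstrates that the pipeline's
logic is correct under its stated statistical model, not that the screen's
thresholds are optimal for any particular real survey — for real data the
domain-table route with a curated HMM library is the recommended screen.

## Problem sizes and numerical choices

The test suite runs the full fixture pipeline (≈ 270 genes), 100 seeded
survey replicates at 20 samples per zone for zone-ordering recovery, one
50-pair survey for enrichment recovery, 200 seeded placement trials, and
1000-sequence motif-scan property checks; these sizes give stable pass/fail
behaviour at conventional Monte-Carlo error. Distances are capped at
d = 5 (the Poisson correction diverges as p → 1); NJ ties break
lexicographically; profile scoring of sequences shorter than the profile
slides the sequence along the profile and normalises by overlap length, so
edge-truncated genes are screened fairly.

## Worked example

```{r example, eval = FALSE}
library(hgcminer)

catalog <- build_locus_catalog()        # or load_gene_catalog(faa, coords)
verified <- verify_candidates(
  screen_candidates(catalog, profiles = default_profiles()), catalog)
loci <- call_loci(verified, catalog)
summarize_loci(loci)

sv <- simulate_survey(survey_config(seed = 1))
report <- run_pipeline(sv$catalog, sv$counts, sv$metadata)
report$zone_summary
```

## Known limitations

* The internal screen is ungapped; distant homologs with long insertions
  relative to the profile may be missed. Use the domain-table route for
  sensitive screening.
* NJ placement is a simplification of maximum-likelihood phylogenetics;
  the `-like` flag and consensus truncation are guards, not substitutes,
  for a curated tree.
* Fraction pairing is exact on (station, date, depth); near-miss depths
  are not matched.
* Fused single-ORF hgcAB architectures and cross-contig scaffolding are
  out of scope.
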