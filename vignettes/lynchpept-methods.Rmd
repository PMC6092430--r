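---
title: "Methods: from pedigree genotypes to neoepitopes and immune scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pedigree genotypes to neoepitopes and immune scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchpept)
```

# Overview

`lynchpept` models the desk analysis of a hereditary
mismatch-repair-deficient (Lynch syndrome) colorectal tumour: identify
the causal germline variant by co-segregation, enumerate
mutation-derived peptides, pass them through an HLA- and TCR-binding
filter cascade, weigh RNA-level evidence, and score the tumour's immune
microenvironment. This vignette records the models, the tunable
parameters, and the design decisions taken where the analysis admitted
more than one defensible choice.

# Co-segregation

A variant co-segregates with disease when it is carrier-state in every
affected subject and absent from the unaffected. `cosegregating_variants`
applies this rule over a long-format genotype panel and ranks survivors
pathogenic-first, then by consequence severity (frameshift > nonsense >
missense), with the gene symbol as a deterministic alphabetical
tie-break.

Hereditary cancer syndromes show incomplete penetrance: a middle-aged
unaffected carrier is entirely plausible and, under strict exclusivity,
vetoes the true causal variant. We expose this as
`penetrance_allowance` (default 0): the number of unaffected carriers
tolerated before a variant is excluded. The default reproduces the
strict informative-subset comparison (two affected carriers, two
unaffected non-carriers); raising it to 1 admits pedigrees with one
escapee. `penetrance_report` cross-tabulates carrier state by affection
and names the unaffected carriers so the analyst can judge.

Subjects whose genotypes are all unknown carry no information and are
excluded with a warning; a panel without affected or without unaffected
subjects is a usage error, since exclusivity is undefined.

# Consequence calling and mutant proteins

Variants arrive in VCF style (anchored alleles, 1-based CDS
coordinates). Before classification the edit is reduced to its minimal
form (shared suffix, then prefix, trimmed) and pure indels are
right-aligned per the HGVS 3' rule, which decides which residue counts
as "first changed" in repeat contexts. SNVs are classified by the
translated codon effect (missense / nonsense / synonymous); indels by
net length modulo 3 (frameshift vs in-frame).

`mutant_protein` applies the edit and translates codon-by-codon from
the start, stopping at the first stop codon. For a frameshift the
shifted frame is therefore translated to the novel stop, and the HGVS
string uses `fsTer<n>` notation with the first changed residue counted
as position 1 — `fsTer5` means the stop is the fifth residue of the new
frame (`fsX` in older tables is the same notation). Two degenerate
cases are handled explicitly: a shifted frame that runs off the
transcript without a stop is annotated `fsTer?` and flagged, and a
shifted frame that happens to re-encode the wildtype protein is
reported as `p.=` with no changed residue. One notational note: the CDS
position printed for a deletion in a repeat run can place the first
changed residue one codon away from a naive reading; following the 3'
rule resolves this deterministically, and we do not attempt to force
agreement with any particular printed residue number.

# Peptide pair enumeration

`enumerate_peptide_pairs` emits every k-length window (default k = 9,
the class I epitope length) of the mutant protein that overlaps the
*changed region*, truncated — never padded — at the mutant C-terminus.
For same-length proteins (missense) the changed region is the span of
differing residues, so an interior missense residue yields exactly k
windows, each at Hamming distance 1 from wildtype. For frameshifts the
changed region runs from the first changed residue to the C-terminus.

The wildtype partner of each window is *positional*: the wildtype
residues at the same protein coordinates, or NA where the wildtype
protein is shorter. This means a window fully inside a novel
frameshifted tail is paired with an entirely unrelated wildtype
peptide — which is the behaviour that reproduces published
wildtype/mutant pairs for frameshift neoepitopes, where the "wildtype"
column shows the peptide occupying those coordinates in the normal
protein.

# The binding cascade

Peptide–HLA affinity is scored by a position-specific scoring matrix:
the raw score *s* is the mean of per-position weights in [0, 1], mapped
to the nanomolar scale by the convention `IC50 = 50000^(1−s)` so that a
consensus peptide scores 1 nM and a null peptide 50 000 nM, and IC50 is
strictly decreasing in *s*. This transform is adopted so the
conventional affinity thresholds — 1000 nM for candidate immunogens,
150 nM for strong binders (`scoring_config`) — remain meaningful.
**The scorer is a documented stand-in**: it does not reproduce the
affinities of NetMHC-family tools, and published affinities should be
supplied through the record tables instead (as the shipped case fixture
does).

TCR binding is likewise a stand-in heuristic: a 9-mer is called `High`
when at least 2 of its central residues (positions 4–6, the ones arched
toward the TCR) are bulky/aromatic or charged ({F, W, Y, R, K, H, L,
I}). The rule object is swappable — any function from peptide to
High/Deprioritized can be injected — and whichever rule is in force is
serialized into the run manifest, so no run is ambiguous about how its
calls were made.

The immunogenicity filter keeps records with `tcr_call == "High"` and
IC50 *strictly* below the threshold; it preserves order, is idempotent,
and shrinks monotonically as the threshold tightens. Cascade summaries
report integer percentages with half-up rounding (`floor(100x + 0.5)`),
which matches how such stage percentages are conventionally printed;
note that a true fraction just under a half-percent boundary (e.g.
30.87%) will print as 31 here even where a source table chose to
truncate.

# Expression evidence

"Expressed in tumour" is FPKM ≥ 1, inclusive: below 1 FPKM is the
conventional "low expression" tier, and no finer cut-off is defensible
from bulk RNA-seq alone. `dna_rna_concordance` compares percent
alternate allele depth (`100·alt/(ref+alt)`) across assays; a tumour-DNA
fraction at least 1.8× the blood fraction flags a possible second hit
(the germline heterozygote at ~38% climbing to ~73% after loss of the
wildtype allele — "nearly double" operationalized as a configurable
ratio). RNA fractions above zero but under 5% are tiered "low but
detectable", the pattern of transcripts being actively down-regulated
rather than absent.

The association between mutant allele depth and CTL activation uses
Spearman rank correlation with mid-ranked ties, reported with n (no
p-value below n = 5; with so few informative points the rho itself is
the result). When either axis is constant the correlation is undefined
in the 0/0 sense; we define it as 0, since a constant response carries
no evidence of association in either direction.

# Tumour-microenvironment scoring

Marker genes for eight immune cell types (CD8 T, CD4 T, B, NK,
monocyte, macrophage, neutrophil, Treg) are selected from reference
immune-cell expression profiles by two criteria, which we operationalize
as rank statistics because only their intent — selectivity and
stability — is fixed by the underlying method descriptions:

* **Average Rank Score (ARS)**: per dataset, rank the cell types by the
  gene's expression (descending, mid-ranked ties) and score
  `(C − r)/(C − 1)`; ARS is the mean over datasets. 1 means the gene
  tops its own cell type everywhere; 0 means it always ranks last.
* **Marker Evaluation Score (MES)**: the fraction of datasets in which
  the gene's target type ranks strictly first.

A gene enters a signature when ARS ≥ 0.8 and MES ≥ 0.5 (defaults,
configurable); a gene qualifying for several types goes to its max-ARS
type and is dropped entirely on an exact tie, making signatures
pairwise disjoint by construction (asserted on every `signature_set`).
Signatures are truncated to 25 genes by descending ARS with the gene
name as tie-break. A cell type with no qualifying gene is a hard error
naming the type: silently scoring with an empty signature would be
worse.

The per-sample enrichment score is an ssGSEA of the
integrated-running-sum form: genes sorted by expression (descending,
ties broken by gene name for determinism), rank weight
`r_j = N − j + 1`, and

$$ES = \sum_{i=1}^{N}\left(\frac{\sum_{g\in G,\,pos(g)\le i} r_g^{\alpha}}
{\sum_{g\in G} r_g^{\alpha}} -
\frac{|\{g\notin G : pos(g)\le i\}|}{N-|G|}\right)$$

with α = 0.25 by default (α = 0 gives the unweighted Kolmogorov-style
sum). We use the integrated sum, not the maximum deviation, because the
score should reflect coordinate up-regulation of the whole signature
rather than a single extreme excursion, and no sample-wise
normalization is applied by default since it is meaningless for a
single sample. The implementation is verified against a brute-force
double-loop ECDF evaluation in the test suite, and the permutation loop
uses an algebraically identical closed form (each gene's contribution
summed over the positions it affects) for speed.

Presence calls compare the observed ES with a null of `n_perm` random
same-size gene sets (gene-label permutation), with the add-one
estimator `p = (1 + #(null ≥ ES)) / (n_perm + 1)`; a type is present
when `p < 0.05`. A permutation null is used instead of a fixed score
cut-off because the ES scale depends on N, signature size and α — note
in particular that for α > 0 the null mean is *not* zero (top-weighted
ranks bias random sets positively), so only a calibrated null makes
presence calls comparable across signatures. Only the eight cell types
above are modelled; macrophage polarization states and MDSC subsets are
not, as no defensible marker sets for them are part of this design.

`checkpoint_report` tabulates FPKM for the checkpoint genes (PDCD1,
CD274, CTLA4, HAVCR2, LAG3) and the presentation machinery (TAP1, TAP2,
HLA-A/B/C), flagging values under 1 FPKM and emitting NA rows for genes
missing from the table.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed) and their
defaults are the study conditions the pipeline targets:

* `simulate_family`: 2 affected + 2 unaffected subjects, one planted
  pathogenic frameshift carried by exactly the affected, 6 benign
  missense variants carried by all — the informative MMR-panel
  configuration. An optional unaffected carrier provides the
  reduced-penetrance negative control.
* `simulate_somatic`: 959 variants (a hypermutated MSI-H panel burden)
  with class probabilities 0.69/0.30/0.01 for missense/indel/nonsense
  (renormalized; the published component counts are internally
  inconsistent with their printed total, so proportions — not raw
  counts — are the parameterization). Variants are placed consistently
  on simulated CDSs (a missense draw really does change a codon, an
  indel really does shift the frame). Tumour allele fractions are Beta
  around purity/2 with concentration 40 and purity 0.6, giving the
  realistic 20–40% somatic allele-depth range; sequencing depth is
  Poisson around 200×. Each mutated gene is expressed (FPKM ≥ 1) with
  probability 0.23, the transcript-level expression rate of predicted
  neoantigens.
* `simulate_reference_profiles` / `simulate_immune_mixture`: planted
  exclusive markers (high in their own type, ~50× lower elsewhere,
  lognormal noise) across 3 independent datasets, and bulk mixtures in
  which signature genes scale with their cell type's mixing proportion.

They do **not** emulate: read-level error and mapping artefacts
(alignment and variant calling are upstream of this package), real
linkage structure in pedigrees, splice isoforms, correlated
marker-gene biology (real markers co-vary within cell types),
microsatellite locus structure, or compositional effects in bulk
expression. Passing recovery tests therefore demonstrates that the
algorithms are correct on data obeying their stated models — not that
the models capture every property of patient sequencing data. Reference
immune profiles and published peptide tables used in tests are
synthetic or transcribed fixtures, never derivatives of any deposited
dataset.

# Numerical choices and degenerate inputs

* Coordinates: genomic and CDS positions are 1-based inclusive (HGVS);
  window arithmetic is 0-based half-open internally.
* Multi-allelic VCF records are split one variant per ALT, with the
  matching AD component per sample; symbolic ALTs are skipped with a
  counted warning.
* Percent allele depth with zero total depth is an error, not NA: a
  silent NA propagates into ratio tables unnoticed.
* Stop codons never appear in peptides; windows truncate at the mutant
  C-terminus rather than padding.
* ssGSEA with a signature disjoint from the expression genes, or
  covering all of them, is an error; `n_perm < 100` is rejected
  (empirical p-values coarser than 1/101 are not meaningful at
  α = 0.05).
* All ranking ties (cell types in ARS, genes in sorting, severity in
  segregation) are resolved mid-rank or by name, never by input order,
  so every result is permutation-invariant.

# Problem sizes used by the test and acceptance suites

Property suites run at sizes chosen to make the statistics sharp while
keeping a full run inside a coffee break: ssGSEA oracle checks on 200
random instances with N ≤ 50 plus a 1000-draw null; 100 random
frameshifts against an independent codon-table translation; 50 seeded
pedigrees for co-segregation recovery; 200 pure-noise samples × 8 cell
types (199 permutations each) for the presence-call type-I rate; one
959-variant somatic simulation for the class-mix and expression-rate
checks.

# Known limitations

* The binding and TCR scorers are stand-ins by design; published
  affinities are inputs, not targets, and no attempt is made to
  reproduce them.
* Proteasomal cleavage and TAP transport are not modelled (adapter
  tables can carry external predictions through the same record
  format).
* Carrier state is binary; zygosity is not modelled in segregation.
* Patient-level results (a specific tumour's mutation burden, its
  Fig-style immune score bars, its printed nM affinities) are not
  reproducible from this package alone: the underlying sequencing data
  are not publicly deposited and the external predictors are out of
  scope. The property suites above are the evidence that each stage
  behaves correctly.
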