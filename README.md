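# lynchpept

Neoepitope prioritization and tumour-microenvironment scoring for
hereditary mismatch-repair-deficient (Lynch syndrome) tumours.

## What it is for

Lynch syndrome families carry germline mutations in mismatch-repair (MMR)
genes such as *MLH1*; carriers who lose the remaining wildtype allele
develop hypermutated, microsatellite-unstable colorectal tumours whose
hundreds of somatic mutations are a rich source of candidate neoepitopes.
`lynchpept` implements the full desk analysis for such a case, for
bioinformaticians working on cancer-immunology pipelines:

1. **Co-segregation** — screen a pedigree genotype panel for the variant
   carried by every affected member and by no unaffected member,
   distinguishing a pathogenic frameshift from benign missense variants
   shared family-wide (`cosegregating_variants`, `penetrance_report`).
2. **Peptides** — call coding consequences against a CDS, build the
   mutant protein (frameshifts are translated in the shifted frame to the
   novel stop, with HGVS `p.X123YfsTer5` annotation under the 3' rule),
   and enumerate wildtype/mutant 9-mer pairs with positional wildtype
   partners (`classify_consequence`, `mutant_protein`,
   `enumerate_peptide_pairs`).
3. **Immunogenicity cascade** — HLA restriction, peptide–HLA affinity on
   the IC50 (nM) scale via a position-weight stand-in scorer
   (`ic50 = 50000^(1-s)`), a swappable TCR-binding heuristic, and the
   filter *TCR-positive AND IC50 < 1000 nM* (`score_binding`,
   `call_tcr_binding`, `filter_immunogenic`, `summarize_cascade`).
4. **Expression evidence** — expressed-gene calls (FPKM ≥ 1), DNA/RNA
   percent-allele-depth concordance with a second-hit flag when the
   tumour fraction is ≥ 1.8× the germline fraction, and the Spearman
   association between mutant allele depth and CTL response
   (`is_expressed`, `dna_rna_concordance`,
   `expression_response_association`).
5. **Tumour microenvironment** — marker selection from reference
   immune-cell profiles by Average Rank Score (selectivity) and Marker
   Evaluation Score (cross-dataset stability), disjoint signatures for
   eight immune cell types, single-sample gene-set enrichment (ssGSEA)
   scores, permutation presence calls, and a checkpoint/HLA/TAP
   expression report (`select_signatures`, `ssgsea_score`,
   `call_presence`, `checkpoint_report`).
6. **Synthetic data** — seeded generators for every input the pipeline
   consumes (reference CDSs, pedigree panels, somatic variant sets with
   a 69/30/1 missense/indel/nonsense mix, immune mixtures), each with a
   truth ledger for recovery tests (`simulate_*`).

The ssGSEA statistic, for a sample with genes sorted by expression
(descending, position *j* carrying rank weight *r_j = N − j + 1*):

    P_in(i)  = Σ_{g∈G, pos(g)≤i} r_g^α / Σ_{g∈G} r_g^α
    P_out(i) = |{g∉G, pos(g)≤i}| / (N − |G|)
    ES       = Σ_{i=1..N} ( P_in(i) − P_out(i) ),   α = 0.25 by default

## Worked example

```r
library(lynchpept)

# a 2-affected / 2-unaffected family with one planted pathogenic
# frameshift among 6 benign shared missense variants
fam <- simulate_family(n_affected = 2, n_unaffected = 2,
                       n_benign_shared = 6, seed = 7)
cosegregating_variants(fam$panel, fam$variants)
#>   rank        variant_key gene consequence pathogenicity ...
#> 1    1 chr3:18747599:CT>C MSH3  frameshift    pathogenic ...

# frameshift translation: deleting c.4 of ATG CAA ATA AGC TGA (MQIS*)
mp <- mutant_protein("ATGCAAATAAGCTGA", 3, "GC", "G")
mp$protein; mp$hgvs_p
#> "MK"   "p.Q2KfsTer2"

# the wildtype/mutant pair at the changed residue
enumerate_peptide_pairs("TSIQVIVKEGAKITDLA", "TSIQVIVKRWLAV",
                        first_changed_residue = 9, k = 9)[1, 1:3]
#>      wt_seq   mut_seq protein_start
#> 1 TSIQVIVKE TSIQVIVKR             1

# replay published predictor output through the cascade: the
# sub-10-nM MSH6 peptide falls to the TCR call, PIGO and AXIN2 survive
tab  <- case_pathogenic_peptides()
recs <- data.frame(gene = tab$gene, peptide = tab$mut_peptide,
                   allele = tab$allele, ic50 = tab$mut_ic50_nM,
                   tcr_call = tab$tcr_call)
filter_immunogenic(hla_restrict(recs, "HLA-A*02:06"))
#>    gene   peptide      allele   ic50 tcr_call
#> 2  PIGO KLTWIMWSL HLA-A*02:06  10.30     High
#> 3 AXIN2 HLWGATAGT HLA-A*02:06 425.67     High

# second-hit screen: 38% germline vs 73% tumour allele depth
cc <- dna_rna_concordance(list(blood = c(62, 38), tumour_dna = c(27, 73)))
cc$percents                       # blood 38, tumour_dna 73
cc$ratios["tumour_dna_vs_blood"]  # 1.921
cc$second_hit_flag                # TRUE
```

The ~1.9× jump of the mutant allele fraction from blood to tumour is
the classic signature of a somatic second hit on the remaining wildtype
MMR allele.

## Vignette

`vignettes/lynchpept-methods.Rmd` describes the models and scoring
rules, the parameters that matter, what the synthetic generators do and
do not emulate, and known limitations — in particular, that the binding
and TCR scorers are documented stand-ins, not reimplementations of the
proprietary or third-party predictors used to produce published
affinities.
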