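toy_cds <- "ATGGAAACTTGGTAA"  # M E T W *

test_that("SNV and indel consequences are called from the translated effect", {
  expect_equal(classify_consequence(toy_cds, 4, "G", "A"), "missense")
  expect_equal(classify_consequence(toy_cds, 4, "G", "T"), "nonsense")
  expect_equal(classify_consequence(toy_cds, 4, "GA", "G"), "frameshift")
  expect_equal(classify_consequence(toy_cds, 6, "A", "G"), "synonymous")
  expect_equal(classify_consequence(toy_cds, 4, "GAAA", "G"), "inframe_indel")
  expect_error(classify_consequence(toy_cds, 4, "C", "A"), "disagrees")
})

test_that("missense and nonsense proteins follow hand translation", {
  mis <- mutant_protein(toy_cds, 4, "G", "A")
  expect_equal(mis$protein, "MKTW")
  expect_equal(mis$hgvs_p, "p.E2K")
  expect_equal(mis$first_changed_residue, 2L)
  expect_equal(hamming(mis$protein, "METW"), 1)
  non <- mutant_protein(toy_cds, 4, "G", "T")
  expect_equal(non$protein, "M")
  expect_equal(non$hgvs_p, "p.E2Ter")
})

test_that("frameshift translation runs the shifted frame to the novel stop", {
  # ATG CAA ATA AGC TGA = M Q I S *; deleting c.4 gives ATG AAA TAA = M K *
  mp <- mutant_protein("ATGCAAATAAGCTGA", 3, "GC", "G")
  expect_equal(mp$protein, "MK")
  expect_equal(mp$consequence, "frameshift")
  expect_equal(mp$first_changed_residue, 2L)
  expect_equal(mp$hgvs_p, "p.Q2KfsTer2")
  expect_false(mp$flagged)
})

test_that("a shifted frame with no stop is annotated fsTer? and flagged", {
  mp <- mutant_protein(toy_cds, 4, "GA", "G")  # ATG GAA CTT GGT AA
  expect_equal(mp$protein, "MELG")
  expect_true(mp$flagged)
  expect_match(mp$hgvs_p, "fsTer\\?$")
})

test_that("deletions are right-aligned per the HGVS 3' rule", {
  # homopolymer run: ATG AAAAA G TAG; a deletion written at the left end
  # of the run must be shifted to its right end
  cds <- "ATGAAAAAGTAG"
  mut <- apply_cds_edit(cds, 3, "GA", "G")
  expect_equal(attr(mut, "edit")$pos, 8L)
  expect_equal(as.character(mut), "ATGAAAAGTAG")
})

test_that("frameshift proteins match an independent translation oracle on
          random synthetic indels", {
  ref <- simulate_reference(n_transcripts = 15, mean_cds_len = 240,
                            seed = 101)
  set.seed(202)
  n_done <- 0
  while (n_done < 100) {
    cds <- ref$transcripts[[sample.int(length(ref$transcripts), 1)]]
    fs <- random_frameshift(cds)
    mp <- mutant_protein(cds, fs$pos, fs$ref, fs$alt)
    expect_equal(mp$consequence, "frameshift")
    mut_cds <- oracle_edit(cds, fs$pos, fs$ref, fs$alt)
    orc <- oracle_translate(mut_cds)
    expect_equal(mp$protein, as.character(orc))
    expect_equal(mp$flagged, !attr(orc, "terminated"))
    # fsTer offset contract: novel tail length (first changed residue
    # inclusive, to the residue before the stop) + 1
    if (grepl("fsTer[0-9]+$", mp$hgvs_p)) {
      off <- as.integer(sub(".*fsTer", "", mp$hgvs_p))
      tail_len <- nchar(mp$protein) - mp$first_changed_residue + 1L
      expect_equal(off, tail_len + 1L)
    }
    n_done <- n_done + 1
  }
})

test_that("mutant protein construction is deterministic and re-translation
          of the edited CDS is idempotent", {
  cds <- "ATGCAAATAAGCTGA"
  a <- mutant_protein(cds, 3, "GC", "G")
  b <- mutant_protein(cds, 3, "GC", "G")
  expect_identical(a, b)
})

test_that("published wildtype/mutant 9-mer pairs are recovered from their
          protein contexts", {
  for (ctx in published_pair_contexts()) {
    pp <- enumerate_peptide_pairs(ctx$wt, ctx$mut, ctx$first_changed, k = 9)
    row <- pp[pp$protein_start == ctx$window_start, ]
    expect_equal(row$wt_seq, ctx$wt_pep)
    expect_equal(row$mut_seq, ctx$mut_pep)
  }
})

test_that("window enumeration matches a brute-force enumerator and the
          missense window count equals k", {
  wt <- "ABCDEFGHIJKLMNOPQRST"
  mut <- "ABCDEFGHIWKLMNOPQRST"  # missense at interior residue 10
  pp <- enumerate_peptide_pairs(wt, mut, 10, k = 9)
  expect_equal(nrow(pp), 9)
  expect_equal(pp$mut_seq, oracle_windows(mut, 10, 9, last_changed = 10))
  expect_true(all(vapply(seq_len(nrow(pp)), function(i)
    hamming(pp$wt_seq[i], pp$mut_seq[i]), numeric(1)) == 1))
})

test_that("frameshift pairs first differ at the changed residue and novel-tail
          windows have positional wildtype partners", {
  ctx <- published_pair_contexts()$AXIN2
  pp <- enumerate_peptide_pairs(ctx$wt, ctx$mut, ctx$first_changed, k = 9)
  for (i in seq_len(nrow(pp))) {
    if (is.na(pp$wt_seq[i])) next
    expect_gte(hamming(pp$wt_seq[i], pp$mut_seq[i]), 1)
    if (pp$protein_start[i] <= ctx$first_changed) {
      d <- which(strsplit(pp$wt_seq[i], "")[[1]] !=
                   strsplit(pp$mut_seq[i], "")[[1]])[1]
      expect_equal(d, ctx$first_changed - pp$protein_start[i] + 1L)
    }
  }
  # window fully inside the novel tail shares no residues with wildtype
  pigo <- published_pair_contexts()$PIGO
  pp2 <- enumerate_peptide_pairs(pigo$wt, pigo$mut, pigo$first_changed, k = 9)
  row <- pp2[pp2$protein_start == 3, ]
  expect_equal(hamming(row$wt_seq, row$mut_seq), 9)
})

test_that("edge windows: single-window proteins, C-terminal truncation,
          oversized k", {
  pp <- enumerate_peptide_pairs("ABCDEFGHI", "WBCDEFGHI", 1, k = 9)
  expect_equal(nrow(pp), 1)
  expect_equal(hamming(pp$wt_seq, pp$mut_seq), 1)
  # mutant shorter than wildtype: windows truncate at mutant C-terminus
  pp2 <- enumerate_peptide_pairs("ABCDEFGHIJKL", "ABCDEFGHIW", 10, k = 9)
  expect_true(all(nchar(pp2$mut_seq) == 9))
  expect_equal(max(pp2$protein_start + 8), 10)
  expect_warning(out <- enumerate_peptide_pairs("ABCD", "ABCW", 4, k = 9),
                 "exceeds")
  expect_equal(nrow(out), 0)
})

test_that("variant-table peptide generation annotates pairs per variant", {
  ref <- simulate_reference(n_transcripts = 5, mean_cds_len = 150, seed = 7)
  som <- simulate_somatic(ref, n_variants = 20, seed = 8)
  pp <- peptide_pairs_for_variants(som$variants, ref$transcripts)
  expect_gt(nrow(pp), 0)
  expect_true(all(nchar(pp$mut_seq) == 9))
  expect_true(all(pp$source_variant %in% som$variants$variant_key))
})
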