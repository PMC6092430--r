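# Mutant protein construction and wildtype/mutant peptide enumeration.
# Coordinates: CDS positions are 1-based inclusive (HGVS convention);
# internal window arithmetic is 0-based half-open.

codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a CDS (or shifted reading frame) to the first stop
#'
#' Codon-by-codon translation of the standard genetic code, tolerant of
#' frames whose length is not a multiple of 3 (the trailing partial
#' codon is dropped) — needed for frameshifted sequences.
#'
#' @param seq DNA string (A/C/G/T), read from position 1.
#' @return amino-acid string up to but excluding the first stop codon,
#'   with attribute `terminated` (logical): whether a stop was reached
#'   before the end of the sequence.
#' @export
translate_cds <- function(seq) {
  gc <- codon_table()
  n_codon <- nchar(seq) %/% 3
  aa <- character(0)
  terminated <- FALSE
  for (i in seq_len(n_codon)) {
    codon <- substr(seq, 3 * i - 2, 3 * i)
    a <- gc[[codon]]
    if (is.null(a)) stop("invalid codon: ", codon)
    if (a == "*") { terminated <- TRUE; break }
    aa[i] <- a
  }
  structure(paste(aa, collapse = ""), terminated = terminated)
}

# Reduce a VCF-style (pos, ref, alt) to its minimal edit by trimming the
# shared suffix then prefix, and right-align (3'-shift) pure indels per
# the HGVS 3' rule.  Returns list(pos, ref, alt, type).
normalize_cds_edit <- function(cds, pos, ref, alt) {
  n <- nchar(cds)
  if (pos < 1 || pos + nchar(ref) - 1 > n)
    stop("variant outside CDS (pos ", pos, ", ref ", ref, ")")
  if (substr(cds, pos, pos + nchar(ref) - 1) != ref)
    stop("reference allele '", ref, "' disagrees with transcript at CDS pos ",
         pos)
  # trim shared suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) > 1 && nchar(alt) == 1 && substr(ref, 1, 1) == alt) {
    # anchored deletion: REF = anchor + deleted
    del <- substr(ref, 2, nchar(ref))
    dpos <- pos + 1L
    L <- nchar(del)
    while (dpos + L <= n &&
           substr(cds, dpos + L, dpos + L) == substr(cds, dpos, dpos))
      dpos <- dpos + 1L
    return(list(pos = dpos, ref = substr(cds, dpos, dpos + L - 1), alt = "",
                type = "del"))
  }
  if (nchar(alt) > 1 && nchar(ref) == 1 && substr(alt, 1, 1) == ref) {
    # anchored insertion: ALT = anchor + inserted, inserted before pos+1
    ins <- substr(alt, 2, nchar(alt))
    ipos <- pos + 1L  # insertion point: before cds[ipos]
    while (ipos <= n && substr(cds, ipos, ipos) == substr(ins, 1, 1)) {
      ins <- paste0(substr(ins, 2, nchar(ins)), substr(ins, 1, 1))
      ipos <- ipos + 1L
    }
    return(list(pos = ipos, ref = "", alt = ins, type = "ins"))
  }
  if (ref == alt) stop("ref and alt identical after trimming")
  list(pos = pos, ref = ref, alt = alt,
       type = if (nchar(ref) == 1 && nchar(alt) == 1) "snv" else "delins")
}

#' Apply a CDS-level edit, returning the mutant CDS
#'
#' @param cds wildtype CDS string (coding strand).
#' @param cds_pos 1-based CDS position of the first REF base.
#' @param ref,alt VCF-style alleles (anchored for indels).
#' @return mutant CDS string with attribute `edit`, the normalized
#'   (3'-shifted) minimal edit.
#' @export
apply_cds_edit <- function(cds, cds_pos, ref, alt) {
  e <- normalize_cds_edit(cds, cds_pos, ref, alt)
  n <- nchar(cds)
  mut <- switch(e$type,
    del = paste0(substr(cds, 1, e$pos - 1),
                 substr(cds, e$pos + nchar(e$ref), n)),
    ins = paste0(substr(cds, 1, e$pos - 1), e$alt, substr(cds, e$pos, n)),
    paste0(substr(cds, 1, e$pos - 1), e$alt,
           substr(cds, e$pos + nchar(e$ref), n)))
  structure(mut, edit = e)
}

#' Classify the coding consequence of a variant
#'
#' @param cds wildtype CDS string.
#' @param cds_pos,ref,alt edit in VCF style, CDS coordinates.
#' @return one of `"missense"`, `"nonsense"`, `"synonymous"`,
#'   `"frameshift"`, `"inframe_indel"`, `"other"` (e.g. stop-loss).
#' @export
classify_consequence <- function(cds, cds_pos, ref, alt) {
  e <- normalize_cds_edit(cds, cds_pos, ref, alt)
  net <- abs(nchar(e$ref) - nchar(e$alt))
  if (net > 0) return(if (net %% 3 != 0) "frameshift" else "inframe_indel")
  if (e$type == "snv") {
    gc <- codon_table()
    ci <- (e$pos - 1L) %/% 3L
    wt_codon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
    mut_codon <- wt_codon
    substr(mut_codon, e$pos - 3 * ci, e$pos - 3 * ci) <- e$alt
    wt_aa <- gc[[wt_codon]]
    mut_aa <- gc[[mut_codon]]
    if (wt_aa == mut_aa) return("synonymous")
    if (mut_aa == "*") return("nonsense")
    if (wt_aa == "*") return("other")
    return("missense")
  }
  # same-length multi-base substitution: compare translations
  mut <- apply_cds_edit(cds, cds_pos, ref, alt)
  wt_p <- translate_cds(cds)
  mut_p <- translate_cds(mut)
  if (wt_p == mut_p) return("synonymous")
  if (nchar(mut_p) < nchar(wt_p) &&
      mut_p == substr(wt_p, 1, nchar(mut_p))) return("nonsense")
  d <- first_difference(wt_p, mut_p)
  if (nchar(wt_p) == nchar(mut_p) &&
      sum(strsplit(wt_p, "")[[1]] != strsplit(mut_p, "")[[1]]) == 1)
    return("missense")
  "other"
}

# 1-based index of the first differing residue, or NA if one string is a
# prefix of the other and nothing differs
first_difference <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m > 0) {
    av <- strsplit(substr(a, 1, m), "")[[1]]
    bv <- strsplit(substr(b, 1, m), "")[[1]]
    d <- which(av != bv)
    if (length(d)) return(d[1])
  }
  if (nchar(a) != nchar(b)) m + 1L else NA_integer_
}

#' Mutant protein and HGVS protein annotation for a coding variant
#'
#' Applies the (3'-shifted) edit to the CDS and translates.  For a
#' frameshift the shifted frame is translated from the first affected
#' codon until the first stop; the HGVS string reports the first changed
#' residue and the stop offset in `fsTer<n>` notation, where the first
#' changed residue counts as 1 (so `fsTer5` means the novel stop is the
#' 5th residue of the new frame).  `fsX` in published tables is the same
#' notation.  A shifted frame that runs off the transcript end without a
#' stop is reported as `fsTer?` and flagged.
#'
#' @param cds wildtype CDS string.
#' @param cds_pos,ref,alt edit in VCF style, CDS coordinates.
#' @return list with `protein` (mutant protein to the first stop, stop
#'   excluded), `hgvs_p`, `first_changed_residue` (1-based, NA for
#'   synonymous), `consequence`, and `flagged` (TRUE when no stop was
#'   reached).
#' @export
mutant_protein <- function(cds, cds_pos, ref, alt) {
  cons <- classify_consequence(cds, cds_pos, ref, alt)
  wt_p <- as.character(translate_cds(cds))
  mut_cds <- apply_cds_edit(cds, cds_pos, ref, alt)
  mut_tr <- translate_cds(mut_cds)
  mut_p <- as.character(mut_tr)
  terminated <- attr(mut_tr, "terminated")
  i <- first_difference(wt_p, mut_p)
  flagged <- FALSE
  if (cons == "synonymous") {
    hgvs <- "p.="
  } else if (cons == "missense") {
    hgvs <- sprintf("p.%s%d%s", substr(wt_p, i, i), i, substr(mut_p, i, i))
  } else if (cons == "nonsense") {
    i <- nchar(mut_p) + 1L
    hgvs <- sprintf("p.%s%dTer", substr(wt_p, i, i), i)
  } else if (cons == "frameshift") {
    if (is.na(i)) {
      # shifted frame happens to re-encode the wildtype protein
      return(list(protein = mut_p, hgvs_p = "p.=",
                  first_changed_residue = NA_integer_,
                  consequence = cons, flagged = FALSE))
    }
    ref_aa <- if (i <= nchar(wt_p)) substr(wt_p, i, i) else "*"
    if (i > nchar(mut_p)) {
      # the shifted frame opens directly on a stop codon
      hgvs <- sprintf("p.%s%dTer", ref_aa, i)
    } else if (terminated) {
      offset <- nchar(mut_p) - i + 2L
      hgvs <- sprintf("p.%s%d%sfsTer%d", ref_aa, i, substr(mut_p, i, i),
                      offset)
    } else {
      flagged <- TRUE
      hgvs <- sprintf("p.%s%d%sfsTer?", ref_aa, i, substr(mut_p, i, i))
    }
  } else if (cons == "inframe_indel") {
    hgvs <- sprintf("p.%s%d_inframe", if (!is.na(i) && i <= nchar(wt_p))
      substr(wt_p, i, i) else "?", if (is.na(i)) 0L else i)
  } else {
    hgvs <- "p.?"
  }
  list(protein = mut_p, hgvs_p = hgvs,
       first_changed_residue = if (cons == "synonymous") NA_integer_
                               else as.integer(i),
       consequence = cons, flagged = flagged)
}

#' Enumerate wildtype/mutant k-mer peptide pairs around a mutation
#'
#' All k-length windows of the mutant protein that contain at least one
#' residue at or after the first changed residue, truncated at the
#' mutant C-terminus (never padded).  The wildtype partner of each
#' window is defined positionally — the wildtype residues at the same
#' protein coordinates — which for windows inside a novel frameshifted
#' tail can be a completely different peptide, and is NA where the
#' wildtype protein does not extend that far.
#'
#' @param wt_protein wildtype protein string.
#' @param mut_protein mutant protein string.
#' @param first_changed_residue 1-based coordinate of the first residue
#'   that differs from wildtype.
#' @param k peptide length (default 9, the class I epitope length).
#' @param source_variant optional variant key recorded per pair.
#' @return data.frame with wt_seq (NA when out of wildtype range),
#'   mut_seq, protein_start, first_changed_residue, source_variant.
#' @export
enumerate_peptide_pairs <- function(wt_protein, mut_protein,
                                    first_changed_residue, k = 9,
                                    source_variant = NA_character_) {
  stopifnot(k >= 1, nchar(mut_protein) > 0, first_changed_residue >= 1)
  empty <- data.frame(wt_seq = character(), mut_seq = character(),
                      protein_start = integer(),
                      first_changed_residue = integer(),
                      source_variant = character(),
                      stringsAsFactors = FALSE)
  if (k > nchar(mut_protein)) {
    warning("k = ", k, " exceeds mutant protein length ", nchar(mut_protein))
    return(empty)
  }
  # changed region: for same-length proteins (missense/MNV) it ends at
  # the last differing residue, so windows past it are not emitted; for
  # frameshifts and length changes everything to the C-terminus is novel
  last_changed <- nchar(mut_protein)
  if (nchar(wt_protein) == nchar(mut_protein)) {
    d <- which(strsplit(wt_protein, "")[[1]] != strsplit(mut_protein, "")[[1]])
    if (length(d)) last_changed <- max(d)
  }
  lo <- max(1L, first_changed_residue - k + 1L)
  hi <- nchar(mut_protein) - k + 1L
  if (lo > hi) return(empty)  # changed region lies past the last full window
  starts <- seq(lo, hi)
  starts <- starts[starts + k - 1L >= first_changed_residue &
                     starts <= last_changed]
  if (!length(starts)) return(empty)
  wt <- vapply(starts, function(s)
    if (nchar(wt_protein) >= s + k - 1L) substr(wt_protein, s, s + k - 1L)
    else NA_character_, character(1))
  mut <- vapply(starts, function(s) substr(mut_protein, s, s + k - 1L),
                character(1))
  data.frame(wt_seq = wt, mut_seq = mut, protein_start = as.integer(starts),
             first_changed_residue = as.integer(first_changed_residue),
             source_variant = source_variant, stringsAsFactors = FALSE)
}

#' Peptide pairs for every coding variant in a table
#'
#' Convenience wrapper running [mutant_protein()] and
#' [enumerate_peptide_pairs()] over a variant table against its
#' transcripts; synonymous and unclassifiable variants are skipped.
#'
#' @param variants a `variant_table` with transcript_id and cds_pos.
#' @param transcripts named character vector of CDS sequences (as from
#'   [read_transcripts()]).
#' @param k peptide length.
#' @return data.frame of peptide pairs with gene and variant annotation.
#' @export
peptide_pairs_for_variants <- function(variants, transcripts, k = 9) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    tid <- variants$transcript_id[i]
    if (is.na(tid) || is.null(transcripts[[tid]]) ||
        is.na(variants$cds_pos[i])) next
    cds <- transcripts[[tid]]
    mp <- mutant_protein(cds, variants$cds_pos[i], variants$ref[i],
                         variants$alt[i])
    if (mp$consequence %in% c("synonymous", "other")) next
    if (is.na(mp$first_changed_residue) || nchar(mp$protein) == 0) next
    pp <- suppressWarnings(enumerate_peptide_pairs(
      as.character(translate_cds(cds)), mp$protein,
      mp$first_changed_residue, k = k,
      source_variant = variants$variant_key[i]))
    if (nrow(pp)) {
      pp$gene <- variants$gene[i]
      pp$consequence <- mp$consequence
      pp$hgvs_p <- mp$hgvs_p
      out[[length(out) + 1L]] <- pp
    }
  }
  if (!length(out))
    return(data.frame(wt_seq = character(), mut_seq = character(),
                      protein_start = integer(),
                      first_changed_residue = integer(),
                      source_variant = character(), gene = character(),
                      consequence = character(), hgvs_p = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
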