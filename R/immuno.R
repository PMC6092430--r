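# HLA-binding and TCR-binding scoring and the immunogenicity filter
# cascade.  The binding scorer is a deliberately simple position-weight
# stand-in mapped onto the conventional IC50 (nM) scale so that the
# usual 1000 nM immunogenicity and 150 nM strong-binder thresholds are
# meaningful; it makes no claim of agreement with NetMHC-family tools.
# The TCR-binding call is likewise a documented, swappable heuristic.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Scoring configuration for the immunogenicity cascade
#'
#' @param immunogenic_affinity_nM IC50 below which a peptide counts as a
#'   candidate immunogen (default 1000 nM, strict inequality).
#' @param strong_binder_nM IC50 below which a peptide is a strong binder
#'   (default 150 nM); must not exceed `immunogenic_affinity_nM`.
#' @param tcr_rule TCR-binding rule, see [call_tcr_binding()].
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(immunogenic_affinity_nM = 1000,
                           strong_binder_nM = 150,
                           tcr_rule = tcr_rule_central()) {
  if (!(strong_binder_nM > 0 && strong_binder_nM <= immunogenic_affinity_nM))
    stop("need 0 < strong_binder_nM <= immunogenic_affinity_nM")
  structure(list(immunogenic_affinity_nM = immunogenic_affinity_nM,
                 strong_binder_nM = strong_binder_nM,
                 tcr_rule = tcr_rule),
            class = "scoring_config")
}

#' Score peptide-HLA binding with a position-specific scoring matrix
#'
#' The raw score is the mean of per-position matrix weights (each in
#' \[0, 1\]) for the peptide's residues; it is mapped to the nM scale by
#' the convention `ic50 = 50000^(1 - s)`, so a consensus peptide scores
#' 1 nM and a null peptide 50000 nM, and IC50 decreases strictly as the
#' raw score increases.
#'
#' @param peptide amino-acid string over the 20 standard residues.
#' @param allele HLA allele name, a key of `pssm_set`.
#' @param pssm_set PSSM set as returned by [read_pssm()] or
#'   [random_pssm()]: `pssm_set[[allele]][[as.character(k)]]` is a
#'   k x 20 weight matrix with residue column names.
#' @return predicted IC50 in nM.
#' @export
score_binding <- function(peptide, allele, pssm_set) {
  if (is.null(pssm_set[[allele]]))
    stop("no scoring matrix for allele ", allele, "; available: ",
         paste(names(pssm_set), collapse = ", "))
  k <- nchar(peptide)
  mat <- pssm_set[[allele]][[as.character(k)]]
  if (is.null(mat))
    stop("no length-", k, " matrix for allele ", allele)
  res <- strsplit(peptide, "")[[1]]
  if (!all(res %in% colnames(mat)))
    stop("non-standard residue in peptide ", peptide)
  s <- mean(mat[cbind(seq_len(k), match(res, colnames(mat)))])
  50000 ^ (1 - s)
}

#' Random position-specific scoring matrices
#'
#' Generates a PSSM set for testing and simulation: each allele/length
#' gets uniform \[0, 1\] weights with one high-weight consensus residue
#' per position.
#'
#' @param alleles character vector of HLA allele names.
#' @param k peptide length(s).
#' @param seed RNG seed.
#' @return a PSSM set usable with [score_binding()].
#' @export
random_pssm <- function(alleles, k = 9, seed = NULL) {
  with_seed(seed, {
    out <- lapply(alleles, function(a) {
      mats <- lapply(k, function(len) {
        m <- matrix(stats::runif(len * 20, 0, 0.6), nrow = len,
                    dimnames = list(NULL, AA20))
        cons <- sample.int(20, len, replace = TRUE)
        m[cbind(seq_len(len), cons)] <- stats::runif(len, 0.9, 1)
        m
      })
      names(mats) <- as.character(k)
      mats
    })
    names(out) <- alleles
    out
  })
}

#' Read / write a PSSM set as JSON
#'
#' File layout: `{allele: {"<length>": [[w...20] x length]}}` with
#' weights in \[0, 1\] in the fixed residue order ACDEFGHIKLMNPQRSTVWY.
#'
#' @param path JSON file path.
#' @return for `read_pssm`, a PSSM set; `write_pssm` returns `path`
#'   invisibly.
#' @export
read_pssm <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(by_len) {
    lapply(by_len, function(m) {
      m <- as.matrix(m)
      colnames(m) <- AA20
      m
    })
  })
}

#' @rdname read_pssm
#' @param pssm_set a PSSM set.
#' @export
write_pssm <- function(pssm_set, path) {
  stripped <- lapply(pssm_set, function(by_len)
    lapply(by_len, function(m) unname(as.matrix(m))))
  jsonlite::write_json(stripped, path, digits = NA)
  invisible(path)
}

#' Default TCR-binding heuristic: central-residue composition
#'
#' A peptide is called `High` when at least `min_count` of the central
#' residues (positions 4-6 of a 9-mer) are bulky/aromatic or charged —
#' the positions that arch out of the MHC groove toward the TCR.  This
#' is an openly simple stand-in for proprietary TCR-contact models; the
#' rule in force is serialized into every run manifest.
#'
#' @param positions central residue positions examined.
#' @param residues qualifying residue set.
#' @param min_count minimum number of qualifying central residues.
#' @return a rule object for [call_tcr_binding()].
#' @export
tcr_rule_central <- function(positions = 4:6,
                             residues = c("F", "W", "Y", "R", "K", "H",
                                          "L", "I"),
                             min_count = 2) {
  structure(list(name = "central_bulky_charged", positions = positions,
                 residues = residues, min_count = min_count),
            class = "tcr_rule")
}

#' Call TCR binding for a peptide
#'
#' @param peptide amino-acid string, length >= 7.
#' @param tcr_rule either a rule from [tcr_rule_central()] or a function
#'   `peptide -> "High"/"Deprioritized"` (rule-injection hook).
#' @return `"High"` or `"Deprioritized"`.
#' @export
call_tcr_binding <- function(peptide, tcr_rule = tcr_rule_central()) {
  if (nchar(peptide) < 7) stop("peptide shorter than 7 residues")
  if (is.function(tcr_rule)) return(tcr_rule(peptide))
  res <- strsplit(peptide, "")[[1]][tcr_rule$positions]
  n_hit <- sum(res %in% tcr_rule$residues, na.rm = TRUE)
  if (n_hit >= tcr_rule$min_count) "High" else "Deprioritized"
}

#' Immunogenicity filter: TCR-positive and affinity below threshold
#'
#' Keeps records with `tcr_call == "High"` and `ic50` strictly below the
#' immunogenic-affinity threshold (default 1000 nM); record order is
#' preserved and the filter is idempotent.
#'
#' @param records data.frame with columns ic50 and tcr_call.
#' @param config a [scoring_config()].
#' @return the surviving subset of `records`.
#' @export
filter_immunogenic <- function(records, config = scoring_config()) {
  stopifnot(all(c("ic50", "tcr_call") %in% names(records)))
  keep <- records$tcr_call == "High" &
    records$ic50 < config$immunogenic_affinity_nM
  records[keep, , drop = FALSE]
}

#' Restrict binding records to a subject's HLA alleles
#'
#' @param records data.frame with an `allele` column.
#' @param hla_alleles the subject's class I alleles (character vector).
#' @return the subset of records whose allele the subject carries.
#' @export
hla_restrict <- function(records, hla_alleles) {
  stopifnot(length(hla_alleles) > 0)
  records[records$allele %in% hla_alleles, , drop = FALSE]
}

#' Cascade summary: integer percentages per filtering stage
#'
#' @param stage_counts data.frame with columns label, numerator,
#'   denominator.
#' @return the input with `fraction` and `percent` columns; percentages
#'   are rounded half-up to integers.  Rows with zero denominator are
#'   flagged and get NA percent.
#' @export
summarize_cascade <- function(stage_counts) {
  stopifnot(all(c("label", "numerator", "denominator")
                %in% names(stage_counts)))
  out <- stage_counts
  out$fraction <- ifelse(out$denominator > 0,
                         out$numerator / out$denominator, NA_real_)
  out$percent <- ifelse(out$denominator > 0,
                        floor(100 * out$numerator / out$denominator + 0.5),
                        NA_real_)
  out$flagged <- out$denominator <= 0
  out
}

#' Score and filter peptide pairs through the full cascade
#'
#' Runs HLA restriction, binding scoring, TCR calls and the
#' immunogenicity filter over a peptide-pair table, producing one
#' binding record per (mutant peptide, allele).
#'
#' @param pairs peptide-pair data.frame (mut_seq column required).
#' @param hla_alleles subject HLA alleles to score against.
#' @param pssm_set PSSM set covering those alleles.
#' @param config a [scoring_config()].
#' @return list with `records` (all scored records, with `passed`
#'   column) and `manifest` (thresholds and the serialized TCR rule, for
#'   reproducibility).
#' @export
score_peptides <- function(pairs, hla_alleles, pssm_set,
                           config = scoring_config()) {
  recs <- expand.grid(idx = seq_len(nrow(pairs)), allele = hla_alleles,
                      stringsAsFactors = FALSE)
  records <- data.frame(peptide = pairs$mut_seq[recs$idx],
                        wt_peptide = pairs$wt_seq[recs$idx],
                        allele = recs$allele,
                        source_variant =
                          if (!is.null(pairs$source_variant))
                            pairs$source_variant[recs$idx] else NA_character_,
                        stringsAsFactors = FALSE)
  records$ic50 <- mapply(score_binding, records$peptide, records$allele,
                         MoreArgs = list(pssm_set = pssm_set))
  records$tcr_call <- vapply(records$peptide, call_tcr_binding,
                             character(1), tcr_rule = config$tcr_rule)
  records$passed <- records$tcr_call == "High" &
    records$ic50 < config$immunogenic_affinity_nM
  manifest <- list(immunogenic_affinity_nM = config$immunogenic_affinity_nM,
                   strong_binder_nM = config$strong_binder_nM,
                   tcr_rule = if (is.function(config$tcr_rule))
                     "user-supplied function" else unclass(config$tcr_rule))
  list(records = records, manifest = manifest)
}
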