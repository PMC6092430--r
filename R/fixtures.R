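#' Published binding predictions for a hereditary CRC case study
#'
#' External-predictor output for the three pathogenic somatic variants
#' (MSH6, PIGO, AXIN2 frameshifts) prioritized in a Lynch-syndrome
#' colorectal tumour: wildtype/mutant 9-mer pairs, HLA restriction,
#' predicted IC50 (nM) and the TCR-binding call.  Shipped as a
#' plain-text fixture so the filter cascade can be replayed against
#' published adapter values without running any external tool.
#'
#' @return data.frame with columns gene, hgvs_p, allele, wt_peptide,
#'   wt_ic50_nM, mut_peptide, mut_ic50_nM, tcr_call.
#' @export
case_pathogenic_peptides <- function() {
  path <- system.file("extdata", "case_pathogenic_peptides.tsv",
                      package = "lynchpept", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
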