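# RNA-level evidence: expressed-gene calls, DNA/RNA allele-fraction
# concordance (second-hit screen), and the expression-vs-CTL-response
# association.

#' Expressed-gene call from FPKM
#'
#' @param fpkm non-negative FPKM value(s).
#' @param threshold expressed if `fpkm >= threshold` (inclusive);
#'   default 1, the conventional boundary below which a transcript is
#'   reported as lowly expressed.
#' @return logical vector.
#' @export
is_expressed <- function(fpkm, threshold = 1.0) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative")
  fpkm >= threshold
}

#' DNA/RNA allele-depth concordance for one variant
#'
#' Compares the percent alternate allele depth across assays (e.g.
#' blood, tumour DNA, tumour RNA).  A tumour-DNA alternate fraction at
#' least `second_hit_ratio` times the blood (germline) fraction — a
#' heterozygous germline variant climbing from ~38% to ~73% in the
#' tumour — flags a possible second hit (loss of the remaining wildtype
#' allele).  RNA fractions below `low_tier_percent` but above zero are
#' tiered "low but detectable".
#'
#' @param depths named list of `c(ref, alt)` integer count pairs, one
#'   per assay; or a one-row `variant_table` slice.
#' @param second_hit_ratio tumour_dna/blood fraction ratio that triggers
#'   the flag (default 1.8, operationalizing "nearly double").
#' @param low_tier_percent upper bound of the "low but detectable" tier
#'   (default 5 percent).
#' @return list with `percents` (named numeric, percent alt depth per
#'   assay), `tiers` (absent / low_but_detectable / present), `ratios`
#'   (all pairwise fraction ratios, named "a_vs_b"), and
#'   `second_hit_flag`.
#' @export
dna_rna_concordance <- function(depths, second_hit_ratio = 1.8,
                                low_tier_percent = 5) {
  if (inherits(depths, "variant_table") ||
      (is.data.frame(depths) && nrow(depths) == 1)) {
    v <- depths
    depths <- lapply(assay_names(v), function(a) as.integer(get_depths(v, a)))
    names(depths) <- assay_names(v)
  }
  tot <- vapply(depths, sum, numeric(1))
  depths <- depths[tot > 0]
  if (length(depths) < 2)
    stop("need at least two assays with nonzero total depth")
  pct <- vapply(depths, function(d) percent_allele_depth(d[1], d[2]),
                numeric(1))
  tiers <- ifelse(pct == 0, "absent",
                  ifelse(pct < low_tier_percent, "low_but_detectable",
                         "present"))
  names(tiers) <- names(pct)
  combs <- utils::combn(names(pct), 2, simplify = FALSE)
  ratios <- numeric(0)
  for (cb in combs) {
    if (pct[cb[2]] > 0)
      ratios[paste(cb[1], "vs", cb[2], sep = "_")] <- pct[cb[1]] / pct[cb[2]]
    if (pct[cb[1]] > 0)
      ratios[paste(cb[2], "vs", cb[1], sep = "_")] <- pct[cb[2]] / pct[cb[1]]
  }
  flag <- FALSE
  if (all(c("blood", "tumour_dna") %in% names(pct)) && pct["blood"] > 0)
    flag <- unname(pct["tumour_dna"] / pct["blood"]) >= second_hit_ratio
  list(percents = pct, tiers = tiers, ratios = ratios,
       second_hit_flag = flag)
}

#' Association between mutant allele depth and CTL response
#'
#' Rank (Spearman) correlation between the percent allele depth of a
#' set of mutations and the fold-activation of CD8+ T cells their
#' peptides elicit; a strongly negative rho is the signature of tumours
#' down-regulating their most immunogenic neoepitopes.
#'
#' @param allele_depth_percent numeric vector, or a data.frame with
#'   columns allele_depth_percent and activation_fold.
#' @param activation_fold numeric vector (ignored when a data.frame is
#'   given).
#' @return list with `rho` (Spearman, mid-ranked ties; defined as 0 when
#'   either axis is constant), `n`, and `p_value` (NA for n < 5).
#' @export
expression_response_association <- function(allele_depth_percent,
                                            activation_fold = NULL) {
  if (is.data.frame(allele_depth_percent)) {
    df <- allele_depth_percent
    allele_depth_percent <- df$allele_depth_percent
    activation_fold <- df$activation_fold
  }
  x <- as.numeric(allele_depth_percent)
  y <- as.numeric(activation_fold)
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("need at least 3 paired points")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- if (stats::sd(rx) == 0 || stats::sd(ry) == 0) 0
         else stats::cor(rx, ry)
  p <- NA_real_
  if (n >= 5 && stats::sd(rx) > 0 && stats::sd(ry) > 0)
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman")$p.value)
  list(rho = rho, n = n, p_value = p)
}
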