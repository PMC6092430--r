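# Pedigree co-segregation screen: which germline variants are carried by
# every affected family member and by no unaffected member.

severity_rank <- function(pathogenicity, consequence) {
  # pathogenic frameshift > pathogenic nonsense > pathogenic missense >
  # other pathogenic > VUS > benign/unannotated; lower is more severe
  p <- match(pathogenicity, c("pathogenic", "VUS", "unannotated", "benign"))
  cns <- match(consequence,
               c("frameshift", "nonsense", "missense", "inframe_indel",
                 "synonymous", "other"))
  p * 10L + cns
}

check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("subject_id", "affected", "variant_key", "carrier")
                %in% names(panel)))
  panel$affected <- as.logical(panel$affected)
  panel$carrier <- as.integer(panel$carrier)
  # subjects with no informative genotype cannot constrain segregation
  known <- tapply(!is.na(panel$carrier), panel$subject_id, any)
  drop <- names(known)[!known]
  if (length(drop)) {
    warning("excluding subject(s) with all-unknown genotypes: ",
            paste(drop, collapse = ", "))
    panel <- panel[!panel$subject_id %in% drop, , drop = FALSE]
  }
  if (!any(panel$affected)) stop("panel contains no affected subjects")
  if (!any(!panel$affected)) stop("panel contains no unaffected subjects")
  panel
}

#' Variants co-segregating with disease in a family panel
#'
#' Screens a genotype panel for variants carried by every affected
#' subject and absent from the unaffected subjects, the logic used to
#' single out a pathogenic frameshift from a background of benign
#' missense variants shared by the whole family.
#'
#' @param panel long-format genotype panel: data.frame with columns
#'   subject_id, affected (0/1), variant_key, carrier (0/1/NA).
#' @param variants optional `variant_table` (or data.frame with
#'   variant_key, gene, consequence, pathogenicity) used for the
#'   pathogenicity filter and severity ranking.
#' @param require_pathogenic keep only variants annotated pathogenic.
#' @param penetrance_allowance number of unaffected carriers tolerated
#'   before a variant is vetoed (default 0: strict exclusivity).
#'   Incomplete penetrance is common in hereditary cancer pedigrees, so
#'   an unaffected middle-aged carrier need not disqualify a variant.
#' @return data.frame of surviving variants ranked pathogenic-first then
#'   by consequence severity (frameshift/nonsense > missense), with a
#'   rationale column; zero rows when nothing co-segregates.
#' @export
cosegregating_variants <- function(panel, variants = NULL,
                                   require_pathogenic = FALSE,
                                   penetrance_allowance = 0) {
  panel <- check_panel(panel)
  keys <- sort(unique(panel$variant_key))
  keep <- logical(length(keys))
  n_unaff_carrier <- integer(length(keys))
  for (i in seq_along(keys)) {
    pv <- panel[panel$variant_key == keys[i], , drop = FALSE]
    aff <- pv[pv$affected, ]
    unaff <- pv[!pv$affected, ]
    all_aff_carry <- nrow(aff) > 0 && all(!is.na(aff$carrier) & aff$carrier == 1)
    n_unaff_carrier[i] <- sum(unaff$carrier == 1, na.rm = TRUE)
    keep[i] <- all_aff_carry && n_unaff_carrier[i] <= penetrance_allowance
  }
  out <- data.frame(variant_key = keys[keep],
                    unaffected_carriers = n_unaff_carrier[keep],
                    stringsAsFactors = FALSE)
  out$gene <- rep(NA_character_, nrow(out))
  out$consequence <- rep("other", nrow(out))
  out$pathogenicity <- rep("unannotated", nrow(out))
  if (!is.null(variants)) {
    idx <- match(out$variant_key, variants$variant_key)
    out$gene <- variants$gene[idx]
    out$consequence <- ifelse(is.na(idx), "other", variants$consequence[idx])
    out$pathogenicity <- ifelse(is.na(idx), "unannotated",
                                variants$pathogenicity[idx])
  }
  if (require_pathogenic)
    out <- out[out$pathogenicity == "pathogenic", , drop = FALSE]
  sev <- severity_rank(out$pathogenicity, out$consequence)
  ord <- order(sev, ifelse(is.na(out$gene), "~", out$gene), out$variant_key)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rationale <- sprintf(
    "carried by all affected, %d unaffected carrier(s); %s %s",
    out$unaffected_carriers, out$pathogenicity, out$consequence)
  rownames(out) <- NULL
  out[, c("rank", "variant_key", "gene", "consequence", "pathogenicity",
          "unaffected_carriers", "rationale")]
}

#' Carrier-by-affection cross table for one variant
#'
#' @param panel genotype panel as in [cosegregating_variants()].
#' @param variant variant_key of the variant to tabulate.
#' @return list with `counts`, a 2x2 integer matrix (rows carrier /
#'   non_carrier, columns affected / unaffected; unknown genotypes
#'   excluded), and `flagged`, the subject ids of unaffected carriers —
#'   the reduced-penetrance cases.
#' @export
penetrance_report <- function(panel, variant) {
  stopifnot(all(c("subject_id", "affected", "variant_key", "carrier")
                %in% names(panel)))
  pv <- panel[panel$variant_key == variant & !is.na(panel$carrier), ,
              drop = FALSE]
  if (nrow(pv) == 0) stop("no known genotypes for variant ", variant)
  aff <- as.logical(pv$affected)
  car <- pv$carrier == 1
  counts <- matrix(c(sum(car & aff), sum(car & !aff),
                     sum(!car & aff), sum(!car & !aff)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("carrier", "non_carrier"),
                                   c("affected", "unaffected")))
  list(counts = counts, flagged = pv$subject_id[car & !aff])
}
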