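# Tumour-microenvironment scoring: marker selection from reference
# immune-cell expression profiles (ARS/MES), disjoint per-cell-type
# signatures, single-sample gene-set enrichment (ssGSEA) and
# permutation presence calls.

#' The eight modelled immune cell types
#' @export
IMMUNE_CELL_TYPES <- c("CD8_T", "CD4_T", "B", "NK", "Monocyte",
                       "Macrophage", "Neutrophil", "Treg")

# mid-ranked rank of `cell_type` among the columns of dataset `prof`
# for `gene`, by descending expression; NA when the gene is absent
.target_rank <- function(prof, gene, cell_type) {
  if (!gene %in% rownames(prof)) return(NA_real_)
  x <- prof[gene, ]
  rank(-x, ties.method = "average")[[cell_type]]
}

#' Average Rank Score: cell-type selectivity of a marker gene
#'
#' For each reference dataset, cell types are ranked by the gene's
#' expression (descending, ties mid-ranked); the per-dataset score is
#' `(C - r) / (C - 1)` for target rank `r` among `C` cell types (1 when
#' the gene tops its own cell type, 0 when it ranks last).  ARS is the
#' mean over datasets; a high ARS means the gene is selectively highly
#' expressed in the target cell type.
#'
#' @param ref_profiles list of reference datasets, each a genes x
#'   cell-types numeric matrix (rownames = genes).
#' @param gene gene symbol.
#' @param cell_type target cell type (a column name).
#' @return ARS in \[0, 1\] with attribute `D_effective`, the number of
#'   datasets containing the gene (absent datasets are skipped).
#' @export
average_rank_score <- function(ref_profiles, gene, cell_type) {
  r <- vapply(ref_profiles, .target_rank, numeric(1), gene = gene,
              cell_type = cell_type)
  C <- vapply(ref_profiles, ncol, integer(1))
  ok <- !is.na(r)
  if (!any(ok)) stop("gene ", gene, " absent from every reference dataset")
  structure(mean((C[ok] - r[ok]) / (C[ok] - 1)), D_effective = sum(ok))
}

#' Marker Evaluation Score: cross-dataset stability of a marker gene
#'
#' Fraction of reference datasets in which the gene's target cell type
#' ranks first (strictly; a tie for the top gives a mid-rank > 1 and
#' does not count).  A high MES means the marker behaves consistently
#' across independent expression datasets.
#'
#' @inheritParams average_rank_score
#' @return MES in \[0, 1\] with attribute `D_effective`; a warning is
#'   issued when fewer than 2 datasets contain the gene.
#' @export
marker_evaluation_score <- function(ref_profiles, gene, cell_type) {
  r <- vapply(ref_profiles, .target_rank, numeric(1), gene = gene,
              cell_type = cell_type)
  ok <- !is.na(r)
  if (!any(ok)) stop("gene ", gene, " absent from every reference dataset")
  if (sum(ok) < 2)
    warning("gene ", gene, " present in fewer than 2 datasets; ",
            "marker stability cannot be assessed")
  structure(mean(r[ok] == 1), D_effective = sum(ok))
}

#' Select disjoint cell-type marker signatures from reference profiles
#'
#' A gene enters the signature of a cell type when both its ARS and MES
#' for that type pass the thresholds.  A gene qualifying for more than
#' one type is assigned to the type with the highest ARS (and dropped
#' entirely on an exact tie), so signatures are pairwise disjoint by
#' construction.  Each signature is truncated to `max_genes_per_type`
#' genes by descending ARS (gene name as deterministic tie-break).
#'
#' @inheritParams average_rank_score
#' @param ars_min,mes_min inclusion thresholds in (0, 1\]
#'   (defaults 0.8 and 0.5).
#' @param max_genes_per_type signature size cap (default 25).
#' @param cell_types cell types to build signatures for; default the
#'   column names of the first dataset.
#' @return object of class `signature_set`: list with `signatures`
#'   (named list of gene vectors) and `scores` (data.frame gene,
#'   cell_type, ars, mes for the selected genes).
#' @export
select_signatures <- function(ref_profiles, ars_min = 0.8, mes_min = 0.5,
                              max_genes_per_type = 25,
                              cell_types = colnames(ref_profiles[[1]])) {
  stopifnot(ars_min > 0, ars_min <= 1, mes_min > 0, mes_min <= 1)
  genes <- sort(unique(unlist(lapply(ref_profiles, rownames))))
  # per-dataset rank matrices (genes x types), descending expression
  ars_sum <- mes_sum <- d_eff <-
    matrix(0, length(genes), length(cell_types),
           dimnames = list(genes, cell_types))
  for (prof in ref_profiles) {
    C <- ncol(prof)
    rk <- t(apply(prof, 1, function(x) rank(-x, ties.method = "average")))
    colnames(rk) <- colnames(prof)
    g <- intersect(genes, rownames(prof))
    ct <- intersect(cell_types, colnames(prof))
    ars_sum[g, ct] <- ars_sum[g, ct] + (C - rk[g, ct]) / (C - 1)
    mes_sum[g, ct] <- mes_sum[g, ct] + (rk[g, ct] == 1)
    d_eff[g, ct] <- d_eff[g, ct] + 1
  }
  ars <- ars_sum / d_eff
  mes <- mes_sum / d_eff
  qualifies <- !is.na(ars) & ars >= ars_min & mes >= mes_min
  sel <- list()
  rows <- list()
  # assign each qualifying gene to its max-ARS type; drop on exact tie
  assigned_type <- rep(NA_character_, length(genes))
  names(assigned_type) <- genes
  for (g in genes) {
    q <- which(qualifies[g, ])
    if (!length(q)) next
    a <- ars[g, q]
    top <- which(a == max(a))
    if (length(top) > 1) next  # ambiguous marker, dropped entirely
    assigned_type[g] <- cell_types[q[top]]
  }
  for (ct in cell_types) {
    g <- names(assigned_type)[!is.na(assigned_type) & assigned_type == ct]
    if (!length(g))
      stop("no qualifying marker genes for cell type ", ct)
    ord <- order(-ars[g, ct], g)
    g <- g[ord][seq_len(min(length(g), max_genes_per_type))]
    sel[[ct]] <- g
    rows[[ct]] <- data.frame(gene = g, cell_type = ct, ars = ars[g, ct],
                             mes = mes[g, ct], row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  signature_set(sel, scores = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Construct a validated signature set
#'
#' @param signatures named list of per-cell-type gene vectors; must be
#'   pairwise disjoint.
#' @param scores optional per-gene score table.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(signatures, scores = NULL) {
  all_genes <- unlist(signatures, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("signatures are not disjoint: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  structure(list(signatures = signatures, scores = scores),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:",
      paste(sprintf("%s (%d)", names(x$signatures),
                    lengths(x$signatures)), collapse = ", "), "\n")
  invisible(x)
}

# sort a named expression vector descending, ties broken by gene name
.sorted_genes <- function(expression_vector) {
  stopifnot(!is.null(names(expression_vector)))
  nm <- names(expression_vector)
  nm[order(-expression_vector, nm)]
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Genes are sorted by expression (descending; ties broken by gene name
#' for determinism) and the score is the integrated difference between
#' the weighted empirical CDF of the signature genes and the uniform
#' ECDF of the remaining genes.  With rank weight `r_j = N - j + 1` for
#' the gene at sorted position j:
#' `P_in(i) = sum(r^alpha over signature genes at pos <= i) / sum over all
#' signature genes`, `P_out(i) = #(non-signature genes at pos <= i) /
#' (N - |G|)`, and `es = sum_i (P_in(i) - P_out(i))`.
#'
#' Being rank-based, the score is invariant under strictly monotone
#' transforms of the expression values.
#'
#' @param expression_vector named non-negative numeric vector (one
#'   sample).
#' @param signature character vector of signature genes; must overlap
#'   the expression genes and must not cover all of them.
#' @param alpha rank-weight exponent (default 0.25; 0 gives the
#'   unweighted Kolmogorov-style running sum).
#' @return the enrichment score (numeric scalar).
#' @export
ssgsea_score <- function(expression_vector, signature, alpha = 0.25) {
  if (any(expression_vector < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  sorted <- .sorted_genes(expression_vector)
  N <- length(sorted)
  in_set <- sorted %in% signature
  g <- sum(in_set)
  if (g == 0) stop("signature shares no genes with the expression vector")
  if (g == N) stop("signature covers every gene; score undefined")
  w <- (N:1) ^ alpha
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (N - g)
  sum(p_in - p_out)
}

# closed-form ssGSEA for a signature given by sorted positions; equal to
# ssgsea_score (summing each gene's contribution over all i >= its
# position), used in the permutation loop where O(N) per draw matters
.es_from_positions <- function(pos_in, N, alpha) {
  w <- (N - pos_in + 1) ^ alpha
  a <- (N - pos_in + 1) ^ (1 + alpha)
  tot_b <- N * (N + 1) / 2
  sum(a) / sum(w) - (tot_b - sum(N - pos_in + 1)) / (N - length(pos_in))
}

#' Immune-cell presence calls from ssGSEA scores and a permutation null
#'
#' For each cell type, the observed ssGSEA score of its signature is
#' compared with a null distribution of scores for `n_perm` random gene
#' sets of the same size (gene-label permutation).  The empirical
#' p-value uses the add-one estimator `(1 + #(null >= es)) / (n_perm +
#' 1)`; a cell type is called present when `p_perm < alpha_level`.
#'
#' @param expression_vector named non-negative expression vector (one
#'   tumour sample).
#' @param signature_set a [signature_set()].
#' @param n_perm number of permutations (>= 100).
#' @param alpha_level presence threshold on the permutation p-value
#'   (default 0.05).
#' @param seed RNG seed for reproducible permutations.
#' @param alpha ssGSEA rank-weight exponent.
#' @return data.frame of class `immune_scores`: cell_type, es,
#'   null_mean, null_sd, p_perm, present.
#' @export
call_presence <- function(expression_vector, signature_set, n_perm = 1000,
                          alpha_level = 0.05, seed = NULL, alpha = 0.25) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  stopifnot(inherits(signature_set, "signature_set"))
  sorted <- .sorted_genes(expression_vector)
  N <- length(sorted)
  with_seed(seed, {
    rows <- lapply(names(signature_set$signatures), function(ct) {
      sig <- intersect(signature_set$signatures[[ct]], sorted)
      es <- ssgsea_score(expression_vector, sig, alpha = alpha)
      g <- length(sig)
      null <- vapply(seq_len(n_perm), function(i)
        .es_from_positions(sample.int(N, g), N, alpha), numeric(1))
      p <- (1 + sum(null >= es)) / (n_perm + 1)
      data.frame(cell_type = ct, es = es, null_mean = mean(null),
                 null_sd = stats::sd(null), p_perm = p,
                 present = p < alpha_level, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("immune_scores", "data.frame")
    out
  })
}

#' Checkpoint and antigen-presentation expression report
#'
#' Tabulates tumour FPKM for immune-checkpoint genes and the
#' HLA/peptide-transport machinery, flagging genes below 1 FPKM — the
#' pattern of a T-cell-infiltrated but unengaged microenvironment is
#' uniformly low checkpoint expression alongside modest HLA/TAP levels.
#'
#' @param expression_records data.frame with columns gene, fpkm.
#' @param checkpoint_genes checkpoint markers (defaults: PDCD1 (PD-1),
#'   CD274 (PD-L1), CTLA4, HAVCR2 (TIM-3), LAG3).
#' @param presentation_genes antigen-presentation genes (defaults:
#'   TAP1, TAP2, HLA-A, HLA-B, HLA-C).
#' @return data.frame gene, category, fpkm (NA when the gene is missing
#'   from the table), low (fpkm < 1; NA propagates).
#' @export
checkpoint_report <- function(expression_records,
                              checkpoint_genes = c("PDCD1", "CD274",
                                                   "CTLA4", "HAVCR2",
                                                   "LAG3"),
                              presentation_genes = c("TAP1", "TAP2",
                                                     "HLA-A", "HLA-B",
                                                     "HLA-C")) {
  genes <- c(checkpoint_genes, presentation_genes)
  category <- rep(c("checkpoint", "presentation"),
                  c(length(checkpoint_genes), length(presentation_genes)))
  idx <- match(genes, expression_records$gene)
  fpkm <- expression_records$fpkm[idx]
  data.frame(gene = genes, category = category, fpkm = fpkm,
             low = fpkm < 1, stringsAsFactors = FALSE)
}
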