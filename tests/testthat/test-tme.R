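cell8 <- IMMUNE_CELL_TYPES

# one-gene dataset in which the target cell type takes a chosen rank
rank_profile <- function(gene, target, target_rank, C = 8) {
  x <- seq(C, 1)                       # descending values, rank = index
  others <- setdiff(cell8[1:C], target)
  vals <- stats::setNames(numeric(C), cell8[1:C])
  vals[target] <- x[target_rank]
  vals[others] <- x[-target_rank]
  matrix(vals, nrow = 1, dimnames = list(gene, names(vals)))
}

test_that("average rank score rewards selectively high expression", {
  top <- list(rank_profile("g", "CD8_T", 1), rank_profile("g", "CD8_T", 1))
  expect_equal(as.numeric(average_rank_score(top, "g", "CD8_T")), 1)
  bottom <- list(rank_profile("g", "CD8_T", 8), rank_profile("g", "CD8_T", 8))
  expect_equal(as.numeric(average_rank_score(bottom, "g", "CD8_T")), 0)
  mixed <- list(rank_profile("g", "CD8_T", 1), rank_profile("g", "CD8_T", 3))
  expect_equal(as.numeric(average_rank_score(mixed, "g", "CD8_T")),
               (1 + 5 / 7) / 2, tolerance = 1e-12)
})

test_that("marker evaluation score is the fraction of datasets where the
          target tops the ranking", {
  p1 <- rank_profile("g", "B", 1)
  p2 <- rank_profile("g", "B", 2)
  expect_equal(as.numeric(marker_evaluation_score(list(p1, p1, p1), "g", "B")), 1)
  expect_equal(as.numeric(marker_evaluation_score(list(p1, p2), "g", "B")), 0.5)
  expect_equal(as.numeric(marker_evaluation_score(list(p2, p2), "g", "B")), 0)
  expect_warning(marker_evaluation_score(list(p1), "g", "B"), "fewer than 2")
  expect_error(average_rank_score(list(p1), "missing", "B"), "absent")
})

test_that("datasets missing a gene are skipped with D_effective reported", {
  p_with <- rank_profile("g", "NK", 1)
  p_without <- rank_profile("other", "NK", 4)
  ars <- average_rank_score(list(p_with, p_without), "g", "NK")
  expect_equal(as.numeric(ars), 1)
  expect_equal(attr(ars, "D_effective"), 1L)
})

test_that("signature selection recovers planted exclusive markers, disjoint
          and ranked first", {
  rp <- simulate_reference_profiles(n_datasets = 3, markers_per_type = 10,
                                    seed = 11)
  sg <- select_signatures(rp$profiles)
  all_genes <- unlist(sg$signatures, use.names = FALSE)
  expect_equal(anyDuplicated(all_genes), 0)
  for (ct in cell8) {
    expect_true(all(rp$truth[[ct]] %in% sg$signatures[[ct]]),
                info = ct)
    # planted markers are perfect: ARS 1 and MES 1 in every dataset
    sc <- sg$scores[sg$scores$gene %in% rp$truth[[ct]], ]
    expect_equal(sc$ars, rep(1, 10))
    expect_equal(sc$mes, rep(1, 10))
  }
  expect_true(all(sg$scores$ars >= 0.8 & sg$scores$mes >= 0.5))
})

test_that("multi-type qualifiers go to the max-ARS type, exact ties and
          single-criterion genes are dropped", {
  # per-gene rank order across the 8 types -> expression row
  gene_row <- function(order8) stats::setNames(seq(8, 1), order8)[cell8]
  others <- cell8[3:8]
  mk <- function(q_order) rbind(
    fa = gene_row(c("CD8_T", "CD4_T", others)),   # exclusive CD8_T marker
    fb = gene_row(c("CD4_T", "CD8_T", others)),   # exclusive CD4_T marker
    s  = gene_row(c("B", "CD8_T", cell8[c(2, 4:8)])),  # always 2nd: MES 0
    q  = gene_row(q_order))
  # q: top CD8_T in ds1, top CD4_T with CD8_T third in ds2
  ds1 <- mk(c("CD8_T", "CD4_T", others))
  ds2 <- mk(c("CD4_T", "B", "CD8_T", cell8[c(4:8)]))
  sgl <- select_signatures(list(ds1, ds2), ars_min = 0.5, mes_min = 0.5,
                           cell_types = cell8[1:2])
  # q qualifies for both types (MES 0.5 each); ARS CD4_T (1+6/7)/2 beats
  # ARS CD8_T (1+5/7)/2, so q lands in CD4_T only
  expect_equal(sgl$signatures$CD4_T, c("fb", "q"))
  expect_equal(sgl$signatures$CD8_T, "fa")
  # gene s has high ARS for CD8_T but never tops it: excluded everywhere
  expect_false("s" %in% unlist(sgl$signatures))
  # exact ARS tie across the two types: q dropped entirely
  ds2_tie <- mk(c("CD4_T", "CD8_T", others))
  sgl_tie <- select_signatures(list(ds1, ds2_tie), ars_min = 0.5,
                               mes_min = 0.5, cell_types = cell8[1:2])
  expect_false("q" %in% unlist(sgl_tie$signatures))
  # a cell type with no qualifying gene is a hard error naming the type
  expect_error(select_signatures(list(ds1, ds2), ars_min = 0.5,
                                 mes_min = 0.5,
                                 cell_types = cell8[c(1, 2, 4)]),
               "cell type NK")
})

test_that("ssGSEA reproduces the hand-computed ECDF worked example", {
  ev <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  # G at sorted positions 1 and 3, alpha 0: P_in (.5,.5,1,1),
  # P_out (0,.5,.5,1) -> es = .5 + 0 + .5 + 0 = 1
  expect_equal(ssgsea_score(ev, c("g1", "g3"), alpha = 0), 1)
})

test_that("ssGSEA agrees exactly with the brute-force double-loop oracle", {
  set.seed(55)
  for (rep in 1:40) {
    N <- sample(5:50, 1)
    genes <- sprintf("g%03d", seq_len(N))
    ev <- stats::setNames(round(rexp(N, 0.1), 2), genes)
    g <- sample(1:(N - 1), 1)
    sig <- sample(genes, g)
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(ev, sig, alpha = alpha),
                 oracle_ssgsea(ev, sig, alpha), tolerance = 1e-10)
  }
})

test_that("ssGSEA is rank-based: invariant under monotone transforms and
          maximal for the top block", {
  set.seed(66)
  genes <- sprintf("g%03d", 1:100)
  ev <- stats::setNames(runif(100, 0.1, 50), genes)
  sig <- sample(genes, 12)
  base <- ssgsea_score(ev, sig)
  expect_equal(ssgsea_score(log(ev), sig), base)
  expect_equal(ssgsea_score(ev^2, sig), base)
  top_sig <- names(sort(ev, decreasing = TRUE))[1:12]
  top_es <- ssgsea_score(ev, top_sig)
  for (i in 1:25)
    expect_lte(ssgsea_score(ev, sample(genes, 12)), top_es)
})

test_that("ssGSEA rejects degenerate signatures", {
  ev <- c(a = 3, b = 2, c = 1)
  expect_error(ssgsea_score(ev, c("x", "y")), "no genes")
  expect_error(ssgsea_score(ev, c("a", "b", "c")), "every gene")
})

test_that("mean ssGSEA over random same-size signatures is centred on zero", {
  set.seed(77)
  genes <- sprintf("g%03d", 1:60)
  ev <- stats::setNames(rexp(60), genes)
  es <- vapply(1:400, function(i) ssgsea_score(ev, sample(genes, 8),
                                               alpha = 0), numeric(1))
  se <- sd(es) / sqrt(length(es))
  expect_lt(abs(mean(es)), 3 * se + 1e-9)
})

test_that("presence calls find planted cell types and clear absent ones", {
  rp <- simulate_reference_profiles(seed = 21)
  sg <- select_signatures(rp$profiles)
  mix <- simulate_immune_mixture(sg, c(CD8_T = 0.4, Monocyte = 0.25),
                                 seed = 22)
  ps <- call_presence(mix$expression, sg, n_perm = 200, seed = 23)
  expect_s3_class(ps, "immune_scores")
  expect_true(ps$present[ps$cell_type == "CD8_T"])
  expect_true(ps$present[ps$cell_type == "Monocyte"])
  expect_false(ps$present[ps$cell_type == "B"])
  expect_false(ps$present[ps$cell_type == "NK"])
  expect_true(all(ps$p_perm > 0 & ps$p_perm <= 1))
  expect_equal(ps$present, ps$p_perm < 0.05)
  expect_error(call_presence(mix$expression, sg, n_perm = 0), "at least 100")
})

test_that("increasing the planted CD8 proportion never lowers the CD8
          enrichment score", {
  rp <- simulate_reference_profiles(seed = 31)
  sg <- select_signatures(rp$profiles)
  es <- vapply(c(0, 0.1, 0.3), function(p) {
    mix <- simulate_immune_mixture(sg, c(CD8_T = p), seed = 32)
    ssgsea_score(mix$expression, sg$signatures$CD8_T)
  }, numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("the checkpoint/presentation report flags sub-1-FPKM genes and
          emits NA rows for missing genes", {
  expr <- data.frame(gene = c("PDCD1", "CD274", "CTLA4", "HAVCR2", "LAG3",
                              "TAP1"),
                     fpkm = c(0.3, 0.3, 0.3, 0.3, 0.3, 5))
  rep <- checkpoint_report(expr)
  expect_equal(nrow(rep), 10)
  expect_true(all(rep$low[rep$category == "checkpoint"]))
  expect_false(rep$low[rep$gene == "TAP1"])
  expect_true(is.na(rep$fpkm[rep$gene == "HLA-A"]))
  expect_true(is.na(rep$low[rep$gene == "HLA-A"]))
})
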