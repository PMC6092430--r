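# Synthetic-data generators.  Every generator is a pure function of
# (parameters, seed): identical seeds give identical outputs, and each
# returns a truth ledger for recovery testing.  Defaults reflect the
# study conditions the pipeline targets: a 4-member affected/unaffected
# genotype panel with one planted pathogenic frameshift and 6 benign
# shared missense variants; 959 somatic variants with a 69% missense /
# 30% indel / 1% nonsense class mix; ~200x sequencing depth; tumour
# purity 0.6; 23% of mutated genes expressed.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a coding reference (transcripts + annotation)
#'
#' Random CDSs starting with ATG, ending with a stop codon and free of
#' internal stops, with lengths (in codons) scattered around
#' `mean_cds_len / 3`.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param mean_cds_len mean CDS length in nucleotides (>= 30; realized
#'   lengths are multiples of 3).
#' @param seed RNG seed.
#' @return list of class `reference_set` with `transcripts` (named
#'   character vector of CDS) and `annotation` (data.frame
#'   transcript_id, gene, cds_len).
#' @export
simulate_reference <- function(n_transcripts = 20, mean_cds_len = 300,
                               seed = NULL) {
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (mean_cds_len < 30) stop("mean_cds_len must be >= 30")
  with_seed(seed, {
    mean_codons <- round(mean_cds_len / 3)
    n_codons <- pmax(10L, stats::rpois(n_transcripts, mean_codons))
    ids <- sprintf("TX%04d", seq_len(n_transcripts))
    genes <- sprintf("GENE%04d", seq_len(n_transcripts))
    seqs <- vapply(n_codons, function(nc)
      paste(c("ATG", sample(SENSE_CODONS, nc - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L)), collapse = ""), character(1))
    names(seqs) <- ids
    structure(list(transcripts = seqs,
                   annotation = data.frame(transcript_id = ids, gene = genes,
                                           cds_len = 3L * n_codons,
                                           stringsAsFactors = FALSE)),
              class = "reference_set")
  })
}

#' Simulate a family genotype panel with one planted causal variant
#'
#' Emulates the informative pedigree comparison: a pathogenic germline
#' frameshift carried by exactly the affected members, against a
#' background of benign missense variants shared by every member (the
#' situation in mismatch-repair gene panels, where common benign
#' missense variants are present family-wide).
#'
#' @param n_affected,n_unaffected panel composition (each >= 1; the
#'   default 2 + 2 is the informative-subset design).
#' @param n_benign_shared number of benign missense variants carried by
#'   all subjects (default 6).
#' @param seed RNG seed.
#' @param unaffected_carrier if TRUE, one unaffected subject also
#'   carries the causal variant (reduced-penetrance negative control).
#' @return list with `panel` (long data.frame subject_id, affected,
#'   variant_key, carrier), `variants` (a `variant_table`), and `truth`
#'   (causal variant key and gene).
#' @export
simulate_family <- function(n_affected = 2, n_unaffected = 2,
                            n_benign_shared = 6, seed = NULL,
                            unaffected_carrier = FALSE) {
  stopifnot(n_affected >= 1, n_unaffected >= 1, n_benign_shared >= 0)
  with_seed(seed, {
    mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2", "PMS1", "MSH3", "EXO1",
                   "POLD1", "POLE")
    n_var <- n_benign_shared + 1L
    genes <- sample(mmr_genes, n_var, replace = n_var > length(mmr_genes))
    pos <- sort(sample.int(5e7, n_var))
    ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    causal <- sample.int(n_var, 1)
    # causal variant is a 1-bp frameshift deletion (anchored VCF style)
    ref[causal] <- paste0(ref[causal],
                          sample(c("A", "C", "G", "T"), 1))
    alt[causal] <- substr(ref[causal], 1, 1)
    df <- data.frame(chrom = "chr3", pos = pos, ref = ref, alt = alt,
                     gene = genes,
                     consequence = replace(rep("missense", n_var), causal,
                                           "frameshift"),
                     origin = "germline",
                     pathogenicity = replace(rep("benign", n_var), causal,
                                             "pathogenic"),
                     stringsAsFactors = FALSE)
    variants <- variant_table(df)
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_affected + n_unaffected)),
      affected = rep(c(TRUE, FALSE), c(n_affected, n_unaffected)),
      stringsAsFactors = FALSE)
    panel <- merge(subjects, data.frame(variant_key = variants$variant_key),
                   by = NULL)
    panel$carrier <- 1L
    causal_key <- variants$variant_key[causal]
    panel$carrier[panel$variant_key == causal_key & !panel$affected] <- 0L
    if (unaffected_carrier) {
      u <- subjects$subject_id[!subjects$affected][1]
      panel$carrier[panel$variant_key == causal_key &
                      panel$subject_id == u] <- 1L
    }
    list(panel = panel[, c("subject_id", "affected", "variant_key",
                           "carrier")],
         variants = variants,
         truth = list(causal_key = causal_key, causal_gene = genes[causal]))
  })
}

# one random SNV inside codons 2..(last-1) of a CDS with the requested
# translated effect ("missense" or "nonsense"); returns list(pos, ref, alt)
.place_snv <- function(cds, effect) {
  gc <- codon_table()
  n_codon <- nchar(cds) %/% 3L
  repeat {
    ci <- sample(2:(n_codon - 1L), 1)
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    offs <- sample.int(3, 3)
    done <- FALSE
    for (o in offs) {
      for (b in sample(setdiff(c("A", "C", "G", "T"),
                               substr(codon, o, o)))) {
        mut <- codon
        substr(mut, o, o) <- b
        aa_wt <- gc[[codon]]
        aa_mut <- gc[[mut]]
        hit <- if (effect == "nonsense") aa_mut == "*"
               else aa_mut != aa_wt && aa_mut != "*"
        if (hit)
          return(list(pos = 3L * ci - 3L + o, ref = substr(codon, o, o),
                      alt = b))
      }
    }
  }
}

#' Simulate a somatic variant set with depths and expression
#'
#' Draws each variant's class from a multinomial over missense / indel
#' (frameshift) / nonsense, places it consistently on a simulated
#' transcript, and attaches blood and tumour-DNA allele depths drawn
#' around the tumour purity.  Mutated genes are expressed (FPKM >= 1)
#' with probability `expressed_fraction`, the remainder below 1 FPKM.
#'
#' @param reference a `reference_set` from [simulate_reference()].
#' @param n_variants number of somatic variants (default 959, a
#'   hypermutated mismatch-repair-deficient panel burden).
#' @param class_probs named probabilities for (missense, indel,
#'   nonsense); renormalized to sum to 1.  Default c(0.69, 0.30, 0.01).
#' @param expressed_fraction probability a mutated gene is expressed in
#'   the tumour (default 0.23).
#' @param purity tumour purity; heterozygous somatic variants have mean
#'   tumour allele fraction `purity / 2` (default 0.6).
#' @param mean_depth mean sequencing depth (default 200).
#' @param seed RNG seed.
#' @return list with `variants` (a `variant_table` with blood and
#'   tumour_dna depths), `expression` (data.frame gene, fpkm), and
#'   `truth` (class per variant, expressed genes).
#' @export
simulate_somatic <- function(reference, n_variants = 959,
                             class_probs = c(missense = 0.69, indel = 0.30,
                                             nonsense = 0.01),
                             expressed_fraction = 0.23, purity = 0.6,
                             mean_depth = 200, seed = NULL) {
  stopifnot(n_variants >= 0, expressed_fraction >= 0,
            expressed_fraction <= 1)
  if (is.null(names(class_probs)))
    names(class_probs) <- c("missense", "indel", "nonsense")
  probs <- class_probs / sum(class_probs)
  with_seed(seed, {
    ann <- reference$annotation
    if (n_variants == 0) {
      variants <- variant_table(
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), stringsAsFactors = FALSE))
      return(list(variants = variants,
                  expression = data.frame(gene = character(),
                                          fpkm = numeric()),
                  truth = list(classes = character(0),
                               expressed_genes = character(0))))
    }
    cls <- sample(names(probs), n_variants, replace = TRUE, prob = probs)
    ti <- sample.int(nrow(ann), n_variants, replace = TRUE)
    make_row <- function(class, tx_idx) {
      cds <- reference$transcripts[[ann$transcript_id[tx_idx]]]
      if (class %in% c("missense", "nonsense")) {
        mv <- .place_snv(cds, class)
        cons <- class
      } else {
        # 1-2 bp frameshift indel, anchored VCF style, away from the
        # start and stop codons
        p <- sample(4:(nchar(cds) - 6L), 1)
        L <- sample(1:2, 1)
        if (stats::runif(1) < 0.5) {
          mv <- list(pos = p, ref = substr(cds, p, p + L),
                     alt = substr(cds, p, p))
        } else {
          mv <- list(pos = p, ref = substr(cds, p, p),
                     alt = paste0(substr(cds, p, p),
                                  paste(sample(c("A", "C", "G", "T"), L,
                                               replace = TRUE),
                                        collapse = "")))
        }
        cons <- "frameshift"
      }
      data.frame(
        chrom = "chr1", pos = tx_idx * 100000L + mv$pos, ref = mv$ref,
        alt = mv$alt, gene = ann$gene[tx_idx],
        transcript_id = ann$transcript_id[tx_idx],
        cds_pos = mv$pos, consequence = cons, origin = "somatic",
        pathogenicity = "unannotated", stringsAsFactors = FALSE)
    }
    rows <- lapply(seq_len(n_variants),
                   function(i) make_row(cls[i], ti[i]))
    df <- do.call(rbind, rows)
    # genomic position = transcript offset + CDS position; colliding
    # placements are re-drawn so the output has exactly n_variants
    # distinct alleles
    key <- paste(df$pos, df$ref, df$alt)
    for (iter in 1:100) {
      dup <- which(duplicated(key))
      if (!length(dup)) break
      for (d in dup) {
        rows[[d]] <- make_row(cls[d], ti[d])
        df[d, ] <- rows[[d]]
      }
      key <- paste(df$pos, df$ref, df$alt)
    }
    if (anyDuplicated(key))
      stop("could not place ", n_variants, " distinct variants on this ",
           "reference; increase n_transcripts or mean_cds_len")
    # depths: tumour allele fraction Beta around purity/2, blood ~ 0
    n <- nrow(df)
    kappa <- 40
    m <- purity / 2
    vaf <- stats::rbeta(n, m * kappa, (1 - m) * kappa)
    tot_t <- stats::rpois(n, mean_depth)
    tot_b <- stats::rpois(n, mean_depth)
    alt_t <- stats::rbinom(n, tot_t, vaf)
    alt_b <- stats::rbinom(n, tot_b, 0.001)
    df$ad_ref.blood <- tot_b - alt_b
    df$ad_alt.blood <- alt_b
    df$ad_ref.tumour_dna <- tot_t - alt_t
    df$ad_alt.tumour_dna <- alt_t
    variants <- variant_table(df)
    genes <- unique(df$gene)
    expressed <- stats::runif(length(genes)) < expressed_fraction
    fpkm <- ifelse(expressed, 1 + stats::rlnorm(length(genes), 1.5, 1),
                   stats::runif(length(genes), 0, 0.99))
    list(variants = variants,
         expression = data.frame(gene = genes, fpkm = fpkm,
                                 stringsAsFactors = FALSE),
         truth = list(classes = cls,
                      expressed_genes = genes[expressed]))
  })
}

#' Simulate reference immune-cell expression profiles
#'
#' `n_datasets` independent genes x cell-types matrices with
#' `markers_per_type` exclusive marker genes per cell type (high in
#' their own type, low elsewhere) plus non-specific background genes —
#' the substrate from which [select_signatures()] should recover the
#' planted markers.
#'
#' @param n_datasets number of independent reference datasets
#'   (default 3).
#' @param markers_per_type planted exclusive markers per cell type
#'   (default 10).
#' @param n_other_genes non-marker background genes (default 200).
#' @param cell_types cell-type names (default the eight modelled types).
#' @param noise_sd lognormal noise sd on all values (default 0.25).
#' @param seed RNG seed.
#' @return list with `profiles` (list of matrices) and `truth` (named
#'   list of planted marker genes per type).
#' @export
simulate_reference_profiles <- function(n_datasets = 3,
                                        markers_per_type = 10,
                                        n_other_genes = 200,
                                        cell_types = IMMUNE_CELL_TYPES,
                                        noise_sd = 0.25, seed = NULL) {
  with_seed(seed, {
    markers <- lapply(cell_types, function(ct)
      sprintf("%s_M%02d", ct, seq_len(markers_per_type)))
    names(markers) <- cell_types
    other <- sprintf("BG%04d", seq_len(n_other_genes))
    genes <- c(unlist(markers, use.names = FALSE), other)
    C <- length(cell_types)
    profiles <- lapply(seq_len(n_datasets), function(d) {
      base <- matrix(2, length(genes), C,
                     dimnames = list(genes, cell_types))
      for (ct in cell_types) base[markers[[ct]], ct] <- 100
      base * matrix(stats::rlnorm(length(base), 0, noise_sd),
                    nrow(base), C)
    })
    list(profiles = profiles, truth = markers)
  })
}

#' Simulate a bulk tumour expression vector as an immune-cell mixture
#'
#' Signature genes of cell type c get expression
#' `base * proportion_c * lognormal noise` (plus a vanishing uniform
#' jitter so that absent cell types do not create massive rank ties);
#' background genes get iid lognormal noise at unit scale.
#'
#' @param signature_set a [signature_set()] (e.g. recovered from
#'   [simulate_reference_profiles()]).
#' @param proportions named non-negative mixing proportions per cell
#'   type (missing types default to 0).
#' @param n_background_genes iid background genes (default 500).
#' @param noise_sd lognormal noise sd (default 0.5).
#' @param base expression scale of a fully present cell type
#'   (default 100).
#' @param seed RNG seed.
#' @return list with `expression` (named numeric vector) and `truth`
#'   (the proportions used).
#' @export
simulate_immune_mixture <- function(signature_set, proportions,
                                    n_background_genes = 500,
                                    noise_sd = 0.5, base = 100,
                                    seed = NULL) {
  stopifnot(inherits(signature_set, "signature_set"),
            all(proportions >= 0))
  with_seed(seed, {
    sigs <- signature_set$signatures
    expr <- numeric(0)
    for (ct in names(sigs)) {
      p <- if (ct %in% names(proportions)) proportions[[ct]] else 0
      n <- length(sigs[[ct]])
      expr[sigs[[ct]]] <- base * p * stats::rlnorm(n, 0, noise_sd) +
        stats::runif(n, 0, 1e-3)
    }
    bg <- sprintf("BGX%04d", seq_len(n_background_genes))
    expr[bg] <- stats::rlnorm(n_background_genes, 0, 1)
    list(expression = expr, truth = list(proportions = proportions))
  })
}
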