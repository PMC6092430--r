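#' Percent alternate allele depth
#'
#' Fraction of reads supporting the alternate allele, expressed as a
#' percentage.  This is the quantity plotted when comparing blood
#' (germline) and tumour DNA/RNA support for the same variant, e.g. a
#' germline heterozygote near 38% versus a tumour with a second hit near
#' 73%.
#'
#' @param ref_count,alt_count non-negative integer read counts supporting
#'   the reference and alternate allele.  Vectorized; the two vectors are
#'   recycled to a common length.
#' @return numeric vector of percentages in \[0, 100\]:
#'   `100 * alt / (ref + alt)`.
#' @examples
#' percent_allele_depth(62, 38)  # 38
#' percent_allele_depth(27, 73)  # 73
#' @export
percent_allele_depth <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("allele depth counts must be non-negative")
  tot <- ref_count + alt_count
  if (any(tot == 0, na.rm = TRUE))
    stop("undefined allele depth: ref_count + alt_count is zero")
  100 * alt_count / tot
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return character key `chrom:pos:ref>alt`, unique per (split) allele.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "synonymous", "other")
PATHOGENICITY <- c("pathogenic", "benign", "VUS", "unannotated")

#' Construct a validated variant table
#'
#' The central container of the pipeline: one row per (chrom, pos, ref,
#' alt) allele, with annotation columns and per-assay allele depths in
#' paired columns `ad_ref.<assay>` / `ad_alt.<assay>` (assays are
#' free-form names such as `"blood"`, `"tumour_dna"`, `"tumour_rna"`).
#'
#' @param df data.frame with at least chrom, pos, ref, alt.  Missing
#'   annotation columns (gene, transcript_id, cds_pos, consequence,
#'   hgvs_p, origin, pathogenicity) are added as NA / defaults.
#' @return the data.frame with class `variant_table`, a `variant_key`
#'   column, and validated invariants (pos >= 1, ref != alt,
#'   depths >= 0).
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  df$pos <- as.integer(df$pos)
  if (nrow(df)) {
    if (any(df$pos < 1)) stop("variant pos must be >= 1")
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  }
  n <- nrow(df)
  for (col in c("gene", "transcript_id", "hgvs_p"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, n)
  if (is.null(df$cds_pos)) df$cds_pos <- rep(NA_integer_, n)
  if (is.null(df$consequence)) df$consequence <- rep("other", n)
  if (is.null(df$origin)) df$origin <- rep(NA_character_, n)
  if (is.null(df$pathogenicity)) df$pathogenicity <- rep("unannotated", n)
  bad <- !df$consequence %in% CONSEQUENCES
  if (any(bad)) stop("unknown consequence: ", df$consequence[which(bad)[1]])
  bad <- !df$pathogenicity %in% PATHOGENICITY
  if (any(bad)) stop("unknown pathogenicity: ", df$pathogenicity[which(bad)[1]])
  ad <- grep("^ad_(ref|alt)\\.", names(df), value = TRUE)
  for (col in ad) {
    df[[col]] <- as.integer(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative depth in ", col)
  }
  df$variant_key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  # pure indels with net length not divisible by 3 must be frameshift
  if (nrow(df)) {
    indel <- nchar(df$ref) != nchar(df$alt)
    net <- abs(nchar(df$ref) - nchar(df$alt))
    fs_expect <- indel & net %% 3L != 0L
    clash <- (df$consequence == "frameshift") != fs_expect &
      df$consequence %in% c("frameshift", "inframe_indel")
    if (any(clash))
      stop("indel length inconsistent with frameshift/inframe label: ",
           df$variant_key[which(clash)[1]])
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants, assays: %s\n", nrow(x),
              paste(assay_names(x), collapse = ", ")))
  NextMethod()
}

#' Assay names carried by a variant table
#' @param variants a `variant_table`.
#' @return character vector of assay names with depth columns.
#' @export
assay_names <- function(variants) {
  unique(sub("^ad_(ref|alt)\\.", "", grep("^ad_(ref|alt)\\.",
                                          names(variants), value = TRUE)))
}

#' Extract per-assay allele depths
#' @param variants a `variant_table`.
#' @param assay assay name, e.g. `"blood"`.
#' @return two-column integer matrix (ref, alt), one row per variant.
#' @export
get_depths <- function(variants, assay) {
  rc <- variants[[paste0("ad_ref.", assay)]]
  ac <- variants[[paste0("ad_alt.", assay)]]
  if (is.null(rc) || is.null(ac)) stop("no depth columns for assay ", assay)
  cbind(ref = rc, alt = ac)
}

#' Read variants from VCF with optional annotation
#'
#' Reads a VCF 4.2 file with per-sample AD (allele depth) fields.  Each
#' VCF sample becomes an assay.  Multi-allelic records are split into one
#' variant per ALT allele, with the matching component of each sample's
#' AD field.  Symbolic ALT alleles (e.g. `<DEL>`) are skipped with a
#' warning reporting the count.
#'
#' @param vcf_path path to a VCF file.
#' @param annotation optional annotation data.frame or TSV path with
#'   columns chrom, pos, ref, alt, gene, transcript_id, cds_pos,
#'   pathogenicity; matched by variant key.
#' @return a [variant_table()].
#' @export
read_variants <- function(vcf_path, annotation = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))  # single-record files come back as a bare vector
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  ad <- if (length(samples)) vcfR::extract.gt(v, element = "AD") else NULL
  if (!is.null(ad) && is.null(dim(ad)))
    ad <- matrix(ad, nrow = n, dimnames = list(NULL, samples))
  rows <- list()
  n_sym <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.null(ad)) {
      lapply(samples, function(s)
        suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]])))
    } else list()
    for (j in seq_along(alts)) {
      if (grepl("^<.*>$", alts[j]) || grepl("[\\[\\]]", alts[j])) {
        n_sym <- n_sym + 1L
        next
      }
      row <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                        ref = fix$REF[i], alt = alts[j],
                        stringsAsFactors = FALSE)
      for (si in seq_along(samples)) {
        counts <- ads[[si]]
        row[[paste0("ad_ref.", samples[si])]] <-
          if (length(counts) >= 1) counts[1] else NA_integer_
        row[[paste0("ad_alt.", samples[si])]] <-
          if (length(counts) >= j + 1) counts[j + 1] else NA_integer_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (n_sym > 0)
    warning(sprintf("skipped %d record(s) with symbolic/breakend ALT", n_sym))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    if (is.character(annotation)) annotation <- read_annotation(annotation)
    key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    akey <- variant_key(annotation$chrom, annotation$pos,
                        annotation$ref, annotation$alt)
    idx <- match(key, akey)
    for (col in c("gene", "transcript_id", "cds_pos", "pathogenicity"))
      if (!is.null(annotation[[col]])) df[[col]] <- annotation[[col]][idx]
    if (!is.null(df$pathogenicity))
      df$pathogenicity[is.na(df$pathogenicity)] <- "unannotated"
  }
  variant_table(df)
}

#' Write variants to a minimal VCF 4.2 file
#'
#' Emits one record per variant with a per-assay AD FORMAT field, the
#' exact inverse of [read_variants()] for the coordinate and depth
#' columns (annotation travels separately as a TSV).
#'
#' @param variants a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  assays <- assay_names(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(assays)) c("FORMAT", assays)),
                 collapse = "\t"))
  recs <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    fields <- c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
                variants$alt[i], ".", "PASS", ".")
    if (length(assays)) {
      fields <- c(fields, "AD",
                  vapply(assays, function(a)
                    paste(variants[[paste0("ad_ref.", a)]][i],
                          variants[[paste0("ad_alt.", a)]][i], sep = ","),
                    character(1)))
    }
    recs[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a variant annotation table
#'
#' @param path TSV with columns chrom, pos, ref, alt, gene,
#'   transcript_id, cds_pos, pathogenicity.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  df$pos <- as.integer(df$pos)
  if (!is.null(df$cds_pos)) df$cds_pos <- as.integer(df$cds_pos)
  df
}

#' Write the variant annotation TSV
#' @param variants a `variant_table` (or compatible data.frame).
#' @param path output path.
#' @export
write_annotation <- function(variants, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "transcript_id",
                      "cds_pos", "pathogenicity", "consequence"),
                    names(variants))
  utils::write.table(as.data.frame(variants)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coding transcripts from FASTA
#'
#' @param path FASTA file; record ids are transcript ids.  Sequences are
#'   expected on the coding strand.
#' @param validate check each CDS starts with ATG, ends with a stop codon
#'   and has length divisible by 3 (default TRUE).
#' @return named character vector of CDS sequences.
#' @export
read_transcripts <- function(path, validate = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (validate) {
    for (id in names(seqs)) {
      s <- seqs[[id]]
      if (nchar(s) %% 3 != 0)
        stop("CDS length of ", id, " not a multiple of 3")
      if (substr(s, 1, 3) != "ATG") stop("CDS of ", id, " must start ATG")
      last <- substr(s, nchar(s) - 2, nchar(s))
      if (!last %in% c("TAA", "TAG", "TGA"))
        stop("CDS of ", id, " must end with a stop codon")
    }
  }
  seqs
}

#' Write transcripts to FASTA
#' @param seqs named character vector of CDS sequences.
#' @param path output FASTA path.
#' @export
write_transcripts <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a gene-level expression table
#'
#' @param path TSV with columns gene, fpkm and optional rna_ref, rna_alt
#'   RNA allele-depth counts.
#' @return data.frame with non-negative fpkm.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("gene", "fpkm") %in% names(df)))
  if (any(df$fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative")
  df
}

#' Validate HLA class I allele names
#'
#' @param x character vector of 4-digit class I alleles,
#'   e.g. `"HLA-A*02:06"`.
#' @return `x` invisibly; errors on malformed names.
#' @export
validate_hla <- function(x) {
  bad <- !grepl("^HLA-[A-C]\\*[0-9]{2}:[0-9]{2}$", x)
  if (any(bad)) stop("malformed HLA allele name: ", x[which(bad)[1]])
  invisible(x)
}

# run generator code under a local, seeded RNG without disturbing the
# caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
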