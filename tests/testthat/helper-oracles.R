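# Independent oracles used across the suite.

# protein translation oracle: plain string surgery for the edit, then
# Biostrings::translate, cut at the first stop
oracle_edit <- function(cds, pos, ref, alt) {
  paste0(substr(cds, 1, pos - 1), alt, substr(cds, pos + nchar(ref),
                                              nchar(cds)))
}

oracle_translate <- function(seq) {
  n <- 3 * (nchar(seq) %/% 3)
  if (n == 0) return(structure("", terminated = FALSE))
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, n)), no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0)
    structure(substr(aa, 1, stop_at - 1), terminated = TRUE)
  else structure(aa, terminated = FALSE)
}

# brute-force double-loop ssGSEA ECDF oracle (the definitional form)
oracle_ssgsea <- function(expression_vector, signature, alpha) {
  nm <- names(expression_vector)
  sorted <- nm[order(-expression_vector, nm)]
  N <- length(sorted)
  in_set <- sorted %in% signature
  g <- sum(in_set)
  W <- sum((N - which(in_set) + 1) ^ alpha)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- 0
    n_out <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) p_in <- p_in + (N - j + 1) ^ alpha / W
      else n_out <- n_out + 1
    }
    es <- es + p_in - n_out / (N - g)
  }
  es
}

# brute-force k-mer window enumerator over the mutant protein: every
# full window overlapping the changed residue range
oracle_windows <- function(mut_protein, first_changed, k,
                           last_changed = nchar(mut_protein)) {
  out <- character(0)
  for (s in seq_len(max(nchar(mut_protein) - k + 1, 0))) {
    covers <- (s + k - 1) >= first_changed && s <= last_changed
    if (covers) out <- c(out, substr(mut_protein, s, s + k - 1))
  }
  out
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# random anchored frameshift indel (VCF style) inside a CDS
random_frameshift <- function(cds) {
  p <- sample(4:(nchar(cds) - 6L), 1)
  L <- sample(c(1, 2, 4), 1)  # net length change not divisible by 3
  if (runif(1) < 0.5 && p + L <= nchar(cds) - 3) {
    list(pos = p, ref = substr(cds, p, p + L), alt = substr(cds, p, p))
  } else {
    list(pos = p, ref = substr(cds, p, p),
         alt = paste0(substr(cds, p, p),
                      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")))
  }
}

# the four published wildtype/mutant 9-mer pair contexts, encoded as
# (wildtype fragment, mutant fragment, first changed residue): pairs are
# recovered as the k-mer window starting at position `window_start`
published_pair_contexts <- function() {
  list(
    MLH1 = list(wt = "TSIQVIVKEGAKITDLA", mut = "TSIQVIVKRWLAV",
                first_changed = 9, window_start = 1,
                wt_pep = "TSIQVIVKE", mut_pep = "TSIQVIVKR"),
    MSH6 = list(wt = "LLPEDTPPFKRARTSDA", mut = "LLPEDTPPLVKQ",
                first_changed = 9, window_start = 1,
                wt_pep = "LLPEDTPPF", mut_pep = "LLPEDTPPL"),
    PIGO = list(wt = "MAQADLDYVVPLAGHER", mut = "MAKLTWIMWSLGR",
                first_changed = 3, window_start = 3,
                wt_pep = "QADLDYVVP", mut_pep = "KLTWIMWSL"),
    AXIN2 = list(wt = "HLWGGNSGHARSLE", mut = "HLWGATAGTPRW",
                 first_changed = 5, window_start = 1,
                 wt_pep = "HLWGGNSGH", mut_pep = "HLWGATAGT"))
}
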