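# Fixtures are built in code. Genomic fixtures use a tiny hand-laid genome
# so expected codon mappings can be written down by eye.

# One chromosome carrying a plus-strand uORF (AUG AAA UAA at chr1:100-109,
# 0-based) and the same ORF mirrored on the minus strand at chr1:200-209.
make_tiny_genome <- function() {
  pre <- strrep("T", 100)                      # 0..99
  orf_plus <- "ATGAAATAA"                      # 100..108
  mid <- strrep("G", 200 - 109)                # 109..199
  orf_minus <- "TTATTTCAT"                     # revcomp(ATGAAATAA), 200..208
  post <- strrep("C", 60)
  c(chr1 = paste0(pre, orf_plus, mid, orf_minus, post))
}

tiny_orf_plus <- function() {
  orf_annotation("orfP", "txP", "chr1", "+", matrix(c(100L, 109L), ncol = 2),
                 "uORF", "AUGAAAUAA", cds_start_distance = 20L)
}

tiny_orf_minus <- function() {
  orf_annotation("orfM", "txM", "chr1", "-", matrix(c(200L, 209L), ncol = 2),
                 "uORF", "AUGAAAUAA", cds_start_distance = 20L)
}

# An ORF with an arbitrary codon placed at codon index 1 (internal), built
# on a fresh genome; used to exercise every codon substitution genomically.
orf_with_internal_codon <- function(codon_rna, strand = "+") {
  seq <- paste0("AUG", codon_rna, "AAACCCUAA")  # 5 internal-safe codons
  dna <- chartr("U", "T", seq)
  revcomp <- function(x) chartr("ACGTN", "TGCAN",
                                paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
  genomic <- if (strand == "+") dna else revcomp(dna)
  genome <- c(chrT = paste0(strrep("A", 50), genomic, strrep("A", 50)))
  orf <- orf_annotation("orfT", "txT", "chrT", strand,
                        matrix(c(50L, 50L + nchar(seq)), ncol = 2),
                        "uORF", seq, cds_start_distance = 10L)
  list(orf = orf, genome = genome)
}

# A minimal variant table with sensible defaults.
make_variants <- function(n = 10, context = "ACG:C>T", singleton = NULL,
                          ac = NULL, an = 1000L) {
  if (is.null(ac)) {
    if (is.null(singleton)) singleton <- rep(FALSE, n)
    ac <- ifelse(singleton, 1L, 5L)
  }
  as_variant_table(data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "C", alt = "T",
    ac = ac, an = an, context = rep_len(context, n),
    stringsAsFactors = FALSE))
}

# A one-context rate table (plus any extra contexts supplied as key=mu).
make_rates <- function(mu = c("ACG:C>T" = 1e-8)) {
  as_rate_table(data.frame(
    context = substr(names(mu), 1, 3),
    alt = substr(names(mu), 7, 7),
    methyl_level = 0L,
    mu = unname(mu), stringsAsFactors = FALSE))
}

# Independent brute-force consequence oracle: only the genetic-code table
# and the stop ranking, no shared code path with classify_orf_snv.
oracle_category <- function(ref_codon, alt_codon, offset, is_first) {
  gc <- Biostrings::RNA_GENETIC_CODE
  stops <- c("UAA", "UAG", "UGA")
  rank <- c(UGA = 1, UAG = 2, UAA = 3)
  if (is_first) {
    if (offset == 0 && alt_codon %in% c("AUG", "CUG", "GUG", "UUG"))
      return("start_maintain")
    return("start_disrupt")
  }
  r_stop <- ref_codon %in% stops
  a_stop <- alt_codon %in% stops
  if (!r_stop && a_stop) return("stop_gain")
  if (r_stop && a_stop)
    return(if (rank[alt_codon] > rank[ref_codon]) "stop_strengthen"
           else "stop_weaken")
  if (r_stop && !a_stop) return("stop_loss")
  if (gc[[ref_codon]] == gc[[alt_codon]]) "synonymous" else "missense"
}

# Enumerate all single-base substitutions of one codon.
codon_substitutions <- function(codon) {
  out <- list()
  for (off in 0:2) {
    ref_base <- substr(codon, off + 1, off + 1)
    for (b in setdiff(c("A", "C", "G", "U"), ref_base)) {
      alt <- codon
      substr(alt, off + 1, off + 1) <- b
      out[[length(out) + 1]] <- list(offset = off, alt_codon = alt)
    }
  }
  out
}
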