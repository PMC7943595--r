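## Nucleotide alphabets, codon tables and small sequence helpers shared by
## every module. Sequences attached to ORF/UTR annotations are RNA, in
## translation (5'->3' transcript) orientation; genomes and variant alleles
## are DNA on the reference strand.

RNA_STOPS <- c("UAA", "UAG", "UGA")

## Termination-efficiency hierarchy UAA > UAG > UGA (readthrough-prone UGA
## is weakest).
STOP_STRENGTH_RANK <- c(UGA = 1L, UAG = 2L, UAA = 3L)

## Near-cognate start set observed for translated uORFs.
NUG_STARTS <- c("AUG", "CUG", "GUG", "UUG")

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

ORF_CLASSES <- c("uORF", "dORF", "lncRNA", "pseudogene")

dna_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

dna_complement <- function(x) chartr("ACGTN", "TGCAN", x)

rna_revcomp <- function(x) {
  chartr("ACGUN", "UGCAN", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

#' Translate an RNA codon
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param codon Character vector of RNA triplets.
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codon <- function(codon) {
  aa <- Biostrings::RNA_GENETIC_CODE[codon]
  if (anyNA(aa)) stop("not a valid RNA codon: ",
                      paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

is_stop_codon <- function(codon) codon %in% RNA_STOPS

## All 61 sense codons, RNA alphabet.
sense_codons <- function() {
  all64 <- names(Biostrings::RNA_GENETIC_CODE)
  setdiff(all64, RNA_STOPS)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
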