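## SNV records, VCF I/O, quality filtering and the trinucleotide mutation
## context convention. Variants live in a plain data.frame ("variant
## table") with one row per biallelic SNV:
##   chrom, pos (1-based), ref, alt, ac, an, filter, lcr, context,
##   methyl, cds_labels, revel, maf, singleton

variant_table_columns <- c("chrom", "pos", "ref", "alt", "ac", "an",
                           "filter", "lcr", "context", "methyl",
                           "cds_labels", "revel", "maf", "singleton")

#' Assemble a variant table
#'
#' Derived columns (`maf = ac/an`, `singleton = (ac == 1)`) are recomputed;
#' missing optional columns are filled with `NA`.
#'
#' @param df Data frame with at least chrom, pos, ref, alt, ac, an.
#' @return Data frame with the full variant-table column set.
#' @export
as_variant_table <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "ac", "an") %in% names(df)))
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (any(df$ac < 1L) || any(df$an < df$ac)) stop("require 1 <= AC <= AN")
  df$filter <- if (is.null(df$filter)) "PASS" else df$filter
  df$lcr <- if (is.null(df$lcr)) FALSE else df$lcr
  df$context <- if (is.null(df$context)) NA_character_ else df$context
  df$methyl <- if (is.null(df$methyl)) NA_integer_ else df$methyl
  df$cds_labels <- if (is.null(df$cds_labels)) NA_character_ else df$cds_labels
  df$revel <- if (is.null(df$revel)) NA_real_ else df$revel
  df$maf <- df$ac / df$an
  df$singleton <- df$ac == 1L
  rownames(df) <- NULL
  df[variant_table_columns]
}

#' Normalize a trinucleotide mutation context
#'
#' Collapses the reference-strand triplet around a SNV so that the central
#' reference base is A or C, reverse-complementing the triplet and
#' complementing the alt allele otherwise. This places each of the 64 x 3
#' possible (triplet, alt) pairs into one of 96 strand-symmetric context
#' classes. Triplets containing N map to `"unknown"` and are excluded from
#' MAPS calibration and scoring.
#'
#' @param triplet Reference-strand DNA triplet centred on the ref base.
#' @param ref,alt Single reference / alternate DNA bases.
#' @return Character context key, e.g. `"ACG:C>T"`.
#' @export
normalize_context <- function(triplet, ref, alt) {
  triplet <- toupper(triplet); ref <- toupper(ref); alt <- toupper(alt)
  n <- length(triplet)
  out <- character(n)
  central <- substr(triplet, 2L, 2L)
  bad <- grepl("N", triplet) | ref == "N" | alt == "N"
  if (any(central[!bad] != ref[!bad]))
    stop("triplet central base does not match ref allele")
  flip <- !bad & central %in% c("G", "T")
  if (any(flip)) {
    triplet[flip] <- dna_revcomp(triplet[flip])
    ref[flip] <- dna_complement(ref[flip])
    alt[flip] <- dna_complement(alt[flip])
  }
  out[!bad] <- paste0(triplet[!bad], ":", ref[!bad], ">", alt[!bad])
  out[bad] <- "unknown"
  out
}

## Context of each variant row computed from the genome reference triplet.
context_from_genome <- function(genome, chrom, pos, ref, alt) {
  triplet <- vapply(seq_along(pos), function(i) {
    s <- genome[[chrom[i]]]
    if (pos[i] < 2L || pos[i] > nchar(s) - 1L) return("NNN")
    substr(s, pos[i] - 1L, pos[i] + 1L)
  }, character(1))
  normalize_context(triplet, ref, alt)
}

info_field <- function(info, key) {
  m <- regexec(paste0("(?:^|;)", key, "=([^;]*)"), info)
  vapply(regmatches(info, m), function(x)
    if (length(x) >= 2L) x[2L] else NA_character_, character(1))
}

#' Read SNVs from a VCF file
#'
#' Parses a VCF (v4.x, plain text) into a variant table. Multi-allelic
#' sites are split into biallelic records (per-allele AC taken from the
#' comma-separated AC field); non-SNV records are skipped with a reported
#' count. No quality filtering is applied here — see [qc_filter()].
#'
#' INFO fields used: `AC`, `AN`, flag `LCR` (low-complexity region),
#' optional `CTX` (reference-strand trinucleotide around the site) and
#' `MET` (methylation level 0/1/2). When `genome` is supplied the context
#' is computed from the reference triplet instead of `CTX`.
#'
#' @param path VCF file.
#' @param genome Optional genome (named DNA vector or FASTA path) for
#'   context computation.
#' @return Variant table data frame (see [as_variant_table()]).
#' @export
read_variants_vcf <- function(path, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  acs <- strsplit(info_field(info, "AC"), ",", fixed = TRUE)
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    an <- as.integer(info_field(info[i], "AN"))
    for (j in seq_along(alts[[i]])) {
      alt <- toupper(alts[[i]][j])
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% DNA_BASES || !alt %in% DNA_BASES) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt,
        ac = as.integer(acs[[i]][min(j, length(acs[[i]]))]),
        an = an,
        filter = ifelse(is.na(fix[i, "FILTER"]) | fix[i, "FILTER"] == ".",
                        "PASS", fix[i, "FILTER"]),
        lcr = grepl("(^|;)LCR(;|$|=1)", info[i]),
        ctx = info_field(info[i], "CTX"),
        methyl = suppressWarnings(as.integer(info_field(info[i], "MET"))),
        revel = suppressWarnings(as.numeric(info_field(info[i], "REVEL"))),
        cds_labels = info_field(info[i], "CDSLAB"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) message(n_skipped, " non-SNV record(s) skipped")
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no SNV records in ", path)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    df$context <- context_from_genome(genome, df$chrom, df$pos, df$ref, df$alt)
  } else {
    df$context <- ifelse(is.na(df$ctx), NA_character_,
                         normalize_context(df$ctx, df$ref, df$alt))
  }
  df$ctx <- NULL
  as_variant_table(df)
}

#' Write a variant table as VCF
#'
#' Emits a minimal VCF v4.2 with INFO fields AC, AN, CTX (raw reference
#' triplet is not retained, so the collapsed context is not written), LCR
#' and optional MET/REVEL/CDSLAB. Rows are written sorted by (chrom, pos,
#' alt) so output bytes are a pure function of the table contents.
#'
#' @param variants Variant table.
#' @param path Output path.
#' @param genome Optional genome used to write the `CTX` reference triplet.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  v <- variants[order(variants$chrom, variants$pos, variants$alt), ]
  info <- sprintf("AC=%d;AN=%d", v$ac, v$an)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    trip <- vapply(seq_len(nrow(v)), function(i)
      substr(genome[[v$chrom[i]]], v$pos[i] - 1L, v$pos[i] + 1L), character(1))
    info <- paste0(info, ";CTX=", trip)
  }
  info <- paste0(info, ifelse(v$lcr, ";LCR", ""))
  has_met <- !is.na(v$methyl)
  info[has_met] <- paste0(info[has_met], ";MET=", v$methyl[has_met])
  has_rev <- !is.na(v$revel)
  info[has_rev] <- paste0(info[has_rev], ";REVEL=", v$revel[has_rev])
  has_lab <- !is.na(v$cds_labels)
  info[has_lab] <- paste0(info[has_lab], ";CDSLAB=", v$cds_labels[has_lab])
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference trinucleotide\">",
    "##INFO=<ID=LCR,Number=0,Type=Flag,Description=\"Low complexity region\">",
    "##INFO=<ID=MET,Number=1,Type=Integer,Description=\"Methylation level\">",
    "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL score\">",
    "##INFO=<ID=CDSLAB,Number=1,Type=String,Description=\"CDS-level labels\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter, info,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Quality-filter a variant table
#'
#' Keeps PASS records outside low-complexity regions whose allele number is
#' at least `an_fraction` of the maximum allele number observed in the
#' input set (controls for uneven sequencing depth).
#'
#' @param variants Variant table.
#' @param an_fraction Minimum AN as a fraction of the set-wide maximum AN.
#' @return Filtered variant table.
#' @export
qc_filter <- function(variants, an_fraction = 0.8) {
  if (nrow(variants) == 0L) return(variants)
  if (an_fraction <= 0 || an_fraction > 1)
    stop("an_fraction must be in (0, 1]")
  an_min <- an_fraction * max(variants$an)
  keep <- variants$filter == "PASS" & !variants$lcr & variants$an >= an_min
  message(sum(!keep), " of ", nrow(variants), " variant(s) removed by QC")
  out <- variants[keep, ]
  rownames(out) <- NULL
  out
}
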