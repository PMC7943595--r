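## Translated-ORF and 5'UTR annotations.
##
## Coordinate conventions, used throughout the package:
##   * internal blocks are 0-based half-open [start, end), ascending genomic
##     order, like BED;
##   * variant positions (VCF) are 1-based;
##   * attached sequences are RNA in translation orientation (minus-strand
##     features are reverse-complemented on construction).

#' Construct a translated-ORF annotation
#'
#' An ORF is a set of strand-aware genomic blocks plus its in-frame spliced
#' RNA sequence. uORFs additionally carry the distance from their 3' end to
#' the downstream CDS start, used for distance-matched control sets.
#'
#' @param orf_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param blocks Two-column matrix of 0-based half-open intervals in
#'   ascending genomic order.
#' @param orf_class One of `"uORF"`, `"dORF"`, `"lncRNA"`, `"pseudogene"`.
#' @param spliced_sequence RNA sequence in translation orientation; length
#'   must equal the summed block length and be divisible by 3. uORFs must
#'   start with a NUG codon; all ORFs must end with a stop codon.
#' @param cds_start_distance Non-negative distance (nt) from the ORF 3' end
#'   to the downstream CDS start; `NA` for non-uORF classes.
#' @return An object of class `orf_annotation`.
#' @export
orf_annotation <- function(orf_id, transcript_id, chrom, strand, blocks,
                           orf_class, spliced_sequence,
                           cds_start_distance = NA_integer_) {
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (any(blocks[, 2L] <= blocks[, 1L])) stop("empty or inverted block")
  if (is.unsorted(blocks[, 1L], strictly = TRUE) && nrow(blocks) > 1L)
    stop("blocks must be in ascending genomic order")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!orf_class %in% ORF_CLASSES)
    stop("orf_class must be one of ", paste(ORF_CLASSES, collapse = ", "))
  len <- sum(blocks[, 2L] - blocks[, 1L])
  if (len != nchar(spliced_sequence))
    stop("block lengths (", len, ") do not match sequence length (",
         nchar(spliced_sequence), ")")
  if (len %% 3L != 0L) stop("ORF length not divisible by 3")
  codons <- split_codons(spliced_sequence)
  if (orf_class == "uORF" && !codons[1L] %in% NUG_STARTS)
    stop("uORF start codon ", codons[1L], " not in NUG set")
  if (!is_stop_codon(codons[length(codons)]))
    stop("terminal codon ", codons[length(codons)], " is not a stop codon")
  if (orf_class == "uORF" && (is.na(cds_start_distance) || cds_start_distance < 0L))
    stop("uORFs require a non-negative cds_start_distance")
  structure(list(
    orf_id = as.character(orf_id),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = strand,
    blocks = blocks,
    orf_class = orf_class,
    spliced_sequence = spliced_sequence,
    cds_start_distance = as.integer(cds_start_distance)
  ), class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("<orf_annotation> %s (%s) %s:%s %s, %d nt / %d codons\n",
              x$orf_id, x$orf_class, x$chrom,
              paste(apply(x$blocks, 1L, function(b)
                sprintf("%d-%d", b[1L], b[2L])), collapse = ","),
              x$strand, nchar(x$spliced_sequence),
              nchar(x$spliced_sequence) %/% 3L))
  invisible(x)
}

#' Genomic positions of an ORF in translation order
#'
#' Maps spliced-sequence indices 1..L to 1-based genomic positions; minus
#' strand features run 3'->5' in genomic coordinates.
#'
#' @param x An `orf_annotation` or `utr_annotation`.
#' @return Integer vector of length L; `orf_positions(x)[i]` is the genomic
#'   position of sequence index i.
#' @export
orf_positions <- function(x) {
  pos <- unlist(lapply(seq_len(nrow(x$blocks)), function(i)
    seq.int(x$blocks[i, 1L] + 1L, x$blocks[i, 2L])), use.names = FALSE)
  if (x$strand == "-") pos <- rev(pos)
  pos
}

#' Map a genomic position to its spliced-sequence index
#'
#' @param x An `orf_annotation` or `utr_annotation`.
#' @param pos 1-based genomic position(s).
#' @return Integer index into the spliced sequence (`NA` if outside).
#' @export
genomic_to_index <- function(x, pos) match(pos, orf_positions(x))

#' Construct a 5'UTR annotation
#'
#' @param transcript_id,chrom,strand,blocks As in [orf_annotation()].
#' @param sequence RNA sequence in transcript orientation.
#' @param contained_orf_ids IDs of translated ORFs lying within the UTR.
#' @return An object of class `utr_annotation`.
#' @export
utr_annotation <- function(transcript_id, chrom, strand, blocks, sequence,
                           contained_orf_ids = character()) {
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  len <- sum(blocks[, 2L] - blocks[, 1L])
  if (len != nchar(sequence)) stop("block lengths do not match sequence")
  structure(list(
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = strand,
    blocks = blocks,
    sequence = sequence,
    contained_orf_ids = as.character(contained_orf_ids)
  ), class = "utr_annotation")
}

#' @export
print.utr_annotation <- function(x, ...) {
  cat(sprintf("<utr_annotation> %s %s:%d-%d %s, %d nt, %d contained ORF(s)\n",
              x$transcript_id, x$chrom, min(x$blocks[, 1L]),
              max(x$blocks[, 2L]), x$strand, nchar(x$sequence),
              length(x$contained_orf_ids)))
  invisible(x)
}

## Extract the spliced transcript-orientation RNA sequence for a blocked
## feature from a named character vector of chromosome DNA sequences.
extract_spliced_rna <- function(genome, chrom, blocks, strand) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  parts <- apply(blocks, 1L, function(b)
    substr(genome[[chrom]], b[1L] + 1L, b[2L]))
  seq <- paste(parts, collapse = "")
  if (strand == "-") seq <- dna_revcomp(seq)
  dna_to_rna(seq)
}

## ---- BED12 serialization --------------------------------------------------
## Canonical layout: name = orf_id|class|transcript_id, score carries
## cds_start_distance (0 when absent), thickStart == thickEnd == chromStart.

format_bed12 <- function(chrom, start, end, name, score, strand, blocks) {
  rel <- sweep(blocks, 2L, start)
  sizes <- paste0(paste(blocks[, 2L] - blocks[, 1L], collapse = ","), ",")
  starts <- paste0(paste(rel[, 1L], collapse = ","), ",")
  paste(chrom, start, end, name, score, strand, start, start, "0",
        nrow(blocks), sizes, starts, sep = "\t")
}

#' Write ORF annotations as BED12
#'
#' The name column is `orf_id|class|transcript_id`; the score column carries
#' the distance to the downstream CDS start (0 for non-uORF classes), so a
#' file written here round-trips exactly through [read_orf_bed()].
#'
#' @param orfs List of `orf_annotation`.
#' @param path Output file.
#' @export
write_orf_bed <- function(orfs, path) {
  lines <- vapply(orfs, function(o) {
    format_bed12(o$chrom, min(o$blocks[, 1L]), max(o$blocks[, 2L]),
                 paste(o$orf_id, o$orf_class, o$transcript_id, sep = "|"),
                 if (is.na(o$cds_start_distance)) 0L else o$cds_start_distance,
                 o$strand, o$blocks)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write UTR annotations as BED12
#'
#' @param utrs List of `utr_annotation`; name column is the transcript_id.
#' @param path Output file.
#' @export
write_utr_bed <- function(utrs, path) {
  lines <- vapply(utrs, function(u) {
    format_bed12(u$chrom, min(u$blocks[, 1L]), max(u$blocks[, 2L]),
                 u$transcript_id, 0L, u$strand, u$blocks)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## Parse a BED12 file into chrom/start/end/name/score/strand plus an
## absolute 0-based half-open block matrix per record.
parse_bed12 <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(g)
  rel <- S4Vectors::mcols(g)$blocks
  lapply(seq_len(nrow(df)), function(i) {
    cs <- df$start[i] - 1L  # chromStart, 0-based
    bl <- rel[[i]]
    blocks <- cbind(start = cs + IRanges::start(bl) - 1L,
                    end   = cs + IRanges::end(bl))
    list(chrom = as.character(df$seqnames[i]),
         name = df$name[i],
         score = df$score[i],
         strand = as.character(df$strand[i]),
         blocks = blocks)
  })
}

#' Read translated-ORF annotations from BED12
#'
#' Spliced sequences are extracted from `genome` across blocks and
#' reverse-complemented into translation orientation for minus-strand
#' records. Records whose length is not divisible by 3, or that fail any
#' ORF invariant, are rejected with a warning and parsing continues.
#'
#' @param path BED12 file; name column `orf_id|class[|transcript_id]`,
#'   score column the distance to the downstream CDS start.
#' @param genome Named character vector of chromosome DNA sequences, or a
#'   FASTA path.
#' @return List of [orf_annotation()] objects.
#' @export
read_orf_bed <- function(path, genome) {
  genome <- as_genome(genome)
  recs <- parse_bed12(path)
  out <- vector("list", length(recs))
  kept <- logical(length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    fields <- strsplit(r$name, "|", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      warning("record ", r$name, ": name is not orf_id|class, skipped")
      next
    }
    seq <- extract_spliced_rna(genome, r$chrom, r$blocks, r$strand)
    o <- tryCatch(
      orf_annotation(
        orf_id = fields[1L],
        transcript_id = if (length(fields) >= 3L) fields[3L] else fields[1L],
        chrom = r$chrom, strand = r$strand, blocks = r$blocks,
        orf_class = fields[2L], spliced_sequence = seq,
        cds_start_distance = if (fields[2L] == "uORF") as.integer(r$score)
                             else NA_integer_),
      error = function(e) {
        warning("record ", fields[1L], " rejected: ", conditionMessage(e))
        NULL
      })
    if (!is.null(o)) {
      out[[i]] <- o
      kept[i] <- TRUE
    }
  }
  out[kept]
}

#' Read 5'UTR annotations from BED12
#'
#' @param path BED12 file with the transcript_id in the name column.
#' @param genome Named character vector of chromosome DNA sequences, or a
#'   FASTA path.
#' @param orfs Optional list of `orf_annotation`; translated ORFs whose
#'   blocks fall within a UTR are recorded in `contained_orf_ids`.
#' @return List of [utr_annotation()] objects.
#' @export
read_utr_bed <- function(path, genome, orfs = NULL) {
  genome <- as_genome(genome)
  recs <- parse_bed12(path)
  lapply(recs, function(r) {
    seq <- extract_spliced_rna(genome, r$chrom, r$blocks, r$strand)
    contained <- character()
    if (!is.null(orfs)) {
      contained <- vapply(
        Filter(function(o) o$chrom == r$chrom && o$strand == r$strand &&
                 all(apply(o$blocks, 1L, function(b)
                   any(b[1L] >= r$blocks[, 1L] & b[2L] <= r$blocks[, 2L]))),
               orfs),
        function(o) o$orf_id, character(1))
    }
    utr_annotation(r$name, r$chrom, r$strand, r$blocks, seq, contained)
  })
}

#' Read or pass through a genome
#'
#' @param genome A named character vector of chromosome DNA sequences or a
#'   FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(ss), names(ss))
  }
  stats::setNames(toupper(genome), names(genome))
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome DNA sequences.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
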