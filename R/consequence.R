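## Reading-frame-aware consequence classification of SNVs inside translated
## ORFs. Every possible SNV in an ORF falls into exactly one category:
##
##   stop_gain        sense codon -> stop codon (a new upstream termination
##                    codon, UTC)
##   stop_strengthen  stop -> stronger stop in the hierarchy UAA > UAG > UGA
##   stop_weaken      stop -> weaker stop
##   stop_loss        stop -> sense codon
##   start_disrupt    position 2 or 3 of the first (NUG) codon
##   start_maintain   position 1 of the first codon (start stays NUG)
##   missense         sense -> sense, amino acid changes
##   synonymous       sense -> sense, amino acid unchanged
##
## First-codon rules take precedence over the stop/amino-acid rules so the
## eight categories partition all 9L possible SNVs of an L-nt ORF.

CONSEQUENCE_CATEGORIES <- c("stop_gain", "stop_strengthen", "stop_weaken",
                            "stop_loss", "start_disrupt", "start_maintain",
                            "missense", "synonymous")

## Deduplication order for variants hitting several overlapping ORFs.
## stop_weaken / stop_loss (not analyzed as selected classes) rank between
## start_disrupt and missense.
SEVERITY_ORDER <- c(stop_gain = 8L, stop_strengthen = 7L, start_disrupt = 6L,
                    stop_loss = 5L, stop_weaken = 4L, missense = 3L,
                    synonymous = 2L, start_maintain = 1L)

#' Stop-codon strength rank
#'
#' Termination-efficiency hierarchy UAA > UAG > UGA: UGA is the weakest
#' (most readthrough-prone) stop, UAA the strongest.
#'
#' @param codon RNA stop codon(s).
#' @return Integer rank: UGA = 1, UAG = 2, UAA = 3.
#' @export
stop_strength <- function(codon) {
  rank <- STOP_STRENGTH_RANK[codon]
  if (anyNA(rank))
    stop("not a stop codon: ", paste(codon[is.na(rank)], collapse = ", "))
  unname(rank)
}

## Category of one codon substitution. `codon_index` is 0-based;
## `is_first` applies the start-codon rules.
classify_codon_change <- function(ref_codon, alt_codon, offset, is_first) {
  if (is_first) {
    if (offset == 0L) {
      return(if (alt_codon %in% NUG_STARTS) "start_maintain" else "start_disrupt")
    }
    return("start_disrupt")
  }
  ref_stop <- is_stop_codon(ref_codon)
  alt_stop <- is_stop_codon(alt_codon)
  if (!ref_stop && alt_stop) return("stop_gain")
  if (ref_stop && alt_stop) {
    return(if (stop_strength(alt_codon) > stop_strength(ref_codon))
      "stop_strengthen" else "stop_weaken")
  }
  if (ref_stop && !alt_stop) return("stop_loss")
  if (translate_codon(ref_codon) == translate_codon(alt_codon))
    "synonymous" else "missense"
}

#' Classify one SNV against one translated ORF
#'
#' The variant's genomic alleles are mapped into the ORF reading frame
#' (minus-strand variants are complemented into translation orientation),
#' the affected codon substituted, and the category assigned: first-codon
#' rules for codon 0 of uORFs, otherwise stop-table membership of the ref
#' and alt codons, then amino-acid comparison under the standard genetic
#' code.
#'
#' @param orf An [orf_annotation()].
#' @param chrom,pos,ref,alt The SNV (1-based position, DNA alleles on the
#'   reference strand).
#' @param csc Optional CSC table (see [read_csc_table()]); when given,
#'   `csc_delta` and the codon-optimality direction are filled in.
#' @return One-row data frame: orf_id, chrom, pos, ref, alt, codon_index
#'   (0-based), codon_offset (0..2), ref_codon, alt_codon, category,
#'   new_stop, aa_ref, aa_alt, csc_delta, optimality.
#' @export
classify_orf_snv <- function(orf, chrom, pos, ref, alt, csc = NULL) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || !ref %in% DNA_BASES ||
      !alt %in% DNA_BASES)
    stop("SNV only: ref and alt must be single A/C/G/T bases")
  if (ref == alt) stop("ref and alt must differ")
  if (chrom != orf$chrom) stop("variant chromosome does not match ORF")
  i <- genomic_to_index(orf, pos)
  if (is.na(i)) stop("variant position ", pos, " outside ORF ", orf$orf_id)
  # alleles in translation orientation, RNA alphabet
  ref_tx <- dna_to_rna(if (orf$strand == "-") dna_complement(ref) else ref)
  alt_tx <- dna_to_rna(if (orf$strand == "-") dna_complement(alt) else alt)
  seq_base <- substr(orf$spliced_sequence, i, i)
  if (seq_base != ref_tx)
    stop("reference allele mismatch at ", chrom, ":", pos, " (ORF has ",
         seq_base, ", variant ref maps to ", ref_tx, ")")
  codon_index <- (i - 1L) %/% 3L
  offset <- (i - 1L) %% 3L
  ref_codon <- substr(orf$spliced_sequence, codon_index * 3L + 1L,
                      codon_index * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, offset + 1L, offset + 1L) <- alt_tx
  category <- classify_codon_change(ref_codon, alt_codon, offset,
                                    is_first = codon_index == 0L)
  new_stop <- if (category %in% c("stop_gain", "stop_strengthen"))
    alt_codon else NA_character_
  both_sense <- !is_stop_codon(ref_codon) && !is_stop_codon(alt_codon)
  csc_delta <- NA_real_
  optimality <- "n/a"
  if (!is.null(csc) && both_sense) {
    dirres <- csc_direction(ref_codon, alt_codon, csc)
    csc_delta <- attr(dirres, "delta")
    optimality <- as.character(dirres)
  }
  data.frame(
    orf_id = orf$orf_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    codon_index = codon_index, codon_offset = offset,
    ref_codon = ref_codon, alt_codon = alt_codon, category = category,
    new_stop = new_stop,
    aa_ref = if (both_sense || !is_stop_codon(ref_codon))
      translate_codon(ref_codon) else "*",
    aa_alt = if (both_sense || !is_stop_codon(alt_codon))
      translate_codon(alt_codon) else "*",
    csc_delta = csc_delta, optimality = optimality,
    stringsAsFactors = FALSE)
}

#' Start-codon consequence of a first-codon SNV
#'
#' Mutations of position 1 of the NUG start codon keep the NUG context
#' (start-maintaining); mutations of positions 2 or 3 disrupt translation
#' initiation (start-disrupting).
#'
#' @inheritParams classify_orf_snv
#' @return `"start_maintain"` or `"start_disrupt"`.
#' @export
classify_start_snv <- function(orf, chrom, pos, ref, alt) {
  call <- classify_orf_snv(orf, chrom, pos, ref, alt)
  if (call$codon_index != 0L)
    stop("variant is not in the first codon of ", orf$orf_id)
  call$category
}

#' Direction of a codon-optimality change
#'
#' Sign of CSC(alt) - CSC(ref): variants decreasing the codon stability
#' coefficient are optimality-decreasing, and vice versa. Undefined
#' (`"n/a"`) when either codon is a stop.
#'
#' @param ref_codon,alt_codon RNA codons.
#' @param csc CSC table (named numeric vector over the 61 sense codons).
#' @return `"increasing"`, `"decreasing"`, `"neutral"` or `"n/a"`, with the
#'   raw difference in attribute `"delta"`.
#' @export
csc_direction <- function(ref_codon, alt_codon, csc) {
  if (is_stop_codon(ref_codon) || is_stop_codon(alt_codon))
    return(structure("n/a", delta = NA_real_))
  absent <- setdiff(c(ref_codon, alt_codon), names(csc))
  if (length(absent) > 0L)
    stop("codon(s) absent from CSC table: ", paste(absent, collapse = ", "))
  delta <- unname(csc[alt_codon] - csc[ref_codon])
  dir <- if (delta > 0) "increasing" else if (delta < 0) "decreasing" else "neutral"
  structure(dir, delta = delta)
}

#' Classify many variants against a set of ORFs
#'
#' Each variant is classified against every ORF containing it (one row per
#' variant x ORF pair). Use [dedup_most_severe()] to reduce to one call per
#' variant for class-level statistics.
#'
#' @param orfs List of [orf_annotation()].
#' @param variants Variant table.
#' @param csc Optional CSC table.
#' @return Data frame of consequence calls (zero rows if no variant lies
#'   in any ORF).
#' @export
classify_variants <- function(orfs, variants, csc = NULL) {
  calls <- list()
  for (o in orfs) {
    pos_set <- orf_positions(o)
    hit <- which(variants$chrom == o$chrom & variants$pos %in% pos_set)
    for (k in hit) {
      calls[[length(calls) + 1L]] <- cbind(
        classify_orf_snv(o, variants$chrom[k], variants$pos[k],
                         variants$ref[k], variants$alt[k], csc = csc),
        orf_class = o$orf_class, variant_row = k)
    }
  }
  if (length(calls) == 0L) return(empty_calls())
  do.call(rbind, calls)
}

empty_calls <- function() {
  data.frame(orf_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), codon_index = integer(),
             codon_offset = integer(), ref_codon = character(),
             alt_codon = character(), category = character(),
             new_stop = character(), aa_ref = character(),
             aa_alt = character(), csc_delta = numeric(),
             optimality = character(), orf_class = character(),
             variant_row = integer(), stringsAsFactors = FALSE)
}

#' Reduce overlapping-ORF calls to one per variant
#'
#' A variant inside two or more overlapping ORFs gets one call per ORF; for
#' class-level statistics it is counted once with its most severe call
#' (stop_gain > stop_strengthen > start_disrupt > stop_loss > stop_weaken >
#' missense > synonymous > start_maintain; ties broken by orf_id for
#' determinism).
#'
#' @param calls Output of [classify_variants()].
#' @return One row per (chrom, pos, ref, alt).
#' @export
dedup_most_severe <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  o <- order(key, -SEVERITY_ORDER[calls$category], calls$orf_id)
  out <- calls[o, ][!duplicated(key[o]), ]
  rownames(out) <- NULL
  out
}

#' Remove consequence calls overlapping annotated CDS
#'
#' Guards against apparent uORF constraint that is really selection on a
#' coding sequence of another isoform.
#'
#' @param calls Consequence-call data frame.
#' @param cds_intervals Data frame with chrom, start, end (0-based
#'   half-open genomic intervals).
#' @return Calls whose variant position does not intersect any CDS
#'   interval; the number removed is reported.
#' @export
exclude_cds_overlap <- function(calls, cds_intervals) {
  if (nrow(calls) == 0L || nrow(cds_intervals) == 0L) return(calls)
  inside <- vapply(seq_len(nrow(calls)), function(i) {
    p0 <- calls$pos[i] - 1L  # 0-based
    any(cds_intervals$chrom == calls$chrom[i] &
          cds_intervals$start <= p0 & p0 < cds_intervals$end)
  }, logical(1))
  message(sum(inside), " call(s) removed for CDS overlap")
  out <- calls[!inside, ]
  rownames(out) <- NULL
  out
}

#' Enumerate potential stop-creating positions of an ORF
#'
#' Positions in internal sense codons where at least one single-nucleotide
#' substitution yields an in-frame stop codon, categorized by which stops
#' (UAA/UAG/UGA) are achievable; positions able to create more than one
#' stop are flagged `multi`. The first (start) codon and the terminal stop
#' codon are excluded, matching the stop-gain category of
#' [classify_orf_snv()].
#'
#' @param orf An [orf_annotation()].
#' @return Data frame: pos (1-based genomic), orf_id, codon_index,
#'   codon_offset, achievable_stops (comma-joined), multi,
#'   distance_to_cds (position to downstream CDS start in transcript
#'   coordinates, `NA` unless a uORF).
#' @export
find_potential_stop_positions <- function(orf) {
  codons <- split_codons(orf$spliced_sequence)
  gpos <- orf_positions(orf)
  L <- nchar(orf$spliced_sequence)
  rows <- list()
  for (ci in seq_along(codons)[-c(1L, length(codons))]) {
    ref_codon <- codons[ci]
    if (is_stop_codon(ref_codon)) next  # internal stops cannot be "created"
    for (off in 0:2) {
      achievable <- character()
      for (b in setdiff(RNA_BASES, substr(ref_codon, off + 1L, off + 1L))) {
        alt_codon <- ref_codon
        substr(alt_codon, off + 1L, off + 1L) <- b
        if (is_stop_codon(alt_codon)) achievable <- c(achievable, alt_codon)
      }
      if (length(achievable) == 0L) next
      i <- (ci - 1L) * 3L + off + 1L
      dist <- if (!is.na(orf$cds_start_distance))
        (L - i) + orf$cds_start_distance else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        pos = gpos[i], orf_id = orf$orf_id, codon_index = ci - 1L,
        codon_offset = off,
        achievable_stops = paste(sort(achievable), collapse = ","),
        multi = length(achievable) > 1L, distance_to_cds = dist,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pos = integer(), orf_id = character(),
                      codon_index = integer(), codon_offset = integer(),
                      achievable_stops = character(), multi = logical(),
                      distance_to_cds = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Enumerate stop-creating positions in UTR sequence outside translated ORFs
#'
#' Control enumeration for conservation analysis: UTR positions where a
#' single substitution turns some trinucleotide containing the position
#' (any of the three local frame alignments, transcript orientation) into
#' a stop-matching UGA/UAG/UAA. Positions inside translated ORFs are
#' masked out. Distance to the CDS start is the transcript-coordinate gap
#' between the position and the UTR 3' end.
#'
#' @param utr A [utr_annotation()].
#' @param mask_orfs Translated ORFs whose bases are excluded.
#' @return Data frame: chrom, pos (1-based genomic), seq_index,
#'   distance_to_cds.
#' @export
find_utr_stop_creating_positions <- function(utr, mask_orfs = NULL) {
  seq <- utr$sequence
  n <- nchar(seq)
  upos <- orf_positions(utr)
  masked <- rep(FALSE, n)
  if (!is.null(mask_orfs)) {
    for (o in mask_orfs) {
      if (o$chrom != utr$chrom) next
      masked <- masked | upos %in% orf_positions(o)
    }
  }
  creating <- rep(FALSE, n)
  for (j in seq_len(max(0L, n - 2L))) {
    tri <- substr(seq, j, j + 2L)
    for (k in 0:2) {
      base <- substr(tri, k + 1L, k + 1L)
      for (b in setdiff(RNA_BASES, base)) {
        alt_tri <- tri
        substr(alt_tri, k + 1L, k + 1L) <- b
        if (alt_tri %in% RNA_STOPS) {
          creating[j + k] <- TRUE
          break
        }
      }
    }
  }
  keep <- which(creating & !masked)
  data.frame(chrom = rep(utr$chrom, length(keep)), pos = upos[keep],
             seq_index = keep, distance_to_cds = n - keep,
             stringsAsFactors = FALSE)
}

#' Enumerate start-disrupting positions of an ORF
#'
#' In frame (`in_frame = TRUE`): the two genomic positions at offsets 1 and
#' 2 of the first codon — mutating them destroys the NUG start. Out of
#' frame (`in_frame = FALSE`): the control enumeration of positions whose
#' out-of-frame NUG triplet inside the ORF would be disrupted the same way.
#'
#' @param orf An [orf_annotation()].
#' @param in_frame Logical.
#' @return Data frame: pos (1-based genomic), orf_id, seq_index,
#'   triplet_start (1-based sequence index of the NUG triplet), in_frame.
#' @export
find_start_disrupting_positions <- function(orf, in_frame = TRUE) {
  gpos <- orf_positions(orf)
  seq <- orf$spliced_sequence
  rows <- list()
  if (in_frame) {
    for (i in 2:3)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = gpos[i], orf_id = orf$orf_id, seq_index = i,
        triplet_start = 1L, in_frame = TRUE, stringsAsFactors = FALSE)
  } else {
    for (j in seq_len(nchar(seq) - 2L)) {
      if ((j - 1L) %% 3L == 0L) next  # in-frame triplets are not controls
      if (substr(seq, j + 1L, j + 2L) != "UG") next
      for (i in c(j + 1L, j + 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          pos = gpos[i], orf_id = orf$orf_id, seq_index = i,
          triplet_start = j, in_frame = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pos = integer(), orf_id = character(),
                      seq_index = integer(), triplet_start = integer(),
                      in_frame = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
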