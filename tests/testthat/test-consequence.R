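test_that("stop strength follows the UAA > UAG > UGA hierarchy", {
  expect_equal(stop_strength("UAA"), 3)  # strongest
  expect_equal(stop_strength("UGA"), 1)  # weakest, readthrough-prone
  expect_gt(stop_strength("UAG"), stop_strength("UGA"))
  expect_error(stop_strength("AAA"), "not a stop codon")
})

test_that("reported codon-change examples classify correctly", {
  # (ref codon, offset, alt transcript base, expected category, new stop)
  cases <- list(
    list("UGG", 1L, "A", "stop_gain", "UAG"),        # Trp -> UAG UTC
    list("UGA", 1L, "A", "stop_strengthen", "UAA"),  # UGA -> UAA
    list("UAG", 2L, "A", "stop_strengthen", "UAA"),  # UAG -> UAA
    list("CAA", 0L, "U", "stop_gain", "UAA"),        # CAA -> UAA UTC
    list("UAC", 2L, "A", "stop_gain", "UAA"),        # UAC -> UAA UTC
    list("AAA", 2L, "G", "synonymous", NA))          # Lys -> Lys
  for (cs in cases) {
    fx <- orf_with_internal_codon(cs[[1]])
    i <- 3L + cs[[2]] + 1L  # codon index 1, sequence position
    pos <- orf_positions(fx$orf)[i]
    ref <- chartr("U", "T", substr(cs[[1]], cs[[2]] + 1L, cs[[2]] + 1L))
    alt <- chartr("U", "T", cs[[3]])
    call <- classify_orf_snv(fx$orf, "chrT", pos, ref, alt)
    expect_equal(call$category, cs[[4]], label = paste(cs[[1]], "->", cs[[4]]))
    if (!is.na(cs[[5]])) expect_equal(call$new_stop, cs[[5]])
  }
})

test_that("category assignment matches the brute-force oracle on 64 x 9", {
  # internal (non-first, non-terminal) codon: stop/amino-acid rules only
  codons <- names(Biostrings::RNA_GENETIC_CODE)
  n_checked <- 0
  for (codon in codons) {
    fx <- orf_with_internal_codon(codon)
    gpos <- orf_positions(fx$orf)
    for (sub in codon_substitutions(codon)) {
      i <- 3L + sub$offset + 1L
      ref_tx <- substr(codon, sub$offset + 1L, sub$offset + 1L)
      alt_tx <- substr(sub$alt_codon, sub$offset + 1L, sub$offset + 1L)
      call <- classify_orf_snv(fx$orf, "chrT", gpos[i],
                               chartr("U", "T", ref_tx),
                               chartr("U", "T", alt_tx))
      expect_equal(call$category,
                   oracle_category(codon, sub$alt_codon, sub$offset, FALSE),
                   label = paste(codon, "->", sub$alt_codon))
      expect_equal(call$alt_codon, sub$alt_codon)
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 64 * 9)
})

test_that("strand reflection leaves classification invariant", {
  set.seed(42)
  for (codon in sample(setdiff(names(Biostrings::RNA_GENETIC_CODE),
                               RNA_STOPS), 12)) {
    fxP <- orf_with_internal_codon(codon, strand = "+")
    fxM <- orf_with_internal_codon(codon, strand = "-")
    for (sub in codon_substitutions(codon)) {
      i <- 3L + sub$offset + 1L
      ref_tx <- substr(codon, sub$offset + 1L, sub$offset + 1L)
      alt_tx <- substr(sub$alt_codon, sub$offset + 1L, sub$offset + 1L)
      comp <- function(b) chartr("ACGU", "TGCA", b)
      callP <- classify_orf_snv(fxP$orf, "chrT", orf_positions(fxP$orf)[i],
                                chartr("U", "T", ref_tx),
                                chartr("U", "T", alt_tx))
      callM <- classify_orf_snv(fxM$orf, "chrT", orf_positions(fxM$orf)[i],
                                comp(ref_tx), comp(alt_tx))
      expect_equal(callM$category, callP$category)
      expect_equal(callM$alt_codon, callP$alt_codon)
    }
  }
})

test_that("start-codon rules: position 1 maintains, positions 2-3 disrupt", {
  mk <- function(start) {
    seq <- paste0(start, "AAAUAA")
    genome <- c(chrS = paste0(strrep("A", 20), chartr("U", "T", seq),
                              strrep("A", 20)))
    list(orf = orf_annotation("o", "t", "chrS", "+",
                              matrix(c(20L, 29L), ncol = 2), "uORF", seq,
                              cds_start_distance = 5L),
         genome = genome)
  }
  # CUG offset 0 C->A: AUG, still an NUG start
  fx <- mk("CUG")
  expect_equal(classify_start_snv(fx$orf, "chrS", 21L, "C", "A"),
               "start_maintain")
  # AUG offset 1 U->C: ACG, initiation lost
  fx <- mk("AUG")
  expect_equal(classify_start_snv(fx$orf, "chrS", 22L, "T", "C"),
               "start_disrupt")
  # GUG offset 2 G->A: GUA
  fx <- mk("GUG")
  expect_equal(classify_start_snv(fx$orf, "chrS", 23L, "G", "A"),
               "start_disrupt")
  # any offset-0 substitution keeps the NUG context
  for (alt in c("A", "C", "T")) {
    fx <- mk("GUG")
    expect_equal(classify_start_snv(fx$orf, "chrS", 21L, "G", alt),
                 "start_maintain")
  }
})

test_that("all 9L substitutions of an ORF partition into the category set", {
  fx <- orf_with_internal_codon("UGG")
  orf <- fx$orf
  gpos <- orf_positions(orf)
  L <- nchar(orf$spliced_sequence)
  cats <- character()
  for (i in seq_len(L)) {
    ref_tx <- substr(orf$spliced_sequence, i, i)
    for (alt_tx in setdiff(c("A", "C", "G", "U"), ref_tx)) {
      ref <- chartr("U", "T", ref_tx)
      alt <- chartr("U", "T", alt_tx)
      call <- classify_orf_snv(orf, "chrT", gpos[i], ref, alt)
      cats <- c(cats, call$category)
    }
  }
  expect_length(cats, 3 * L)  # 9 per codon
  expect_true(all(cats %in% uorfsel:::CONSEQUENCE_CATEGORIES))
  # first codon contributes exactly 3 maintain + 6 disrupt
  expect_equal(sum(cats == "start_maintain"), 3)
  expect_equal(sum(cats == "start_disrupt"), 6)
})

test_that("csc_direction reports the sign of the CSC difference", {
  csc <- make_csc_table(sim_config(seed = 1))
  csc[c("AAA", "AAG")] <- c(0.1, -0.2)
  expect_equal(as.character(csc_direction("AAA", "AAG", csc)), "decreasing")
  expect_equal(attr(csc_direction("AAA", "AAG", csc), "delta"), -0.3)
  expect_equal(as.character(csc_direction("AAA", "AAA", csc)), "neutral")
  expect_equal(as.character(csc_direction("UAA", "AAA", csc)), "n/a")
  expect_error(csc_direction("AAA", "CCC", csc[names(csc) != "CCC"]),
               "CCC")
})

test_that("potential stop positions match brute force over substitutions", {
  # UGG: offset 1 -> UAG, offset 2 -> UGA
  fx <- orf_with_internal_codon("UGG")
  ps <- find_potential_stop_positions(fx$orf)
  ps_codon1 <- ps[ps$codon_index == 1, ]
  expect_equal(ps_codon1$codon_offset, c(1L, 2L))
  expect_equal(ps_codon1$achievable_stops[1], "UAG")
  expect_equal(ps_codon1$achievable_stops[2], "UGA")
  expect_false(any(ps_codon1$multi))
  # AAA: only offset 0 (A->U gives UAA)
  fx <- orf_with_internal_codon("AAA")
  ps0 <- find_potential_stop_positions(fx$orf)
  ps0 <- ps0[ps0$codon_index == 1, ]
  expect_equal(ps0$codon_offset, 0L)
  expect_equal(ps0$achievable_stops, "UAA")
  # UCA: offset 1 is multi {UAA, UGA}
  fx <- orf_with_internal_codon("UCA")
  psm <- find_potential_stop_positions(fx$orf)
  psm <- psm[psm$codon_index == 1 & psm$codon_offset == 1, ]
  expect_true(psm$multi)
  expect_equal(psm$achievable_stops, "UAA,UGA")
})

test_that("stop-position enumeration agrees with the classifier", {
  # cross-module consistency: enumerated positions are exactly those where
  # classify_orf_snv emits stop_gain for at least one alt allele
  cfg <- sim_config(seed = 5, n_genes = 8)
  tx <- make_transcriptome(cfg)
  uorfs <- Filter(function(o) o$orf_class == "uORF", tx$orfs)
  expect_gt(length(uorfs), 0)
  for (o in uorfs[seq_len(min(4, length(uorfs)))]) {
    enumerated <- sort(find_potential_stop_positions(o)$pos)
    gpos <- orf_positions(o)
    by_classifier <- integer()
    for (i in seq_along(gpos)) {
      gref <- substr(tx$genome[[o$chrom]], gpos[i], gpos[i])
      for (alt in setdiff(c("A", "C", "G", "T"), gref)) {
        call <- classify_orf_snv(o, o$chrom, gpos[i], gref, alt)
        if (call$category == "stop_gain") {
          by_classifier <- c(by_classifier, gpos[i])
          break
        }
      }
    }
    expect_equal(enumerated, sort(by_classifier))
  }
})

test_that("start-disrupting enumeration: 2 in-frame, NUG scan out of frame", {
  fx <- orf_with_internal_codon("AAA")
  inf <- find_start_disrupting_positions(fx$orf, in_frame = TRUE)
  expect_equal(nrow(inf), 2)
  expect_equal(inf$seq_index, c(2L, 3L))
  expect_equal(inf$pos, orf_positions(fx$orf)[2:3])
  # internal out-of-frame AUG: seq AUG|CAU|GGG|UAA has AUG at index 4..6?
  seq <- "AUGCAUGGGUAA"  # out-of-frame AUG at positions 5-7
  genome <- c(chrS = paste0(strrep("C", 10), chartr("U", "T", seq),
                            strrep("C", 10)))
  orf <- orf_annotation("o", "t", "chrS", "+", matrix(c(10L, 22L), ncol = 2),
                        "uORF", seq, cds_start_distance = 0L)
  oof <- find_start_disrupting_positions(orf, in_frame = FALSE)
  expect_equal(oof$seq_index, c(6L, 7L))  # U and G of the out-of-frame AUG
  # no internal NUG at all -> empty control set
  seq2 <- "AUGAAAAAAUAA"
  genome2 <- c(chrS = paste0(strrep("C", 10), chartr("U", "T", seq2),
                             strrep("C", 10)))
  orf2 <- orf_annotation("o2", "t2", "chrS", "+",
                         matrix(c(10L, 22L), ncol = 2), "uORF", seq2,
                         cds_start_distance = 0L)
  expect_equal(nrow(find_start_disrupting_positions(orf2, in_frame = FALSE)),
               0)
})

test_that("CDS-overlap exclusion respects half-open boundaries", {
  calls <- data.frame(chrom = "chr1", pos = c(100L, 150L, 200L),
                      category = "stop_gain", stringsAsFactors = FALSE)
  cds <- data.frame(chrom = "chr1", start = 140L, end = 199L)
  expect_message(out <- exclude_cds_overlap(calls, cds), "1 call")
  expect_equal(out$pos, c(100L, 200L))
  # pos 200 is 0-based 199 == interval end above -> outside (half-open);
  # extending the interval end to 200 brings it inside
  cds2 <- data.frame(chrom = "chr1", start = 140L, end = 200L)
  expect_message(out2 <- exclude_cds_overlap(calls, cds2))
  expect_equal(out2$pos, 100L)
  # no overlap -> identity
  expect_message(out3 <- exclude_cds_overlap(calls, data.frame(
    chrom = "chr2", start = 0L, end = 500L)), "0 call")
  expect_equal(out3$pos, calls$pos)
})

test_that("variants in overlapping ORFs deduplicate to the most severe call", {
  calls <- rbind(
    data.frame(orf_id = "a", chrom = "chr1", pos = 10L, ref = "C", alt = "T",
               category = "synonymous", stringsAsFactors = FALSE),
    data.frame(orf_id = "b", chrom = "chr1", pos = 10L, ref = "C", alt = "T",
               category = "stop_gain", stringsAsFactors = FALSE),
    data.frame(orf_id = "c", chrom = "chr1", pos = 11L, ref = "G", alt = "A",
               category = "missense", stringsAsFactors = FALSE))
  out <- dedup_most_severe(calls)
  expect_equal(nrow(out), 2)
  expect_equal(out$category[out$pos == 10], "stop_gain")
})
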