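test_that("plus- and minus-strand ORFs parse into translation orientation", {
  genome <- make_tiny_genome()
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_orf_bed(list(tiny_orf_plus(), tiny_orf_minus()), tmp)
  orfs <- read_orf_bed(tmp, genome)
  expect_length(orfs, 2)
  # plus strand: direct parse
  expect_equal(orfs[[1]]$spliced_sequence, "AUGAAAUAA")
  expect_equal(split_codons(orfs[[1]]$spliced_sequence),
               c("AUG", "AAA", "UAA"))
  # minus strand: genomic TTATTTCAT reverse-complements to the same ORF
  expect_equal(orfs[[2]]$spliced_sequence, "AUGAAAUAA")
  expect_equal(orfs[[2]]$strand, "-")
})

test_that("multi-block spliced sequence equals naive per-base concatenation", {
  # two-block ORF: 6 nt + 3 nt across an intron
  genome <- c(chr2 = paste0(strrep("G", 10), "ATGAAA", strrep("C", 7), "TAA",
                            strrep("G", 10)))
  blocks <- matrix(c(10L, 16L, 23L, 26L), ncol = 2, byrow = TRUE)
  orf <- orf_annotation("orf2b", "tx2b", "chr2", "+", blocks, "uORF",
                        "AUGAAAUAA", cds_start_distance = 0L)
  # oracle: walk each block base by base
  naive <- paste(unlist(lapply(seq_len(nrow(blocks)), function(i)
    strsplit(substr(genome[["chr2"]], blocks[i, 1] + 1, blocks[i, 2]),
             NULL)[[1]])), collapse = "")
  expect_equal(chartr("U", "T", orf$spliced_sequence), naive)
  expect_equal(nchar(orf$spliced_sequence), 9)
  # reader agrees
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_orf_bed(list(orf), tmp)
  back <- read_orf_bed(tmp, genome)
  expect_equal(back[[1]]$spliced_sequence, "AUGAAAUAA")
  expect_equal(back[[1]]$blocks, orf$blocks, ignore_attr = TRUE)
})

test_that("BED12 write/read round-trips bit-identically", {
  cfg <- sim_config(seed = 11, n_genes = 25)
  tx <- make_transcriptome(cfg)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_orf_bed(tx$orfs, f1)
  write_orf_bed(read_orf_bed(f1, tx$genome), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("length-not-divisible-by-3 records are rejected with a warning", {
  genome <- make_tiny_genome()
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t109\tgood|uORF|tx\t20\t+\t100\t100\t0\t1\t9,\t0,",
    "chr1\t100\t108\tbad|uORF|tx\t20\t+\t100\t100\t0\t1\t8,\t0,"), tmp)
  expect_warning(orfs <- read_orf_bed(tmp, genome), "divisible by 3")
  expect_length(orfs, 1)
  expect_equal(orfs[[1]]$orf_id, "good")
})

test_that("sequence index <-> genomic position mapping is the identity", {
  cfg <- sim_config(seed = 3, n_genes = 10)
  tx <- make_transcriptome(cfg)
  for (o in tx$orfs) {
    pos <- orf_positions(o)
    expect_equal(genomic_to_index(o, pos), seq_along(pos))
    # and the mapped base matches the genome (modulo strand)
    i <- length(pos) %/% 2 + 1
    gbase <- substr(tx$genome[[o$chrom]], pos[i], pos[i])
    expected <- chartr("U", "T", substr(o$spliced_sequence, i, i))
    if (o$strand == "-") expected <- chartr("ACGT", "TGCA", expected)
    expect_equal(gbase, expected)
  }
})

test_that("VCF reading populates flags, splits multiallelics, skips non-SNVs", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tA\tT\t.\tPASS\tAC=1;AN=143404;CTX=CAG",
    "chr1\t201\t.\tG\tA\t.\tAC0\tAC=4;AN=1000;CTX=AGT",
    "chr1\t301\t.\tA\tC,G\t.\tPASS\tAC=2,1;AN=1000;CTX=AAA",
    "chr1\t401\t.\tAT\tA\t.\tPASS\tAC=3;AN=1000"), tmp)
  expect_message(v <- read_variants_vcf(tmp), "1 non-SNV")
  expect_equal(nrow(v), 4)  # multiallelic split into two rows
  expect_true(v$singleton[v$pos == 101])
  expect_equal(v$filter[v$pos == 201], "AC0")        # retained, not filtered
  expect_equal(sum(v$pos == 301), 2)
  expect_equal(sort(v$ac[v$pos == 301]), c(1L, 2L))
})

test_that("QC keeps PASS, non-LCR records with AN >= 80% of max", {
  v <- as_variant_table(data.frame(
    chrom = "chr1", pos = 1:4, ref = "C", alt = "T",
    ac = 1L, an = c(100L, 79L, 100L, 100L),
    filter = c("PASS", "PASS", "PASS", "AC0"),
    lcr = c(FALSE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE))
  expect_message(kept <- qc_filter(v), "removed")
  expect_equal(kept$pos, 1L)          # AN=79 < 80, LCR, and AC0 all removed
  # equal AN, all PASS: everything retained
  v2 <- as_variant_table(data.frame(chrom = "chr1", pos = 1:3, ref = "C",
                                    alt = "T", ac = 1L, an = 500L,
                                    stringsAsFactors = FALSE))
  expect_equal(nrow(qc_filter(v2)), 3)
  expect_equal(nrow(qc_filter(v2[0, ])), 0)
})

test_that("context collapsing maps 64x3 raw contexts onto 96 classes", {
  expect_equal(normalize_context("ACG", "C", "T"), "ACG:C>T")
  # central G: reverse-complement the triplet, complement the alt
  expect_equal(normalize_context("CGT", "G", "A"), "ACG:C>T")
  bases <- c("A", "C", "G", "T")
  all_out <- character()
  for (l in bases) for (c in bases) for (r in bases)
    for (a in setdiff(bases, c))
      all_out <- c(all_out, normalize_context(paste0(l, c, r), c, a))
  expect_equal(length(all_out), 64 * 3)
  expect_equal(length(unique(all_out)), 96)
  expect_true(all(substr(unique(all_out), 2, 2) %in% c("A", "C")))
  # strand-collapse symmetry: each class has exactly two preimages
  expect_true(all(table(all_out) == 2))
  # N anywhere -> unknown
  expect_equal(normalize_context("ANG", "N", "T"), "unknown")
})

test_that("conservation track lookups return NA for absent positions", {
  tr <- conservation_track(c("chr1", "chr1"), c(5L, 6L), c(1.5, 3.2))
  expect_equal(track_lookup(tr, "chr1", 5L), 1.5)
  expect_true(is.na(track_lookup(tr, "chr1", 7L)))
  expect_false(identical(track_lookup(tr, "chr1", 7L), 0))
})

test_that("bedGraph round-trips through the reader", {
  tr <- conservation_track(rep("chr1", 4), c(10L, 11L, 12L, 50L),
                           c(-1.25, 2.5, 0, 7.75))
  tmp <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, tmp)
  tr2 <- read_bedgraph(tmp)
  expect_equal(track_lookup(tr2, "chr1", c(10L, 11L, 12L, 50L)),
               c(-1.25, 2.5, 0, 7.75))
})

test_that("CSC table validation demands exactly the 61 sense codons", {
  cfg <- sim_config(seed = 2)
  csc <- make_csc_table(cfg)
  expect_length(csc, 61)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_csc_table(csc, tmp)
  expect_equal(read_csc_table(tmp), csc)
  expect_error(as_csc_table(csc[-5]), "missing sense codon")
  bad <- c(csc, UAA = 0.1)
  expect_error(as_csc_table(bad), "stop codon")
})

test_that("rate tables reject non-collapsed contexts and cover lookups", {
  rates <- make_rates(c("ACG:C>T" = 1e-8, "AAA:A>G" = 2e-9))
  expect_equal(uorfsel:::rate_for_context(rates, "AAA:A>G"), 2e-9)
  expect_error(uorfsel:::rate_for_context(rates, "CCC:C>G"), "CCC:C>G")
  expect_error(as_rate_table(data.frame(context = "AGA", alt = "T",
                                        mu = 1e-8)), "collapsed")
})
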