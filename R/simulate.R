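## Synthetic-data generators. Every input format the pipeline consumes is
## generated here with known ground truth: a small genome with 5'UTRs and
## translated ORFs on both strands, a gnomAD-style SNV table whose
## singleton indicators follow a per-context baseline plus class-specific
## selection excess, a phyloP-style conservation track with designated
## conserved position classes, and a biobank with logistic-model
## phenotypes. All generators are pure functions of (config, seed):
## rerunning with the same config reproduces identical bytes.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions; they are chosen
#' once to emulate the qualitative features of the real data sources
#' (gnomAD v3-like variant tables, ribosome-profiling-style ORF sets, a
#' vertebrate-conservation-like track, an EHR-linked biobank) at desk
#' scale, and are documented in the methods vignette.
#'
#' @param seed Integer RNG seed; every generator derives its stream from
#'   it.
#' @param n_genes Number of protein-coding genes (each gets a 5'UTR and a
#'   short CDS).
#' @param utr_length Min/max 5'UTR length (nt).
#' @param uorf_rate Probability a gene's UTR carries a translated uORF; a
#'   carrying UTR gains a second uORF with probability `uorf_rate / 3`
#'   when space allows.
#' @param uorf_length_codons Min/max uORF length in codons (including
#'   start and stop).
#' @param start_weights Sampling weights over AUG/CUG/GUG/UUG start codons
#'   (non-AUG-skewed by default, as observed for translated uORFs).
#' @param stop_weights Sampling weights over UGA/UAG/UAA stop codons
#'   (UAA-depleted by default, as observed for translated uORFs).
#' @param strand_minus_frac Fraction of genes on the minus strand.
#' @param n_other_orfs Named counts of additional free-standing translated
#'   ORFs per non-uORF class (dORF, lncRNA, pseudogene).
#' @param mu_range Min/max context mutation rate (log-uniform across the
#'   96 collapsed context classes).
#' @param baseline_intercept,baseline_slope Generative singleton model:
#'   baseline singleton probability = intercept + slope * mu(context),
#'   which the MAPS calibration is designed to recover.
#' @param delta Named singleton excess per consequence class (the
#'   selection signal MAPS should estimate); classes not listed get 0.
#' @param variant_rate Per-ORF-position probability of emitting a variant.
#' @param utr_variant_rate Per-non-ORF-UTR-position probability of
#'   emitting a background variant.
#' @param n_calibration Number of neutral calibration (synonymous coding
#'   proxy) variants drawn on a dedicated calibration contig.
#' @param an_max Maximum allele number (cohort chromosomes).
#' @param fail_filter_rate,lcr_rate,low_an_rate Rates of non-PASS filter
#'   status, low-complexity flags, and low-AN records (exercising QC).
#' @param conservation List: `bg_mean`, `bg_sd` (background score
#'   distribution), `q` (named conserved-fraction per designated position
#'   class), `conserved_range`, `nonconserved_range` (score supports
#'   strictly above / below the threshold 2).
#' @param biobank List: `n_individuals`, `n_background_phenotypes`,
#'   `carrier_freq`, `target_or`, `prevalence`, `single_date_frac`,
#'   `missing_rate`, `strata_weights`, `age_beta`, `sex_beta`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_genes = 150L,
    utr_length = c(150L, 400L),
    uorf_rate = 0.6,
    uorf_length_codons = c(5L, 140L),
    start_weights = c(AUG = 0.35, CUG = 0.30, GUG = 0.20, UUG = 0.15),
    stop_weights = c(UGA = 0.45, UAG = 0.36, UAA = 0.19),
    strand_minus_frac = 0.5,
    n_other_orfs = c(dORF = 15L, lncRNA = 15L, pseudogene = 15L),
    mu_range = c(1e-9, 1e-7),
    baseline_intercept = 0.55,
    baseline_slope = -2e6,
    delta = c(stop_gain = 0.05, stop_strengthen = 0.04,
              start_disrupt = 0.04, missense = 0.005),
    variant_rate = 0.35,
    utr_variant_rate = 0.25,
    n_calibration = 20000L,
    an_max = 100000L,
    fail_filter_rate = 0.02,
    lcr_rate = 0.02,
    low_an_rate = 0.03,
    conservation = list(bg_mean = 0, bg_sd = 1.5,
                        q = c(stop_creating = 0.35, start_disrupt = 0.4,
                              uorf_all = 0.15),
                        conserved_range = c(2.5, 8),
                        nonconserved_range = c(-3, 1.5)),
    biobank = list(n_individuals = 5000L, n_background_phenotypes = 30L,
                   carrier_freq = 0.01, target_or = 3, prevalence = 0.05,
                   single_date_frac = 0.1, missing_rate = 0.02,
                   strata_weights = c(EUR = 0.7, AFR = 0.3),
                   age_beta = 0.02, sex_beta = 0.3)) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$start_weights) - 1) < 1e-8,
            abs(sum(cfg$stop_weights) - 1) < 1e-8,
            cfg$uorf_rate >= 0, cfg$uorf_rate <= 1,
            cfg$utr_length[1L] <= cfg$utr_length[2L],
            cfg$uorf_length_codons[1L] >= 3L,
            all(names(cfg$start_weights) == NUG_STARTS),
            all(names(cfg$stop_weights) == c("UGA", "UAG", "UAA")))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: %d genes, uORF rate %.2f, ",
                     "%d calibration variants, %d individuals\n"),
              x$seed, x$n_genes, x$uorf_rate, x$n_calibration,
              x$biobank$n_individuals))
  invisible(x)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

## A uORF-style RNA sequence: weighted start, sense-only internal codons,
## weighted stop.
random_orf_rna <- function(n_codons, start_weights, stop_weights) {
  start <- sample(names(start_weights), 1L, prob = start_weights)
  stop <- sample(names(stop_weights), 1L, prob = stop_weights)
  internal <- if (n_codons > 2L)
    sample(sense_codons(), n_codons - 2L, replace = TRUE) else character()
  paste(c(start, internal, stop), collapse = "")
}

#' Generate a synthetic transcriptome
#'
#' Lays out `n_genes` genes on one chromosome: each gene is a 5'UTR
#' followed (in transcript orientation) by a short CDS whose start
#' position anchors distance-to-CDS computations. Translated uORFs with
#' valid NUG starts, sense-only bodies and weighted stop codons are
#' embedded in UTRs on both strands; additional free-standing translated
#' ORFs carry the dORF/lncRNA/pseudogene classes. A separate calibration
#' contig provides neutral positions for MAPS calibration variants.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named DNA vector), `utrs`, `orfs`, `cds`
#'   (data frame chrom/start/end/strand/transcript_id, 0-based
#'   half-open).
#' @export
make_transcriptome <- function(config) {
  set.seed(config$seed)
  cds_len <- 60L
  gap <- 30L
  chrom <- "chr1"
  cursor <- 0L
  genome_parts <- character()
  utrs <- list()
  orfs <- list()
  cds_rows <- list()
  orf_n <- 0L
  for (g in seq_len(config$n_genes)) {
    U <- sample(config$utr_length[1L]:config$utr_length[2L], 1L)
    strand <- if (stats::runif(1) < config$strand_minus_frac) "-" else "+"
    tx_id <- sprintf("tx%04d", g)
    utr_rna <- dna_to_rna(random_dna(U))
    # place 0-2 non-overlapping uORFs
    n_uorf <- 0L
    if (stats::runif(1) < config$uorf_rate) n_uorf <- 1L
    if (n_uorf == 1L && stats::runif(1) < config$uorf_rate / 3) n_uorf <- 2L
    placed <- list()  # transcript-offset intervals [s, s+len)
    uorf_meta <- list()
    for (k in seq_len(n_uorf)) {
      nc <- sample(config$uorf_length_codons[1L]:config$uorf_length_codons[2L], 1L)
      len <- 3L * nc
      if (len > U - 3L) next
      ok <- FALSE
      for (try in 1:20) {
        s <- sample(0:(U - len), 1L)  # 0-based offset in UTR
        clash <- any(vapply(placed, function(iv)
          s < iv[2L] && iv[1L] < s + len, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) next
      rna <- random_orf_rna(nc, config$start_weights, config$stop_weights)
      substr(utr_rna, s + 1L, s + len) <- rna
      placed[[length(placed) + 1L]] <- c(s, s + len)
      uorf_meta[[length(uorf_meta) + 1L]] <-
        list(s = s, len = len, rna = rna)
    }
    # re-read embedded sequences (overlap-free, so they are intact)
    utr_dna <- rna_to_dna(utr_rna)
    cds_rna <- paste0("AUG", paste(sample(sense_codons(), cds_len / 3L - 2L,
                                          replace = TRUE), collapse = ""),
                      "UAA")
    tx_dna <- paste0(utr_dna, rna_to_dna(cds_rna))
    seg <- if (strand == "+") tx_dna else dna_revcomp(tx_dna)
    g0 <- cursor + gap
    genome_parts <- c(genome_parts, random_dna(gap), seg)
    cursor <- g0 + nchar(seg)
    if (strand == "+") {
      utr_blocks <- matrix(c(g0, g0 + U), ncol = 2L)
      cds_blocks <- c(g0 + U, g0 + U + cds_len)
    } else {
      utr_blocks <- matrix(c(g0 + cds_len, g0 + cds_len + U), ncol = 2L)
      cds_blocks <- c(g0, g0 + cds_len)
    }
    contained <- character()
    for (m in uorf_meta) {
      orf_n <- orf_n + 1L
      orf_id <- sprintf("uorf%05d", orf_n)
      blocks <- if (strand == "+")
        matrix(c(utr_blocks[1L] + m$s, utr_blocks[1L] + m$s + m$len),
               ncol = 2L)
      else
        matrix(c(utr_blocks[2L] - m$s - m$len, utr_blocks[2L] - m$s),
               ncol = 2L)
      orfs[[length(orfs) + 1L]] <- orf_annotation(
        orf_id, tx_id, chrom, strand, blocks, "uORF", m$rna,
        cds_start_distance = U - m$s - m$len)
      contained <- c(contained, orf_id)
    }
    utrs[[length(utrs) + 1L]] <- utr_annotation(
      tx_id, chrom, strand, utr_blocks, utr_rna, contained)
    cds_rows[[length(cds_rows) + 1L]] <- data.frame(
      chrom = chrom, start = cds_blocks[1L], end = cds_blocks[2L],
      strand = strand, transcript_id = tx_id, stringsAsFactors = FALSE)
  }
  # free-standing ORFs of the other classes
  for (cls in names(config$n_other_orfs)) {
    for (k in seq_len(config$n_other_orfs[[cls]])) {
      nc <- sample(config$uorf_length_codons[1L]:min(60L, config$uorf_length_codons[2L]), 1L)
      rna <- random_orf_rna(nc, config$start_weights, config$stop_weights)
      strand <- if (stats::runif(1) < config$strand_minus_frac) "-" else "+"
      dna <- rna_to_dna(rna)
      seg <- if (strand == "+") dna else dna_revcomp(dna)
      g0 <- cursor + gap
      genome_parts <- c(genome_parts, random_dna(gap), seg)
      cursor <- g0 + nchar(seg)
      orf_n <- orf_n + 1L
      orfs[[length(orfs) + 1L]] <- orf_annotation(
        sprintf("%s%05d", tolower(cls), orf_n), sprintf("%s_tx%05d",
                                                        tolower(cls), orf_n),
        chrom, strand, matrix(c(g0, g0 + nchar(dna)), ncol = 2L), cls, rna)
    }
  }
  genome <- c(chr1 = paste(genome_parts, collapse = ""),
              chrC = random_dna(max(1000L, config$n_calibration + 2L)))
  list(genome = genome, utrs = utrs, orfs = orfs,
       cds = do.call(rbind, cds_rows))
}

#' Generate the context mutation-rate table
#'
#' One rate per collapsed context class (32 triplets x 3 alts),
#' log-uniform over `mu_range`.
#'
#' @param config A [sim_config()].
#' @return Keyed rate table (see [as_rate_table()]).
#' @export
make_rate_table <- function(config) {
  set.seed(config$seed + 1L)
  triplets <- as.vector(outer(
    as.vector(outer(DNA_BASES, c("A", "C"), function(a, b) paste0(a, b))),
    DNA_BASES, paste0))
  rows <- list()
  for (tri in triplets) {
    central <- substr(tri, 2L, 2L)
    for (alt in setdiff(DNA_BASES, central)) {
      rows[[length(rows) + 1L]] <- data.frame(
        context = tri, alt = alt, methyl_level = 0L,
        mu = exp(stats::runif(1, log(config$mu_range[1L]),
                              log(config$mu_range[2L]))),
        stringsAsFactors = FALSE)
    }
  }
  as_rate_table(do.call(rbind, rows))
}

#' Generate a codon stability coefficient table
#'
#' One CSC score per sense codon, normal around zero on the scale of
#' published SLAM-seq-derived coefficients.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector over the 61 sense codons.
#' @export
make_csc_table <- function(config) {
  set.seed(config$seed + 5L)
  as_csc_table(stats::setNames(stats::rnorm(61, 0, 0.05), sense_codons()))
}

## Baseline singleton probability for context keys under the generative
## model; errors if baseline + delta leaves [0, 1].
sim_singleton_prob <- function(config, rates, context_keys, delta) {
  mu <- rate_for_context(rates, context_keys)
  p <- config$baseline_intercept + config$baseline_slope * mu + delta
  if (any(p < 0 | p > 1))
    stop("baseline + delta outside [0, 1]; adjust the configuration")
  p
}

#' Simulate a gnomAD-style variant table
#'
#' Emits SNVs at ORF positions (class = the reading-frame consequence of
#' the drawn substitution), at non-ORF UTR positions (class
#' `utr_background`), and on the calibration contig (class
#' `cds_synonymous`, the neutral calibration stand-in). Each variant's
#' singleton indicator is Bernoulli(baseline(context) + delta_class); AC,
#' AN, FILTER and LCR fields are drawn so the QC filters have work to do.
#'
#' @param config A [sim_config()].
#' @param tx Output of [make_transcriptome()].
#' @param rates Rate table from [make_rate_table()].
#' @return List: `variants` (variant table), `truth` (sidecar data frame
#'   chrom/pos/ref/alt/class/orf_id/delta).
#' @export
simulate_variants <- function(config, tx, rates) {
  set.seed(config$seed + 2L)
  genome <- tx$genome
  rows <- list()
  random_alt <- function(ref, bases) {
    vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
           USE.NAMES = FALSE)
  }
  # ORF variants
  for (o in tx$orfs) {
    gpos <- orf_positions(o)
    L <- length(gpos)
    hit <- which(stats::runif(L) < config$variant_rate)
    if (length(hit) == 0L) next
    ref_tx <- substring(o$spliced_sequence, hit, hit)
    alt_tx <- random_alt(ref_tx, RNA_BASES)
    codon_index <- (hit - 1L) %/% 3L
    offset <- (hit - 1L) %% 3L
    ref_codon <- substring(o$spliced_sequence, codon_index * 3L + 1L,
                           codon_index * 3L + 3L)
    alt_codon <- mapply(function(rc, off, a) {
      substr(rc, off + 1L, off + 1L) <- a
      rc
    }, ref_codon, offset, alt_tx, USE.NAMES = FALSE)
    class <- mapply(classify_codon_change, ref_codon, alt_codon, offset,
                    codon_index == 0L, USE.NAMES = FALSE)
    flip <- o$strand == "-"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = o$chrom, pos = gpos[hit],
      ref = rna_to_dna(if (flip) chartr("ACGU", "UGCA", ref_tx) else ref_tx),
      alt = rna_to_dna(if (flip) chartr("ACGU", "UGCA", alt_tx) else alt_tx),
      class = class, orf_id = o$orf_id,
      delta = ifelse(class %in% names(config$delta),
                     config$delta[class], 0),
      stringsAsFactors = FALSE)
  }
  # UTR background variants outside ORFs
  for (u in tx$utrs) {
    upos <- orf_positions(u)
    in_orf <- rep(FALSE, length(upos))
    for (oid in u$contained_orf_ids) {
      o <- Find(function(x) x$orf_id == oid, tx$orfs)
      in_orf <- in_orf | upos %in% orf_positions(o)
    }
    cand <- which(!in_orf & stats::runif(length(upos)) < config$utr_variant_rate)
    if (length(cand) == 0L) next
    ref <- substring(genome[[u$chrom]], upos[cand], upos[cand])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = u$chrom, pos = upos[cand], ref = ref,
      alt = random_alt(ref, DNA_BASES), class = "utr_background",
      orf_id = NA_character_, delta = 0, stringsAsFactors = FALSE)
  }
  # calibration variants on the dedicated contig
  n_cal <- config$n_calibration
  cal_pos <- sort(sample(2:(nchar(genome[["chrC"]]) - 1L), n_cal,
                         replace = n_cal > nchar(genome[["chrC"]]) - 2L))
  cal_ref <- substring(genome[["chrC"]], cal_pos, cal_pos)
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = "chrC", pos = cal_pos, ref = cal_ref,
    alt = random_alt(cal_ref, DNA_BASES), class = "cds_synonymous",
    orf_id = NA_character_, delta = 0, stringsAsFactors = FALSE)
  truth <- do.call(rbind, rows)
  # drop duplicate sites (calibration resampling may repeat a position)
  truth <- truth[!duplicated(paste(truth$chrom, truth$pos)), ]
  context <- context_from_genome(genome, truth$chrom, truth$pos,
                                 truth$ref, truth$alt)
  usable <- context != "unknown"
  truth <- truth[usable, ]
  context <- context[usable]
  p_single <- sim_singleton_prob(config, rates, context, truth$delta)
  singleton <- stats::runif(nrow(truth)) < p_single
  n <- nrow(truth)
  an <- round(config$an_max * stats::runif(n, 0.95, 1))
  low <- stats::runif(n) < config$low_an_rate
  an[low] <- round(config$an_max * stats::runif(sum(low), 0.5, 0.75))
  ac_nonsingleton <- sample(2:50, n, replace = TRUE,
                            prob = 1 / (2:50)^1.5)
  variants <- as_variant_table(data.frame(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    ac = ifelse(singleton, 1L, ac_nonsingleton), an = an,
    filter = ifelse(stats::runif(n) < config$fail_filter_rate, "AC0", "PASS"),
    lcr = stats::runif(n) < config$lcr_rate,
    context = context, stringsAsFactors = FALSE))
  truth$singleton <- singleton
  rownames(truth) <- NULL
  list(variants = variants, truth = truth)
}

#' Simulate a conservation track
#'
#' Designated position classes exceed the strong-conservation threshold
#' (2) with their configured probability `q`; every other base of the
#' supplied chromosomes gets a background score from the configured
#' normal distribution.
#'
#' @param config A [sim_config()].
#' @param genome Named DNA vector (scored end to end).
#' @param positions_by_class Named list of data frames (chrom, pos);
#'   names must appear in `config$conservation$q`.
#' @return A [conservation_track()] plus attribute `"designated"` (the
#'   per-class conserved indicators, for recovery tests).
#' @export
simulate_conservation <- function(config, genome, positions_by_class = list()) {
  set.seed(config$seed + 3L)
  cc <- config$conservation
  chroms <- names(genome)
  chrom_v <- rep(chroms, nchar(genome))
  pos_v <- unlist(lapply(nchar(genome), seq_len), use.names = FALSE)
  score <- stats::rnorm(length(pos_v), cc$bg_mean, cc$bg_sd)
  names(score) <- paste0(chrom_v, ":", pos_v)
  designated <- list()
  for (cls in names(positions_by_class)) {
    q <- cc$q[[cls]]
    if (is.null(q)) stop("no conserved fraction configured for class ", cls)
    pb <- positions_by_class[[cls]]
    conserved <- stats::runif(nrow(pb)) < q
    hi <- stats::runif(sum(conserved), cc$conserved_range[1L],
                       cc$conserved_range[2L])
    lo <- stats::runif(sum(!conserved), cc$nonconserved_range[1L],
                       cc$nonconserved_range[2L])
    keys <- paste0(pb$chrom, ":", pb$pos)
    score[keys[conserved]] <- hi
    score[keys[!conserved]] <- lo
    designated[[cls]] <- conserved
  }
  track <- structure(list(scores = score), class = "conservation_track")
  attr(track, "designated") <- designated
  track
}

#' Simulate a biobank
#'
#' Test-variant dosages are Hardy-Weinberg draws at the configured
#' carrier frequency; each test variant gets a target phenotype whose
#' case probability follows the logistic model
#' `logit(p) = b0 + log(OR) * dosage + age/sex effects`, with `b0` solved
#' so the population prevalence matches the configuration. Cases receive
#' two or more distinct event dates; a configured fraction of non-cases
#' receives exactly one date (exercising the single-date exclusion);
#' background phenotypes are genotype-independent.
#'
#' @param config A [sim_config()].
#' @param test_variants Character ids of test variants (one target
#'   phenotype each); defaults to one variant `"var1"`.
#' @param target_or Per-variant odds ratios (recycled).
#' @return A [biobank_table()] plus attribute `"truth"` (data frame
#'   variant_id, phenotype, or_).
#' @export
simulate_biobank <- function(config, test_variants = "var1",
                             target_or = NULL) {
  set.seed(config$seed + 4L)
  bc <- config$biobank
  n <- bc$n_individuals
  target_or <- rep(target_or %||% bc$target_or,
                   length.out = length(test_variants))
  ids <- sprintf("ind%05d", seq_len(n))
  covariates <- data.frame(
    individual_id = ids,
    age = round(stats::rnorm(n, 55, 12)),
    sex = stats::rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE)
  for (k in 1:10) covariates[[paste0("PC", k)]] <- stats::rnorm(n)
  covariates$stratum <- sample(names(bc$strata_weights), n, replace = TRUE,
                               prob = bc$strata_weights)
  genotypes <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  events <- list()
  truth <- list()
  date_pool <- seq(as.Date("2015-01-01"), as.Date("2020-12-31"), by = "day")
  add_events <- function(id_v, code, n_dates) {
    do.call(rbind, lapply(seq_along(id_v), function(i) data.frame(
      individual_id = id_v[i], code = code,
      date = as.character(sample(date_pool, n_dates[i])),
      stringsAsFactors = FALSE)))
  }
  lin_cov <- bc$age_beta * (covariates$age - mean(covariates$age)) +
    bc$sex_beta * covariates$sex
  for (vi in seq_along(test_variants)) {
    vid <- test_variants[vi]
    dos <- stats::rbinom(n, 2L, bc$carrier_freq)
    lin <- log(target_or[vi]) * dos + lin_cov
    b0 <- tryCatch(stats::uniroot(function(b)
      mean(stats::plogis(b + lin)) - bc$prevalence, c(-30, 30))$root,
      error = function(e) stop("prevalence ", bc$prevalence,
                               " infeasible under the covariate model"))
    case <- stats::runif(n) < stats::plogis(b0 + lin)
    code <- sprintf("P%03d", vi)
    n_case <- sum(case)
    if (n_case > 0L)
      events[[length(events) + 1L]] <-
        add_events(ids[case], code, 2L + stats::rpois(n_case, 1))
    non_case <- which(!case)
    single <- non_case[stats::runif(length(non_case)) < bc$single_date_frac]
    if (length(single) > 0L)
      events[[length(events) + 1L]] <-
        add_events(ids[single], code, rep(1L, length(single)))
    dos_obs <- ifelse(stats::runif(n) < bc$missing_rate, NA_integer_, dos)
    genotypes[[vid]] <- dos_obs
    truth[[length(truth) + 1L]] <- data.frame(
      variant_id = vid, phenotype = code, or_ = target_or[vi],
      stringsAsFactors = FALSE)
  }
  for (b in seq_len(bc$n_background_phenotypes)) {
    code <- sprintf("B%03d", b)
    prev <- stats::runif(1, 0.01, 0.1)
    case <- which(stats::runif(n) < prev)
    if (length(case) > 0L)
      events[[length(events) + 1L]] <-
        add_events(ids[case], code, 2L + stats::rpois(length(case), 1))
  }
  bb <- biobank_table(genotypes, covariates, do.call(rbind, events))
  attr(bb, "truth") <- do.call(rbind, truth)
  bb
}
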