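## End-to-end orchestration: simulate -> serialize -> re-read through the
## format readers -> annotate -> MAPS / stop-usage / conservation / PheWAS,
## with every stage's parameters and output hashes recorded in a JSON run
## manifest. All randomness derives from the configuration seed, so a
## rerun with the same configuration reproduces byte-identical outputs.

## Variant-table join key (one biallelic SNV).
variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' MAPS class labels from deduplicated consequence calls
#'
#' Builds the analysis classes reported by the pipeline: all uORF SNVs,
#' UTC (stop-gain) variants, UAA-creating UTCs, stop-strengthening,
#' start-disrupting/maintaining, uORF missense/synonymous, codon
#' optimality directions, and missense/synonymous/stop-gain analogues for
#' the other ORF classes.
#'
#' @param calls Deduplicated consequence calls ([dedup_most_severe()]).
#' @param uaa_includes_strengthen Count stop-strengthening variants whose
#'   new stop is UAA as UAA-creating (off by default: the UAA class is
#'   stop gains from sense codons).
#' @return Named list of logical masks over rows of `calls`.
#' @export
maps_class_masks <- function(calls, uaa_includes_strengthen = FALSE) {
  u <- calls$orf_class == "uORF"
  uaa <- (calls$category == "stop_gain" & calls$new_stop %in% "UAA")
  if (uaa_includes_strengthen)
    uaa <- uaa | (calls$category == "stop_strengthen" &
                    calls$new_stop %in% "UAA")
  masks <- list(
    all_uorf = u,
    utc_all = u & calls$category == "stop_gain",
    utc_uaa = u & uaa,
    stop_strengthen = u & calls$category == "stop_strengthen",
    start_disrupt = u & calls$category == "start_disrupt",
    start_maintain = u & calls$category == "start_maintain",
    uorf_missense = u & calls$category == "missense",
    uorf_synonymous = u & calls$category == "synonymous",
    optimality_increasing = u & calls$optimality == "increasing",
    optimality_decreasing = u & calls$optimality == "decreasing")
  for (cls in c("dORF", "lncRNA", "pseudogene")) {
    m <- calls$orf_class == cls
    masks[[paste0(tolower(cls), "_stop_gain")]] <-
      m & calls$category == "stop_gain"
    masks[[paste0(tolower(cls), "_missense")]] <-
      m & calls$category == "missense"
    masks[[paste0(tolower(cls), "_synonymous")]] <-
      m & calls$category == "synonymous"
  }
  masks
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates all inputs from `config`, writes them in their on-disk
#' formats (FASTA, BED12, VCF, bedGraph, TSV), reads everything back
#' through the package readers, and runs the annotation, MAPS,
#' stop-usage, conservation and PheWAS stages, writing figure-style
#' summary tables as JSON/TSV plus a run manifest with md5 hashes of
#' every output.
#'
#' @param config A [sim_config()].
#' @param outdir Run directory (created; existing outputs overwritten).
#' @param n_boot Bootstrap iterations for confidence intervals.
#' @param n_iter Iterations for permutation p-values and background
#'   sampling.
#' @param min_class_n Smallest variant class scored by MAPS.
#' @return Invisible list with the per-stage results and `manifest_path`.
#' @export
run_pipeline <- function(config = sim_config(), outdir, n_boot = 2000L,
                         n_iter = 2000L, min_class_n = 10L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  pfile <- function(name) {
    paths[[name]] <<- file.path(outdir, name)
    paths[[name]]
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    tx <- make_transcriptome(config)
    rates <- make_rate_table(config)
    csc <- make_csc_table(config)
    vr <- simulate_variants(config, tx, rates)
    stop_pos <- do.call(rbind, lapply(
      Filter(function(o) o$orf_class == "uORF", tx$orfs),
      find_potential_stop_positions))
    start_pos <- do.call(rbind, lapply(
      Filter(function(o) o$orf_class == "uORF", tx$orfs),
      find_start_disrupting_positions))
    uorf_pos <- do.call(rbind, lapply(
      Filter(function(o) o$orf_class == "uORF", tx$orfs), function(o)
        data.frame(chrom = o$chrom, pos = orf_positions(o))))
    track <- simulate_conservation(config, tx$genome, list(
      stop_creating = data.frame(chrom = "chr1", pos = stop_pos$pos),
      start_disrupt = data.frame(chrom = "chr1", pos = start_pos$pos),
      uorf_all = data.frame(chrom = "chr1",
                            pos = setdiff(uorf_pos$pos,
                                          c(stop_pos$pos, start_pos$pos)))))
    bb <- simulate_biobank(config, test_variants = c("var1", "var2"))
    write_genome_fasta(tx$genome, pfile("genome.fa"))
    write_orf_bed(tx$orfs, pfile("orfs.bed"))
    write_utr_bed(tx$utrs, pfile("utrs.bed"))
    write_variants_vcf(vr$variants, pfile("variants.vcf"), genome = tx$genome)
    utils::write.table(vr$truth, pfile("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_rate_table(rates, pfile("rates.tsv"))
    write_csc_table(csc, pfile("csc.tsv"))
    write_bedgraph(track, pfile("phylop.bedGraph"))
    write_biobank(bb, file.path(outdir, "biobank"))
    for (f in c("genotypes.tsv", "covariates.tsv", "events.tsv"))
      paths[[paste0("biobank/", f)]] <- file.path(outdir, "biobank", f)
    utils::write.table(tx$cds, pfile("cds.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(truth = vr$truth, bb_truth = attr(bb, "truth"))
  })

  ## -- read back through the format readers --------------------------------
  inputs <- stage("read", {
    genome <- as_genome(paths[["genome.fa"]])
    orfs <- read_orf_bed(paths[["orfs.bed"]], genome)
    list(genome = genome, orfs = orfs,
         utrs = read_utr_bed(paths[["utrs.bed"]], genome, orfs = orfs),
         variants = read_variants_vcf(paths[["variants.vcf"]],
                                      genome = genome),
         rates = read_rate_table(paths[["rates.tsv"]]),
         csc = read_csc_table(paths[["csc.tsv"]]),
         track = read_bedgraph(paths[["phylop.bedGraph"]]),
         bb = read_biobank(file.path(outdir, "biobank", "genotypes.tsv"),
                           file.path(outdir, "biobank", "covariates.tsv"),
                           file.path(outdir, "biobank", "events.tsv")),
         cds = utils::read.delim(paths[["cds.tsv"]],
                                 stringsAsFactors = FALSE))
  })

  ## -- annotate -------------------------------------------------------------
  ann <- stage("annotate", {
    qc <- qc_filter(inputs$variants)
    calls <- classify_variants(inputs$orfs, qc, csc = inputs$csc)
    dedup <- dedup_most_severe(calls)
    utils::write.table(calls, pfile("calls_all.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dedup, pfile("calls_dedup.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(qc = qc, calls = calls, dedup = dedup)
  })

  ## -- MAPS -----------------------------------------------------------------
  maps_res <- stage("maps", {
    set.seed(config$seed + 10L)
    qc <- ann$qc
    truth_key <- variant_key(sim$truth)
    calib <- qc[variant_key(qc) %in%
                  truth_key[sim$truth$class == "cds_synonymous"], ]
    model <- maps_fit(calib, inputs$rates)
    dedup <- ann$dedup
    class_rows <- lapply(maps_class_masks(dedup), function(m)
      qc[variant_key(qc) %in% variant_key(dedup[m, ]), ])
    scored <- Filter(function(v) nrow(v) >= min_class_n, class_rows)
    tab <- do.call(rbind, lapply(names(scored), function(lbl)
      as.data.frame(maps_score(scored[[lbl]], model, label = lbl,
                               n_boot = n_boot))))
    pvals <- list()
    if (all(c("utc_all", "all_uorf") %in% names(scored))) {
      pvals$utc_vs_all_uorf <- maps_pvalue(scored$utc_all, scored$all_uorf,
                                           model, n_iter = n_iter)
      matched <- match_by_context(scored$utc_all, scored$all_uorf)
      pvals$utc_vs_context_matched <-
        maps_pvalue(scored$utc_all, matched, model, n_iter = n_iter)
    }
    if (all(c("uorf_missense", "uorf_synonymous") %in% names(scored)))
      pvals$missense_vs_synonymous <-
        maps_pvalue(scored$uorf_missense, scored$uorf_synonymous, model,
                    n_iter = n_iter)
    calib_score <- maps_score(calib, model, label = "calibration")
    out <- list(model_coefficients = as.list(coef(model)),
                calibration_maps = calib_score$maps,
                classes = tab, pvalues = pvals)
    jsonlite::write_json(out, pfile("maps.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    c(out, list(model = model, classes_rows = scored, calib = calib))
  })

  ## -- stop-codon usage -----------------------------------------------------
  usage <- stage("stop_usage", {
    set.seed(config$seed + 11L)
    uorfs <- Filter(function(o) o$orf_class == "uORF", inputs$orfs)
    freq <- uorf_stop_frequencies(uorfs, n_boot = n_iter)
    bg_all <- background_stop_distribution(inputs$utrs, n_iter = n_iter)
    bg_nonorf <- background_stop_distribution(
      inputs$utrs, n_iter = n_iter, exclude_orf_overlap = TRUE,
      orfs = uorfs)
    out <- list(
      uorf_proportions = stats::setNames(as.list(freq$proportions),
                                         freq$codons),
      n_uorfs = freq$n,
      background_mean = as.list(colMeans(bg_all)),
      background_nonorf_mean = as.list(colMeans(bg_nonorf)),
      p_uaa_depletion_all = usage_pvalue(freq$draws, bg_all, "UAA",
                                         "depletion"),
      p_uaa_depletion_nonorf = usage_pvalue(freq$draws, bg_nonorf, "UAA",
                                            "depletion"),
      p_uga_enrichment_all = usage_pvalue(freq$draws, bg_all, "UGA",
                                          "enrichment"),
      p_uag_enrichment_all = usage_pvalue(freq$draws, bg_all, "UAG",
                                          "enrichment"))
    jsonlite::write_json(out, pfile("stop_usage.json"), auto_unbox = TRUE,
                         digits = NA)
    out
  })

  ## -- conservation ---------------------------------------------------------
  cons <- stage("conservation", {
    set.seed(config$seed + 12L)
    uorfs <- Filter(function(o) o$orf_class == "uORF", inputs$orfs)
    stop_pos <- do.call(rbind, lapply(uorfs, find_potential_stop_positions))
    stop_pos$chrom <- "chr1"
    start_pos <- do.call(rbind, lapply(uorfs, find_start_disrupting_positions))
    start_pos$chrom <- "chr1"
    oof_pos <- do.call(rbind, lapply(uorfs, find_start_disrupting_positions,
                                     in_frame = FALSE))
    utr_pool <- do.call(rbind, lapply(inputs$utrs, function(u)
      find_utr_stop_creating_positions(
        u, mask_orfs = Filter(function(o)
          o$orf_id %in% u$contained_orf_ids, uorfs))))
    matched <- match_by_cds_distance(stop_pos, utr_pool)
    out <- list(
      stop_creating = unclass(conserved_proportion(stop_pos, inputs$track,
                                                   n_boot = n_boot)),
      utr_matched_control = unclass(conserved_proportion(
        matched, inputs$track, n_boot = n_boot)),
      start_disrupt = unclass(conserved_proportion(start_pos, inputs$track,
                                                   n_boot = n_boot)),
      p_stop_vs_matched = proportion_pvalue(stop_pos, matched, inputs$track,
                                            n_iter = n_iter),
      p_start_vs_out_of_frame = if (!is.null(oof_pos) && nrow(oof_pos) > 0L) {
        oof_pos$chrom <- "chr1"
        proportion_pvalue(start_pos, oof_pos, inputs$track, n_iter = n_iter)
      } else NA)
    jsonlite::write_json(out, pfile("conservation.json"), auto_unbox = TRUE,
                         digits = NA)
    out
  })

  ## -- PheWAS ---------------------------------------------------------------
  phe <- stage("phewas", {
    set.seed(config$seed + 13L)
    bb <- inputs$bb
    test_vars <- setdiff(names(bb$genotypes), "individual_id")
    res <- list()
    for (vid in test_vars) {
      dos <- stats::setNames(bb$genotypes[[vid]], bb$genotypes$individual_id)
      res[[vid]] <- run_phewas(bb, dos, id = vid)
    }
    res_df <- do.call(rbind, Filter(Negate(is.null), res))
    codes <- sort(unique(bb$events$code))
    thr <- phewas_thresholds(length(test_vars), length(codes))
    utils::write.table(res_df, pfile("phewas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out <- list(thresholds = thr, n_variants = length(test_vars),
                n_phenotypes = length(codes))
    jsonlite::write_json(out, pfile("phewas.json"), auto_unbox = TRUE,
                         digits = NA)
    c(out, list(results = res_df))
  })

  ## -- manifest -------------------------------------------------------------
  files <- unlist(paths, use.names = FALSE)
  manifest <- list(
    package = "uorfsel",
    version = as.character(utils::packageVersion("uorfsel")),
    seed = config$seed,
    config = unclass(config),
    parameters = list(n_boot = n_boot, n_iter = n_iter,
                      min_class_n = min_class_n),
    stages = c("simulate", "read", "annotate", "maps", "stop_usage",
               "conservation", "phewas"),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = config, truth = sim$truth,
                 bb_truth = sim$bb_truth, inputs = inputs,
                 annotate = ann, maps = maps_res, stop_usage = usage,
                 conservation = cons, phewas = phe,
                 manifest_path = manifest_path))
}

#' Output hashes of a pipeline run
#'
#' @param manifest_path Path to a run manifest written by
#'   [run_pipeline()].
#' @return Named character vector of md5 hashes per output file.
#' @export
manifest_hashes <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  vapply(m$outputs, function(o) o$md5, character(1))
}
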