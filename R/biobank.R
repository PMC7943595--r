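## Biobank container: genotype dosages, covariates, dated phenotype events
## and per-variant CDS annotations for burden building.

#' Assemble a biobank table
#'
#' @param genotypes Data frame: `individual_id` plus one dosage column per
#'   test variant (0/1/2 or NA for missing genotypes).
#' @param covariates Data frame: `individual_id`, `age`, `sex` (0/1),
#'   `PC1`..`PC10`; `age2` is derived. Optionally `stratum` (ancestry
#'   label) for stratified association and meta-analysis.
#' @param events Data frame of dated phenotype codes: `individual_id`,
#'   `code`, `date` (coercible to `Date`).
#' @param variant_annotations Data frame: `variant_id`, `cds_labels`
#'   (comma-separated subset of synonymous/missense/pLOF), `revel`, `maf`.
#' @return Object of class `biobank_table`.
#' @export
biobank_table <- function(genotypes, covariates, events,
                          variant_annotations = NULL) {
  stopifnot("individual_id" %in% names(genotypes),
            "individual_id" %in% names(covariates),
            all(c("individual_id", "code", "date") %in% names(events)))
  dos <- as.matrix(genotypes[setdiff(names(genotypes), "individual_id")])
  if (!all(dos %in% c(0, 1, 2) | is.na(dos)))
    stop("dosages must be 0, 1, 2 or NA")
  need <- c("age", "sex", paste0("PC", 1:10))
  missing_cov <- setdiff(need, names(covariates))
  if (length(missing_cov) > 0L)
    stop("covariates missing column(s): ", paste(missing_cov, collapse = ", "))
  if (anyNA(covariates[need])) stop("covariate vectors must be complete")
  if (!setequal(genotypes$individual_id, covariates$individual_id))
    stop("genotype and covariate individuals differ")
  covariates$age2 <- covariates$age^2
  events$date <- as.Date(events$date)
  structure(list(genotypes = genotypes, covariates = covariates,
                 events = events, variant_annotations = variant_annotations),
            class = "biobank_table")
}

#' @export
print.biobank_table <- function(x, ...) {
  cat(sprintf(paste0("<biobank_table> %d individuals, %d test variant(s), ",
                     "%d phenotype event(s)\n"),
              nrow(x$genotypes), ncol(x$genotypes) - 1L, nrow(x$events)))
  invisible(x)
}

#' Read a biobank table from TSV files
#'
#' @param genotypes_path,covariates_path,events_path,annotations_path
#'   TSV files as described in [biobank_table()]; `annotations_path` is
#'   optional.
#' @return A `biobank_table`.
#' @export
read_biobank <- function(genotypes_path, covariates_path, events_path,
                         annotations_path = NULL) {
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE,
                                      check.names = FALSE)
  ann <- if (!is.null(annotations_path)) rd(annotations_path) else NULL
  biobank_table(rd(genotypes_path), rd(covariates_path), rd(events_path), ann)
}

#' Write a biobank table to TSV files
#'
#' @param bb A `biobank_table`.
#' @param dir Output directory; files `genotypes.tsv`, `covariates.tsv`,
#'   `events.tsv` and (if present) `variant_annotations.tsv` are written.
#' @return The directory path, invisibly.
#' @export
write_biobank <- function(bb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(bb$genotypes, "genotypes.tsv")
  cov <- bb$covariates[setdiff(names(bb$covariates), "age2")]
  wr(cov, "covariates.tsv")
  ev <- bb$events
  ev$date <- as.character(ev$date)
  wr(ev[order(ev$individual_id, ev$code, ev$date), ], "events.tsv")
  if (!is.null(bb$variant_annotations))
    wr(bb$variant_annotations, "variant_annotations.tsv")
  invisible(dir)
}
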