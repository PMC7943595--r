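## PheWAS and gene-burden association layer: case/control derivation from
## dated phenotype codes, eligibility filters, covariate-adjusted logistic
## regression under an additive genetic model, inverse-variance-weighted
## meta-analysis across ancestry strata, and the multiple-testing lines.

PHEWAS_COVARIATES <- c("age", "age2", "sex", paste0("PC", 1:10))

#' Derive case/control status from dated phenotype events
#'
#' An individual is a case for a phenotype code when it was recorded on at
#' least `min_case_dates` distinct dates, a control when the code never
#' appears, and excluded otherwise (the single-date rule removes
#' likely rule-out diagnoses). Duplicate (code, date) records collapse to
#' one date. Biobanks differ: the two-date rule suits EHR billing data
#' (PMBB-style); `min_case_dates = 1` reproduces the single-encounter
#' (UKB-style) rule.
#'
#' @param events Data frame: individual_id, code, date.
#' @param phenotype_code Code to derive status for.
#' @param ids Character vector of all individuals in the cohort (controls
#'   are individuals with no event for the code, so the universe must be
#'   supplied).
#' @param min_case_dates Distinct dates required for case status.
#' @param exclusion_codes Optional related codes: individuals carrying any
#'   of them (on any number of dates) are excluded from the control set.
#' @return Named character vector over `ids` with values `"case"`,
#'   `"control"` or `"excluded"`.
#' @export
derive_case_control <- function(events, phenotype_code, ids,
                                min_case_dates = 2L,
                                exclusion_codes = character()) {
  ev <- events[events$code == phenotype_code, ]
  n_dates <- tapply(as.character(ev$date), ev$individual_id,
                    function(d) length(unique(d)))
  status <- stats::setNames(rep("control", length(ids)), ids)
  have <- intersect(names(n_dates), ids)
  status[have] <- ifelse(n_dates[have] >= min_case_dates, "case", "excluded")
  if (length(exclusion_codes) > 0L) {
    rel <- unique(events$individual_id[events$code %in% exclusion_codes])
    drop <- intersect(rel, ids[status[ids] == "control"])
    status[drop] <- "excluded"
  }
  status
}

#' Eligibility of a variant x phenotype test
#'
#' @param dosages Numeric dosage vector (0/1/2, NA missing).
#' @param statuses Status vector from [derive_case_control()] aligned with
#'   `dosages`.
#' @param min_alt_alleles Minimum total alternate alleles among
#'   non-missing genotypes.
#' @param max_missing_frac Maximum fraction of missing genotypes.
#' @param min_cases Minimum number of cases.
#' @return List: `tested` (logical) and `reasons` (character vector of
#'   machine-readable failure reasons, empty when tested).
#' @export
eligibility_filters <- function(dosages, statuses, min_alt_alleles = 5L,
                                max_missing_frac = 0.5, min_cases = 20L) {
  if (length(dosages) != length(statuses))
    stop("dosages and statuses must be aligned")
  reasons <- character()
  if (sum(dosages, na.rm = TRUE) < min_alt_alleles)
    reasons <- c(reasons, "min_alt_alleles")
  if (mean(is.na(dosages)) > max_missing_frac)
    reasons <- c(reasons, "max_missing_frac")
  if (sum(statuses == "case") < min_cases)
    reasons <- c(reasons, "min_cases")
  list(tested = length(reasons) == 0L, reasons = reasons)
}

#' Covariate-adjusted logistic association
#'
#' Fits `case ~ dosage + age + age2 + sex + PC1..PC10` by maximum
#' likelihood under an additive genetic model and reports the Wald test
#' for the dosage term. Individuals with excluded status or missing
#' dosage are dropped. Quasi-complete separation (non-convergence or an
#' exploding standard error) is detected and flagged in the result rather
#' than silently returned; flagged results should be excluded from
#' significance thresholding.
#'
#' @param dosages Dosage vector (0/1/2, NA missing).
#' @param statuses Status vector ("case"/"control"/"excluded"), aligned.
#' @param covariates Data frame of covariates aligned with `dosages`, or
#'   NULL for an unadjusted fit. Columns used: age, age2, sex, PC1..PC10
#'   (those present).
#' @param id Variant or gene identifier for the result row.
#' @param phenotype Phenotype code for the result row.
#' @param stratum Stratum label (e.g. ancestry) for the result row.
#' @return One-row data frame of class `assoc_result`: id, phenotype,
#'   stratum, beta, se, or_, ci_low, ci_high, p, n_cases, n_controls,
#'   separation, converged.
#' @export
logistic_assoc <- function(dosages, statuses, covariates = NULL,
                           id = "variant", phenotype = "phenotype",
                           stratum = "all") {
  keep <- statuses != "excluded" & !is.na(dosages)
  y <- as.integer(statuses[keep] == "case")
  df <- data.frame(y = y, dosage = dosages[keep])
  if (!is.null(covariates)) {
    use <- intersect(PHEWAS_COVARIATES, names(covariates))
    df <- cbind(df, covariates[keep, use, drop = FALSE])
  }
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  sm <- suppressWarnings(summary(fit))$coefficients
  beta <- sm["dosage", "Estimate"]
  se <- sm["dosage", "Std. Error"]
  separation <- !fit$converged || se > 50 || abs(beta) > 15
  res <- data.frame(
    id = id, phenotype = phenotype, stratum = stratum,
    beta = beta, se = se, or_ = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    n_cases = sum(y == 1L), n_controls = sum(y == 0L),
    separation = separation, converged = fit$converged,
    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", class(res))
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf(paste0("<assoc_result> %s x %s [%s]: OR %.3f ",
                       "(%.3f-%.3f), p = %.3g, %d cases / %d controls%s\n"),
                x$id[i], x$phenotype[i], x$stratum[i], x$or_[i], x$ci_low[i],
                x$ci_high[i], x$p[i], x$n_cases[i], x$n_controls[i],
                if (x$separation[i]) " [separation]" else ""))
  invisible(x)
}

#' Inverse-variance-weighted meta-analysis across strata
#'
#' Combines per-stratum log-odds estimates with weights `1/se^2`:
#' pooled beta is the weighted mean, pooled se is `(sum w)^(-1/2)`, and
#' the p-value is two-sided normal. Strata flagged for separation are
#' dropped with a message.
#'
#' @param results Data frame of [logistic_assoc()] rows (one per stratum).
#' @return One-row `assoc_result` with stratum `"meta"` (a single usable
#'   stratum is returned unchanged).
#' @export
ivw_meta <- function(results) {
  usable <- results[!results$separation & is.finite(results$se), ]
  if (nrow(usable) < nrow(results))
    message(nrow(results) - nrow(usable), " stratum/strata dropped from meta")
  if (nrow(usable) == 0L) stop("no usable strata to meta-analyze")
  if (any(usable$se == 0)) stop("zero standard error in a stratum")
  if (nrow(usable) == 1L) return(usable)
  w <- 1 / usable$se^2
  beta <- sum(w * usable$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  res <- data.frame(
    id = usable$id[1L], phenotype = usable$phenotype[1L], stratum = "meta",
    beta = beta, se = se, or_ = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    n_cases = sum(usable$n_cases), n_controls = sum(usable$n_controls),
    separation = FALSE, converged = TRUE, stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", class(res))
  res
}

#' Collapse qualifying rare variants into a per-individual gene burden
#'
#' Qualifying variants are rare (MAF <= `maf_max`) and either pLOF or
#' missense with REVEL >= `revel_min`; the burden is the per-individual
#' sum of qualifying dosages (additive model; missing genotypes
#' contribute 0).
#'
#' @param genotypes Data frame: individual_id plus one dosage column per
#'   variant.
#' @param variant_annotations Data frame: variant_id, cds_labels
#'   (comma-separated labels), revel, maf.
#' @param revel_min Minimum REVEL score for missense inclusion.
#' @param maf_max Maximum minor allele frequency.
#' @return Named numeric burden vector over individuals, with attribute
#'   `"qualifying"` listing the variant ids used.
#' @export
burden_collapse <- function(genotypes, variant_annotations, revel_min = 0.5,
                            maf_max = 0.001) {
  ann <- variant_annotations
  labels <- strsplit(as.character(ifelse(is.na(ann$cds_labels), "",
                                         ann$cds_labels)), ",")
  plof <- vapply(labels, function(l) "pLOF" %in% l, logical(1))
  mis <- vapply(labels, function(l) "missense" %in% l, logical(1)) &
    !is.na(ann$revel) & ann$revel >= revel_min
  qual <- ann$variant_id[(plof | mis) & !is.na(ann$maf) & ann$maf <= maf_max]
  qual <- intersect(qual, names(genotypes))
  burden <- if (length(qual) == 0L) rep(0, nrow(genotypes)) else
    rowSums(as.matrix(genotypes[qual]), na.rm = TRUE)
  structure(stats::setNames(burden, genotypes$individual_id),
            qualifying = qual)
}

#' PheWAS significance thresholds
#'
#' Bonferroni line `alpha / (n_variants * n_phenotypes)` and the plotted
#' FDR line `fdr_level / n_phenotypes`. A Benjamini-Hochberg step-up over
#' observed p-values is available separately via
#' [stats::p.adjust()]`(p, "BH")` for per-result reporting.
#'
#' @param n_variants,n_phenotypes Test grid dimensions.
#' @param alpha Family-wise error rate for the Bonferroni line.
#' @param fdr_level FDR level for the plotted line.
#' @return List: `bonferroni_p`, `fdr_line_p`.
#' @export
phewas_thresholds <- function(n_variants, n_phenotypes, alpha = 0.05,
                              fdr_level = 0.1) {
  if (n_variants < 1L || n_phenotypes < 1L) stop("counts must be positive")
  list(bonferroni_p = alpha / (n_variants * n_phenotypes),
       fdr_line_p = fdr_level / n_phenotypes)
}

#' Run a PheWAS for one variant or burden
#'
#' Derives case/control status per phenotype, applies eligibility
#' filters, fits the covariate-adjusted logistic model per stratum and
#' combines strata by IVW meta-analysis.
#'
#' @param bb A [biobank_table()].
#' @param dosages Named dosage vector over individuals (a genotype column
#'   or a [burden_collapse()] result).
#' @param phenotype_codes Codes to test (default: all codes in the event
#'   table).
#' @param id Identifier for result rows.
#' @param min_case_dates,min_alt_alleles,max_missing_frac,min_cases
#'   Filter parameters (see [derive_case_control()] and
#'   [eligibility_filters()]).
#' @return Data frame: one meta-analyzed `assoc_result` row per tested
#'   phenotype, with untested phenotypes reported in attribute
#'   `"untested"` (phenotype, reasons).
#' @export
run_phewas <- function(bb, dosages, phenotype_codes = NULL, id = "variant",
                       min_case_dates = 2L, min_alt_alleles = 5L,
                       max_missing_frac = 0.5, min_cases = 20L) {
  ids <- bb$covariates$individual_id
  dosages <- dosages[ids]
  covs <- bb$covariates
  strata <- if ("stratum" %in% names(covs)) unique(covs$stratum) else "all"
  phenotype_codes <- phenotype_codes %||% sort(unique(bb$events$code))
  out <- list()
  untested <- list()
  for (code in phenotype_codes) {
    status <- derive_case_control(bb$events, code, ids,
                                  min_case_dates = min_case_dates)
    el <- eligibility_filters(dosages, status, min_alt_alleles,
                              max_missing_frac, min_cases)
    if (!el$tested) {
      untested[[length(untested) + 1L]] <- data.frame(
        phenotype = code, reasons = paste(el$reasons, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    per_stratum <- lapply(strata, function(s) {
      in_s <- if (identical(s, "all")) rep(TRUE, length(ids)) else
        covs$stratum == s
      logistic_assoc(dosages[in_s], status[ids[in_s]],
                     covariates = covs[in_s, , drop = FALSE], id = id,
                     phenotype = code, stratum = s)
    })
    res <- tryCatch(ivw_meta(do.call(rbind, per_stratum)),
                    error = function(e) NULL)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else NULL
  structure(res, untested = if (length(untested) > 0L)
    do.call(rbind, untested) else NULL)
}
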