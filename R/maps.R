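## Mutability-adjusted proportion of singletons (MAPS).
##
## Rare variants are enriched among deleterious mutations because negative
## selection keeps them from rising in frequency. The raw proportion of
## singletons in a variant class confounds selection with mutability:
## high-mutation-rate contexts (e.g. CpG transitions) recur and so are
## depleted of singletons regardless of selection. MAPS calibrates the
## expectation per trinucleotide mutation context on a neutral class
## (synonymous coding variants) and reports
##
##   MAPS = (observed singletons - expected singletons) / n variants,
##
## so a neutral class scores ~0 and positive scores indicate selection.

#' Fit a MAPS calibration model
#'
#' Aggregates a neutral variant class (typically synonymous coding SNVs)
#' by mutation context and regresses the per-context singleton proportion
#' on the context mutation rate, weighting by per-context variant counts.
#' Fitted proportions are clamped to [0, 1]. With a single represented
#' context (or no rate variation) the fit saturates to the weighted mean
#' proportion.
#'
#' @param neutral_variants Variant table of the calibration class; every
#'   row needs a non-missing `context` covered by `rates` and a
#'   `singleton` flag.
#' @param rates Mutation-rate table ([as_rate_table()]).
#' @param link `"identity"` (weighted least squares on the proportion, the
#'   default) or `"logit"` (weighted quasibinomial fit).
#' @return Object of class `maps_model` with components `coefficients`
#'   (intercept and slope on the mutation rate), `contexts` (per-context
#'   training summary: n, n_singleton, proportion, mu, fitted), `link`,
#'   and `n_train`.
#' @export
maps_fit <- function(neutral_variants, rates, link = c("identity", "logit")) {
  link <- match.arg(link)
  v <- neutral_variants[!is.na(neutral_variants$context) &
                          neutral_variants$context != "unknown", ]
  if (nrow(v) == 0L) stop("no variants with usable context to calibrate on")
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(v)),
                                n_singleton = as.integer(v$singleton)),
                          by = list(context = v$context), FUN = sum)
  agg$proportion <- agg$n_singleton / agg$n
  agg$mu <- rate_for_context(rates, agg$context)
  if (nrow(agg) == 1L || stats::sd(agg$mu) == 0) {
    # saturated: one context (or no rate variation) -> weighted mean
    p <- sum(agg$n_singleton) / sum(agg$n)
    coefs <- c(intercept = p, slope = 0)
    agg$fitted <- rep(p, nrow(agg))
  } else if (link == "identity") {
    fit <- stats::lm(proportion ~ mu, data = agg, weights = agg$n)
    coefs <- c(intercept = unname(stats::coef(fit)[1L]),
               slope = unname(stats::coef(fit)[2L]))
    agg$fitted <- pmin(pmax(unname(stats::fitted(fit)), 0), 1)
  } else {
    fit <- suppressWarnings(stats::glm(proportion ~ mu, data = agg,
                                       weights = agg$n,
                                       family = stats::quasibinomial()))
    coefs <- c(intercept = unname(stats::coef(fit)[1L]),
               slope = unname(stats::coef(fit)[2L]))
    agg$fitted <- unname(stats::fitted(fit))
  }
  structure(list(coefficients = coefs, contexts = agg, link = link,
                 n_train = nrow(v)), class = "maps_model")
}

#' @export
print.maps_model <- function(x, ...) {
  cat(sprintf(paste0("<maps_model> %s link; %d training variant(s) in %d ",
                     "context(s)\n  intercept %.4g, slope %.4g\n"),
              x$link, x$n_train, nrow(x$contexts),
              x$coefficients["intercept"], x$coefficients["slope"]))
  invisible(x)
}

#' @export
coef.maps_model <- function(object, ...) object$coefficients

#' @export
summary.maps_model <- function(object, ...) {
  cat(sprintf("MAPS calibration (%s link), %d variants / %d contexts\n",
              object$link, object$n_train, nrow(object$contexts)))
  print(object$contexts[order(object$contexts$mu), ], row.names = FALSE)
  invisible(object$contexts)
}

#' Expected singleton proportion per variant
#'
#' For contexts seen in training the stored fitted value is used (this
#' preserves the exact weighted-residual identity of the fit); unseen
#' contexts are predicted from the regression coefficients and clamped to
#' [0, 1].
#'
#' @param object A `maps_model`.
#' @param newdata Variant table, or a character vector of context keys.
#' @param rates Rate table, required only for contexts outside the
#'   training set.
#' @param ... Unused.
#' @return Numeric vector of expected singleton proportions.
#' @export
predict.maps_model <- function(object, newdata, rates = NULL, ...) {
  ctx <- if (is.character(newdata)) newdata else newdata$context
  if (anyNA(ctx) || any(ctx == "unknown"))
    stop("variants with unknown context cannot be scored")
  p <- object$contexts$fitted[match(ctx, object$contexts$context)]
  new_ctx <- unique(ctx[is.na(p)])
  if (length(new_ctx) > 0L) {
    if (is.null(rates))
      stop("context(s) not in training set and no rates supplied: ",
           paste(new_ctx, collapse = ", "))
    mu <- rate_for_context(rates, ctx[is.na(p)])
    eta <- object$coefficients["intercept"] + object$coefficients["slope"] * mu
    p[is.na(p)] <- if (object$link == "logit") stats::plogis(eta)
                   else pmin(pmax(eta, 0), 1)
  }
  unname(p)
}

## Per-variant singleton excess over expectation; MAPS is its mean.
maps_contributions <- function(variants, model, rates = NULL) {
  as.numeric(variants$singleton) - predict(model, variants, rates = rates)
}

#' MAPS score of a variant class
#'
#' @param variants Variant table of the class (non-empty, contexts covered
#'   by the model).
#' @param model A [maps_fit()] model.
#' @param label Class label carried into the result.
#' @param n_boot Bootstrap iterations for the confidence interval
#'   (0 skips it).
#' @param percentiles CI percentile pair; the default 5/95 gives the 90%
#'   interval.
#' @param rates Optional rate table for contexts outside the training set.
#' @return Object of class `maps_result`: label, n, observed_singletons,
#'   expected_singletons, maps, ci_low/ci_high, n_boot.
#' @export
maps_score <- function(variants, model, label = "class", n_boot = 0L,
                       percentiles = c(5, 95), rates = NULL) {
  if (nrow(variants) == 0L) stop("no variants in class '", label, "'")
  contrib <- maps_contributions(variants, model, rates = rates)
  n <- length(contrib)
  obs <- sum(variants$singleton)
  expected <- obs - sum(contrib)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) ci <- percentile_ci(boot_means(contrib, n_boot), percentiles)
  structure(list(label = label, n = n, observed_singletons = obs,
                 expected_singletons = expected, maps = mean(contrib),
                 ci_low = ci[1L], ci_high = ci[2L], n_boot = n_boot,
                 percentiles = percentiles),
            class = "maps_result")
}

#' @export
print.maps_result <- function(x, ...) {
  cat(sprintf("<maps_result> %s: MAPS = %.4f (n = %d, obs = %d, exp = %.1f)",
              x$label, x$maps, x$n, x$observed_singletons,
              x$expected_singletons))
  if (!is.na(x$ci_low))
    cat(sprintf("\n  %d%% CI [%.4f, %.4f], %d bootstrap iterations",
                round(diff(x$percentiles)), x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.maps_result <- function(x, ...) {
  data.frame(label = x$label, n = x$n,
             observed_singletons = x$observed_singletons,
             expected_singletons = x$expected_singletons, maps = x$maps,
             ci_low = x$ci_low, ci_high = x$ci_high, n_boot = x$n_boot,
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence interval for a MAPS score
#'
#' Resamples the class with replacement `n_iter` times and takes
#' percentiles of the recomputed scores.
#'
#' @inheritParams maps_score
#' @param n_iter Bootstrap iterations.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_maps <- function(variants, model, n_iter = 10000L,
                           percentiles = c(5, 95), seed = NULL,
                           rates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contrib <- maps_contributions(variants, model, rates = rates)
  percentile_ci(boot_means(contrib, n_iter), percentiles)
}

#' Bootstrap p-value for a difference in MAPS scores
#'
#' Paired bootstrap for the one-sided hypothesis that class `a` has a
#' higher MAPS score than class `b`: both classes are resampled each
#' iteration and p is the (finite-sample corrected) proportion of
#' iterations where the score of `a` fails to exceed that of `b`,
#' `p = (1 + #{score_a <= score_b}) / (n_iter + 1)`.
#'
#' @param class_a,class_b Non-empty variant tables.
#' @param model A `maps_model`.
#' @param n_iter Bootstrap iterations.
#' @param seed Optional RNG seed.
#' @param rates Optional rate table for unseen contexts.
#' @return P-value in (0, 1]; attainable minimum `1/(n_iter + 1)`.
#' @export
maps_pvalue <- function(class_a, class_b, model, n_iter = 10000L,
                        seed = NULL, rates = NULL) {
  if (nrow(class_a) == 0L || nrow(class_b) == 0L)
    stop("both classes must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  sa <- boot_means(maps_contributions(class_a, model, rates = rates), n_iter)
  sb <- boot_means(maps_contributions(class_b, model, rates = rates), n_iter)
  perm_pvalue(sum(sa <= sb), n_iter)
}

#' Sample a context-matched control class
#'
#' Draws from `pool` so that the control's trinucleotide-context histogram
#' equals the target's exactly. Contexts whose pool is smaller than the
#' target count are sampled with replacement (with a warning).
#'
#' @param target_class Variant table whose context histogram to match.
#' @param pool Variant table to sample from; must contain at least one
#'   variant for every context present in the target.
#' @param seed Optional RNG seed.
#' @return Variant table of the same size as `target_class`.
#' @export
match_by_context <- function(target_class, pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(target_class) == 0L) return(target_class)
  tab <- table(target_class$context)
  missing <- setdiff(names(tab), unique(pool$context))
  if (length(missing) > 0L)
    stop("pool has no variants for context(s): ",
         paste(missing, collapse = ", "))
  picks <- integer()
  for (ctx in names(tab)) {
    idx <- which(pool$context == ctx)
    k <- tab[[ctx]]
    if (length(idx) < k)
      warning("context ", ctx, ": pool (", length(idx),
              ") smaller than target (", k, "), sampling with replacement")
    picks <- c(picks, idx[sample.int(length(idx), k,
                                     replace = length(idx) < k)])
  }
  out <- pool[picks, ]
  rownames(out) <- NULL
  out
}
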