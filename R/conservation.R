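## Conserved-base-proportion analysis: the fraction of genomic positions
## with a phyloP-style score above a strong-conservation threshold
## (strictly > 2 by default), with bootstrap CIs and permutation p-values
## against distance-matched control position sets.

#' Proportion of strongly conserved positions
#'
#' @param positions Data frame with chrom and pos (1-based); positions
#'   without a track score are dropped with a reported count.
#' @param track A [conservation_track()].
#' @param threshold Conservation threshold; a position is conserved when
#'   its score is strictly greater than this.
#' @param n_boot Bootstrap iterations for the CI (0 skips it).
#' @param percentiles CI percentile pair (default 5/95, the 90% interval).
#' @param seed Optional RNG seed.
#' @return List of class `conserved_proportion`: proportion, n, n_missing,
#'   ci, threshold.
#' @export
conserved_proportion <- function(positions, track, threshold = 2.0,
                                 n_boot = 10000L, percentiles = c(5, 95),
                                 seed = NULL) {
  if (nrow(positions) == 0L) stop("empty position set")
  if (!is.null(seed)) set.seed(seed)
  scores <- track_lookup(track, positions$chrom, positions$pos)
  n_missing <- sum(is.na(scores))
  if (n_missing > 0L)
    message(n_missing, " position(s) without a conservation score dropped")
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scored positions remain")
  conserved <- as.numeric(scores > threshold)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) ci <- percentile_ci(boot_means(conserved, n_boot),
                                       percentiles)
  structure(list(proportion = mean(conserved), n = length(conserved),
                 n_missing = n_missing, ci = ci, threshold = threshold),
            class = "conserved_proportion")
}

#' @export
print.conserved_proportion <- function(x, ...) {
  cat(sprintf("<conserved_proportion> %.4f of %d position(s) > %.3g",
              x$proportion, x$n, x$threshold))
  if (!is.na(x$ci[1L]))
    cat(sprintf(" (CI [%.4f, %.4f])", x$ci[1L], x$ci[2L]))
  cat("\n")
  invisible(x)
}

#' Sample control positions matched by distance to the CDS
#'
#' For each target position a candidate is drawn from the pool bin with
#' the same 10-bp (by default) distance-to-CDS window, so the control
#' set's bin histogram equals the target's exactly. Bins are
#' [0,10), [10,20), ... Sampling is without replacement unless a bin's
#' pool is smaller than its target count.
#'
#' @param target_positions Data frame with a `distance_to_cds` column.
#' @param candidate_pool Data frame with a `distance_to_cds` column.
#' @param window Bin width in base pairs.
#' @param seed Optional RNG seed.
#' @return Rows of `candidate_pool`, one per target position.
#' @export
match_by_cds_distance <- function(target_positions, candidate_pool,
                                  window = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(target_positions) == 0L) return(target_positions[0L, ])
  tbin <- target_positions$distance_to_cds %/% window
  pbin <- candidate_pool$distance_to_cds %/% window
  tab <- table(tbin)
  empty <- setdiff(names(tab), as.character(unique(pbin)))
  if (length(empty) > 0L)
    stop("no pool candidates in distance bin(s): ",
         paste(sprintf("[%s,%s)", as.integer(empty) * window,
                       (as.integer(empty) + 1L) * window), collapse = ", "))
  picks <- integer()
  for (b in names(tab)) {
    idx <- which(pbin == as.integer(b))
    k <- tab[[b]]
    if (length(idx) < k)
      warning("distance bin ", b, ": pool smaller than target, ",
              "sampling with replacement")
    picks <- c(picks, idx[sample.int(length(idx), k,
                                     replace = length(idx) < k)])
  }
  out <- candidate_pool[picks, ]
  rownames(out) <- NULL
  out
}

#' Permutation p-value for a difference in conserved proportions
#'
#' Resamples both position groups with replacement each iteration and
#' recomputes the conserved proportion; for the one-sided hypothesis
#' "group a is more conserved than group b",
#' `p = (1 + #{prop_a <= prop_b}) / (n_iter + 1)`.
#'
#' @param group_a_positions,group_b_positions Non-empty position data
#'   frames (chrom, pos).
#' @param track A [conservation_track()].
#' @param threshold Conservation threshold (strict).
#' @param n_iter Iterations.
#' @param seed Optional RNG seed.
#' @return P-value in (0, 1].
#' @export
proportion_pvalue <- function(group_a_positions, group_b_positions, track,
                              threshold = 2.0, n_iter = 10000L,
                              seed = NULL) {
  if (nrow(group_a_positions) == 0L || nrow(group_b_positions) == 0L)
    stop("both position groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  ca <- track_lookup(track, group_a_positions$chrom, group_a_positions$pos)
  cb <- track_lookup(track, group_b_positions$chrom, group_b_positions$pos)
  ca <- as.numeric(ca[!is.na(ca)] > threshold)
  cb <- as.numeric(cb[!is.na(cb)] > threshold)
  if (length(ca) == 0L || length(cb) == 0L)
    stop("a group has no scored positions")
  pa <- boot_means(ca, n_iter)
  pb <- boot_means(cb, n_iter)
  perm_pvalue(sum(pa <= pb), n_iter)
}
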