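## Stop-codon usage of translated uORFs versus the background distribution
## of stop-matching trinucleotides in 5'UTR sequence. uORFs preferentially
## terminate at readthrough-prone stops (UGA/UAG) and are depleted of the
## strong UAA stop relative to what their host UTR sequence offers.

#' Stop-codon usage of a set of translated ORFs
#'
#' Extracts the terminal codon of each ORF (already in reading frame) and
#' reports proportions over UGA/UAG/UAA with a bootstrap CI from
#' resampling ORFs with replacement.
#'
#' @param orfs Non-empty list of [orf_annotation()].
#' @param n_boot Bootstrap iterations (0 skips the CI and draws).
#' @param percentiles CI percentile pair; default 2.5/97.5 (95% interval).
#' @param seed Optional RNG seed.
#' @return List: `proportions` (named over UGA/UAG/UAA, sums to 1), `n`,
#'   `ci` (3 x 2 matrix), `draws` (`n_boot` x 3 matrix of resampled
#'   proportion triplets, for paired permutation tests).
#' @export
uorf_stop_frequencies <- function(orfs, n_boot = 10000L,
                                  percentiles = c(2.5, 97.5), seed = NULL) {
  if (length(orfs) == 0L) stop("no ORFs supplied")
  if (!is.null(seed)) set.seed(seed)
  stops <- vapply(orfs, function(o) {
    s <- o$spliced_sequence
    substr(s, nchar(s) - 2L, nchar(s))
  }, character(1))
  lev <- c("UGA", "UAG", "UAA")
  props <- prop.table(table(factor(stops, levels = lev)))
  draws <- NULL
  ci <- NULL
  if (n_boot > 0L) {
    idx <- matrix(sample.int(length(stops), length(stops) * n_boot,
                             replace = TRUE), ncol = n_boot)
    draws <- t(apply(idx, 2L, function(j)
      prop.table(table(factor(stops[j], levels = lev)))))
    colnames(draws) <- lev
    ci <- t(apply(draws, 2L, percentile_ci, percentiles = percentiles))
  }
  list(proportions = as.numeric(props), codons = lev, n = length(stops),
       ci = ci, draws = draws)
}

## All stop-matching trinucleotide occurrences of one UTR, in transcript
## orientation, overlapping occurrences counted at every offset. Returns a
## data frame with seq_index and codon; genomic footprint via utr positions.
utr_stop_occurrences <- function(utr, mask_orfs = NULL) {
  seq <- utr$sequence
  n <- nchar(seq)
  if (n < 3L) return(data.frame(seq_index = integer(), codon = character()))
  masked <- rep(FALSE, n)
  if (!is.null(mask_orfs) && length(mask_orfs) > 0L) {
    upos <- orf_positions(utr)
    for (o in mask_orfs) {
      if (o$chrom != utr$chrom) next
      masked <- masked | upos %in% orf_positions(o)
    }
  }
  starts <- seq_len(n - 2L)
  tri <- substring(seq, starts, starts + 2L)
  hit <- tri %in% RNA_STOPS &
    !(masked[starts] | masked[starts + 1L] | masked[starts + 2L])
  data.frame(seq_index = starts[hit], codon = tri[hit],
             stringsAsFactors = FALSE)
}

#' Background stop-trinucleotide sampling distribution over 5'UTRs
#'
#' Per iteration, one stop-matching trinucleotide (UGA/UAG/UAA, scanned in
#' transcript orientation, overlapping occurrences counted at every
#' offset) is drawn uniformly from each UTR's occurrences, and the
#' proportions of the three codons among the draws recorded. UTRs with no
#' eligible occurrence contribute nothing. With `exclude_orf_overlap`,
#' trinucleotides overlapping translated-uORF intervals are masked before
#' scanning.
#'
#' @param utrs List of [utr_annotation()].
#' @param n_iter Iterations.
#' @param exclude_orf_overlap Mask bases inside `orfs` before scanning.
#' @param orfs Translated ORFs used for masking (required when
#'   `exclude_orf_overlap` is TRUE).
#' @param seed Optional RNG seed.
#' @return `n_iter` x 3 matrix of proportion triplets (columns UGA, UAG,
#'   UAA; each row sums to 1).
#' @export
background_stop_distribution <- function(utrs, n_iter = 10000L,
                                         exclude_orf_overlap = FALSE,
                                         orfs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (exclude_orf_overlap && is.null(orfs))
    stop("exclude_orf_overlap requires the list of translated ORFs")
  lev <- c("UGA", "UAG", "UAA")
  occ <- lapply(utrs, function(u) {
    mask <- if (exclude_orf_overlap)
      Filter(function(o) o$orf_id %in% u$contained_orf_ids, orfs) else NULL
    utr_stop_occurrences(u, mask_orfs = mask)$codon
  })
  occ <- occ[lengths(occ) > 0L]
  if (length(occ) == 0L) stop("no UTR contains an eligible stop trinucleotide")
  # one draw per UTR per iteration; codons coded 1..3
  draws <- vapply(occ, function(codons) {
    code <- match(codons, lev)
    code[sample.int(length(code), n_iter, replace = TRUE)]
  }, integer(n_iter))
  if (n_iter == 1L) draws <- matrix(draws, nrow = 1L)
  out <- cbind(rowMeans(draws == 1L), rowMeans(draws == 2L),
               rowMeans(draws == 3L))
  colnames(out) <- lev
  out
}

#' Permutation p-value for stop-codon usage differences
#'
#' Compares paired iteration streams of uORF stop-usage bootstrap draws
#' and background draws for one codon. For `direction = "depletion"` the
#' unfavorable iterations are those where the uORF frequency is >= the
#' background frequency; `"enrichment"` is the reverse. The finite-sample
#' corrected p is `(1 + #unfavorable) / (n_iter + 1)`.
#'
#' @param orf_draws Matrix of uORF bootstrap proportion triplets
#'   (`$draws` of [uorf_stop_frequencies()]).
#' @param background_draws Matrix from [background_stop_distribution()]
#'   with the same number of rows.
#' @param codon `"UGA"`, `"UAG"` or `"UAA"`.
#' @param direction `"depletion"` or `"enrichment"` (of the codon in
#'   uORFs relative to background).
#' @return P-value in (0, 1].
#' @export
usage_pvalue <- function(orf_draws, background_draws, codon,
                         direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  if (!codon %in% c("UGA", "UAG", "UAA")) stop("invalid codon: ", codon)
  if (nrow(orf_draws) != nrow(background_draws))
    stop("draw streams must be paired (equal iteration counts)")
  a <- orf_draws[, codon]
  b <- background_draws[, codon]
  unfavorable <- if (direction == "depletion") sum(a >= b) else sum(a <= b)
  perm_pvalue(unfavorable, nrow(orf_draws))
}
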