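## Per-base conservation tracks (phyloP-style), codon stability coefficient
## tables, and trinucleotide mutation-rate tables.

#' Build a conservation track
#'
#' A sparse per-base score map. Lookups at positions absent from the track
#' return `NA`, never 0 — missing conservation data is explicit.
#'
#' @param chrom,pos,score Parallel vectors: chromosome, 1-based position,
#'   phyloP-like score.
#' @return Object of class `conservation_track`.
#' @export
conservation_track <- function(chrom, pos, score) {
  keys <- paste0(chrom, ":", pos)
  if (anyDuplicated(keys)) stop("duplicate positions in track")
  structure(list(scores = stats::setNames(as.numeric(score), keys)),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("<conservation_track> %d scored base(s), range [%.3g, %.3g]\n",
              length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Look up conservation scores
#'
#' @param track A `conservation_track`.
#' @param chrom,pos Parallel chromosome / 1-based position vectors.
#' @return Numeric scores, `NA` where the track has no value.
#' @export
track_lookup <- function(track, chrom, pos) {
  unname(track$scores[paste0(chrom, ":", pos)])
}

#' Read a bedGraph file into a conservation track
#'
#' Intervals (0-based half-open) are expanded to per-base scores.
#'
#' @param path bedGraph file.
#' @return A [conservation_track()].
#' @export
read_bedgraph <- function(path) {
  g <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
  pos <- unlist(mapply(seq.int, g$start, g$end, SIMPLIFY = FALSE),
                use.names = FALSE)
  n <- g$end - g$start + 1L
  conservation_track(rep(as.character(g$seqnames), n), pos,
                     rep(g$score, n))
}

#' Write a conservation track as bedGraph
#'
#' One line per base, 0-based half-open, sorted by (chrom, pos) so output
#' is deterministic.
#'
#' @param track A `conservation_track`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  keys <- names(track$scores)
  chrom <- sub(":.*$", "", keys)
  pos <- as.integer(sub("^.*:", "", keys))
  o <- order(chrom, pos)
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom[o], pos[o] - 1L, pos[o],
                     formatC(track$scores[o], format = "g", digits = 8)),
             path)
  invisible(path)
}

#' Read a codon stability coefficient (CSC) table
#'
#' TSV with columns `codon` (RNA triplets) and `csc`. All 61 sense codons
#' must be present and stop codons must be absent.
#'
#' @param path TSV file.
#' @return Named numeric vector of CSC scores keyed by codon.
#' @export
read_csc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "csc") %in% names(df)))
  as_csc_table(stats::setNames(df$csc, toupper(df$codon)))
}

#' Validate a CSC table
#'
#' @param x Named numeric vector keyed by RNA sense codon.
#' @return The validated table.
#' @export
as_csc_table <- function(x) {
  if (any(names(x) %in% RNA_STOPS))
    stop("CSC table must not contain stop codons: ",
         paste(intersect(names(x), RNA_STOPS), collapse = ", "))
  missing <- setdiff(sense_codons(), names(x))
  if (length(missing) > 0L)
    stop("CSC table missing sense codon(s): ", paste(missing, collapse = ", "))
  x[sense_codons()]
}

#' Write a CSC table
#' @param csc Named numeric vector keyed by codon.
#' @param path Output TSV.
#' @export
write_csc_table <- function(csc, path) {
  utils::write.table(data.frame(codon = names(csc), csc = unname(csc)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trinucleotide mutation-rate table
#'
#' TSV with columns `context` (collapsed reference triplet, central base A
#' or C), `alt`, optional `methyl_level`, and `mu` (> 0). Internally keyed
#' by the same `"ACG:C>T"` context strings as variant tables.
#'
#' @param path TSV file.
#' @return Data frame with columns key, context, alt, methyl_level, mu.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("context", "alt", "mu") %in% names(df)))
  if (is.null(df$methyl_level)) df$methyl_level <- 0L
  as_rate_table(df)
}

#' Validate a mutation-rate table
#' @param df Data frame with columns context (triplet), alt, mu, optional
#'   methyl_level.
#' @return Keyed rate table.
#' @export
as_rate_table <- function(df) {
  if (any(df$mu <= 0)) stop("mutation rates must be positive")
  central <- substr(df$context, 2L, 2L)
  if (!all(central %in% c("A", "C")))
    stop("rate-table contexts must be collapsed (central base A or C)")
  df$key <- paste0(df$context, ":", central, ">", df$alt)
  if (is.null(df$methyl_level)) df$methyl_level <- 0L
  if (anyDuplicated(paste(df$key, df$methyl_level))) stop("duplicate rate rows")
  df[c("key", "context", "alt", "methyl_level", "mu")]
}

#' Write a mutation-rate table
#' @param rates Keyed rate table.
#' @param path Output TSV.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates[c("context", "alt", "methyl_level", "mu")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## mu for each variant context key; error listing any context without a rate.
rate_for_context <- function(rates, context_keys) {
  mu <- rates$mu[match(context_keys, rates$key)]
  if (anyNA(mu)) {
    missing <- unique(context_keys[is.na(mu)])
    stop("no mutation rate for context(s): ", paste(missing, collapse = ", "))
  }
  mu
}
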