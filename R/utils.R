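#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bootstrap means of a numeric vector, chunked so memory stays bounded.
## Returns a length-n_iter vector of resampled means.
boot_means <- function(x, n_iter, chunk = 2e7L) {
  n <- length(x)
  if (n == 0L) stop("cannot bootstrap an empty vector")
  per <- max(1L, as.integer(chunk %/% n))
  out <- numeric(n_iter)
  done <- 0L
  while (done < n_iter) {
    k <- min(per, n_iter - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    out[(done + 1L):(done + k)] <- colMeans(matrix(x[idx], nrow = n, ncol = k))
    done <- done + k
  }
  out
}

## Finite-sample permutation/bootstrap p-value: never 0, floor 1/(n_iter+1).
perm_pvalue <- function(n_unfavorable, n_iter) {
  (1 + n_unfavorable) / (n_iter + 1)
}

## Percentile pair, e.g. c(5, 95), to a two-sided quantile interval.
percentile_ci <- function(draws, percentiles = c(5, 95)) {
  stats::quantile(draws, probs = percentiles / 100, names = FALSE, type = 7)
}

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a non-missing scalar")
  invisible(x)
}
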