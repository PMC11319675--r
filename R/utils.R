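# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

## Deterministic per-trait seed derived from a global seed and a trait label.
## Kept below 2^31 so it is always a valid R integer seed; arithmetic in
## doubles (exact up to 2^53) so no integer overflow.
derive_seed <- function(global_seed, label) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- global_seed %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## Open a path as a text connection, transparently handling gzip by extension.
open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labellings of the same items, corrected for
#' chance; 1 means identical partitions, 0 is the expectation under random
#' labelling. Used to score recovery of planted BGC group structure.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single numeric value (ARI).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must have equal length")
  if (length(a) == 0L) return(NaN)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
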