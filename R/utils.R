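#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dnbinom median na.omit p.adjust pnorm pt quantile
#'   rnbinom rnorm rpois runif sd setNames var phyper
#' @importFrom utils combn head read.delim tail write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead (98.585 -> 98.59).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

log2p1 <- function(x) log2(x + 1)

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Shared engine of the over-representation test and the ceRNA sponge test.
#' `X ~ Hypergeometric(N, K, n)`: `n` draws without replacement from a
#' population of size `N` containing `K` successes.
#'
#' @param k observed overlap (successes drawn).
#' @param K successes in the population.
#' @param n number of draws.
#' @param N population size.
#' @return `P(X >= k)`, a probability in (0, 1].
#' @examples
#' hypergeom_tail(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == length(K) || length(K) == 1L)
  if (any(K > N) || any(n > N) || any(k < 0) || any(K < 0) || any(n < 0)) {
    stop("invalid hypergeometric parameters: need 0 <= k, K <= N, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# write a data.frame as plain TSV (no quoting, no row names)
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Read a count or expression matrix from TSV
#'
#' First column holds transcript ids, remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return numeric matrix with transcript-id rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV with a transcript_id leading column
#'
#' @param m matrix with rownames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# deterministic seed stream offsets for the generator sub-stages
.seed_offsets <- c(counts = 101L, sequences = 202L, qpcr = 303L)
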