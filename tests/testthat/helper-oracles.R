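# Independent oracles and fixture builders shared across the suite.

# Exhaustive-enumeration oracle for P(X >= k), X ~ Hypergeometric(N, K, n):
# enumerate every one of the C(N, n) draws from a population whose first K
# elements are the successes and count overlaps directly.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Brute-force unweighted Kolmogorov-Smirnov running-sum oracle: walk the
# ranked list, +1/Nh on hits, -1/Nm on misses, return the signed maximum
# deviation (ties broken toward the positive side, as in the engine).
ks_es_oracle <- function(hit, n) {
  nh <- sum(hit)
  nm <- n - nh
  running <- cumsum(ifelse(hit, 1 / nh, -1 / nm))
  i <- which.max(abs(running))
  mx <- max(running)
  mn <- min(running)
  if (mx >= -mn) mx else mn
}

# Closed-form Spearman on tie-free data: 1 - 6 sum(d^2) / (n (n^2 - 1))
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# one-transcript-per-row exon table builder: each element of `txs` is
# list(id, gene, chrom, strand, exons = matrix/list of c(start, end))
make_exons <- function(txs, biotype = NA_character_) {
  rows <- lapply(txs, function(t) {
    ex <- do.call(rbind, t$exons)
    data.frame(transcript_id = t$id, gene_id = t$gene %||% t$id,
               chrom = t$chrom %||% "chr1", start = ex[, 1], end = ex[, 2],
               strand = t$strand %||% "+",
               biotype = t$biotype %||% biotype,
               stringsAsFactors = FALSE)
  })
  transcript_set(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard three-exon coding gene used by classification fixtures
fixture_gene <- function(gene = "gA", chrom = "chr1", a = 100000,
                         strand = "+") {
  make_exons(list(list(
    id = paste0(gene, "_t1"), gene = gene, chrom = chrom, strand = strand,
    exons = list(c(a, a + 999), c(a + 20000, a + 20999),
                 c(a + 40000, a + 40999)))), biotype = "coding")
}

# small deterministic FPKM-like matrix
fixture_expr <- function(values, samples) {
  m <- matrix(values, ncol = length(samples), byrow = TRUE)
  colnames(m) <- samples
  rownames(m) <- sprintf("t%02d", seq_len(nrow(m)))
  m
}

fixture_design <- function(stages = c("IV", "V"), reps = 3) {
  data.frame(sample_id = paste0(rep(stages, each = reps), "_",
                                seq_len(reps)),
             stage = rep(stages, each = reps),
             replicate = rep(seq_len(reps), length(stages)),
             stringsAsFactors = FALSE)
}
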