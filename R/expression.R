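# FPKM normalization, the stand-in differential test, BH adjustment and the
# fold-change / FDR gates.

#' FPKM normalization
#'
#' `FPKM_ts = 1e9 * C_ts / (N_s * L_t)` with `N_s` the per-sample library
#' size (column sum) and `L_t` the spliced transcript length in bp.
#'
#' @param counts nonnegative integer matrix, transcripts x samples.
#' @param lengths named vector of transcript lengths (bp); names must cover
#'   rownames of `counts`.
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  L <- lengths[rownames(counts)]
  if (anyNA(L)) {
    stop("missing lengths for: ",
         paste(head(rownames(counts)[is.na(L)], 5), collapse = ", "))
  }
  if (any(L <= 0)) stop("transcript lengths must be positive")
  N <- colSums(counts)
  if (any(N == 0)) {
    stop("library size is zero for sample ",
         paste(colnames(counts)[N == 0], collapse = ", "))
  }
  1e9 * sweep(counts / L, 2, N, "/")
}

rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Stand-in differential expression test (Welch on log2 FPKM)
#'
#' A transparent replacement for a count-model test: per transcript,
#' `log2fc = log2((mean_B + eps) / (mean_A + eps))` on FPKM, and a Welch
#' two-sample t comparison of `log2(FPKM + 1)`. Transcripts with zero
#' variance in both groups get p = 1 when the group means are equal and
#' p = 0 otherwise. The interface is deliberately narrow so a different
#' test can be slotted in.
#'
#' @param fpkm FPKM matrix, transcripts x samples.
#' @param design data.frame with `sample_id` and `stage` columns.
#' @param stage_a,stage_b stage labels; fold change is B over A.
#' @param eps pseudo-FPKM added to the means before the ratio (default 0.01).
#' @return data.frame: `transcript_id`, `comparison`, `log2fc`, `pvalue`.
#' @export
de_test <- function(fpkm, design, stage_a, stage_b, eps = 0.01) {
  for (st in c(stage_a, stage_b)) {
    if (!st %in% design$stage) stop("unknown stage label: ", st)
  }
  sa <- design$sample_id[design$stage == stage_a]
  sb <- design$sample_id[design$stage == stage_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("need >= 2 replicates per stage")
  }
  xa <- fpkm[, sa, drop = FALSE]
  xb <- fpkm[, sb, drop = FALSE]
  log2fc <- log2((rowMeans(xb) + eps) / (rowMeans(xa) + eps))
  la <- log2p1(xa); lb <- log2p1(xb)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowVars(la); vb <- rowVars(lb)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  data.frame(transcript_id = rownames(fpkm),
             comparison = paste0(stage_a, "_vs_", stage_b),
             log2fc = unname(log2fc), pvalue = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1, mapped back to the
#' input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return FDR-adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Apply the fold-change / significance gates
#'
#' `up` iff `log2fc >= log2(fc_min)` and the gate passes; `down` iff
#' `log2fc <= -log2(fc_min)` and the gate passes; otherwise `ns`. The gate
#' is `fdr < fdr_max` (strict), or `pvalue < p_max` when `use_pvalue = TRUE`
#' (the miRNA-style gate). The fold-change bound is inclusive.
#'
#' @param records data.frame with `log2fc` and `fdr` (and `pvalue` when
#'   `use_pvalue`).
#' @param fc_min minimum fold change (default 2).
#' @param fdr_max FDR gate (default 0.05, strict).
#' @param use_pvalue gate on raw p instead of FDR.
#' @param p_max p gate used when `use_pvalue` (default 0.05, strict).
#' @return `records` with a `status` column in `{up, down, ns}`.
#' @export
classify_de <- function(records, fc_min = 2, fdr_max = 0.05,
                        use_pvalue = FALSE, p_max = 0.05) {
  lfc_min <- log2(fc_min)
  gate <- if (use_pvalue) records$pvalue < p_max else records$fdr < fdr_max
  status <- rep("ns", nrow(records))
  status[gate & records$log2fc >= lfc_min] <- "up"
  status[gate & records$log2fc <= -lfc_min] <- "down"
  records$status <- status
  records
}

#' Full differential-expression pass for one comparison
#'
#' Runs [de_test()], adds BH FDR and the status gates.
#'
#' @inheritParams de_test
#' @inheritParams classify_de
#' @return DE record data.frame with `fdr` and `status`.
#' @export
run_de <- function(fpkm, design, stage_a, stage_b, eps = 0.01, fc_min = 2,
                   fdr_max = 0.05, use_pvalue = FALSE, p_max = 0.05) {
  rec <- de_test(fpkm, design, stage_a, stage_b, eps)
  rec$fdr <- bh_adjust(rec$pvalue)
  classify_de(rec, fc_min = fc_min, fdr_max = fdr_max,
              use_pvalue = use_pvalue, p_max = p_max)
}
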