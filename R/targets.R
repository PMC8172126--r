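# lncRNA target prediction by the three mechanisms: antisense (positional),
# cis (neighborhood distance), trans (expression correlation).

#' Antisense lncRNA-gene pairs
#'
#' A pair is emitted iff a lncRNA exon overlaps a coding-gene exon by at
#' least 1 bp on the opposite strand. Evidence is the total overlapping bp.
#'
#' @param lnc_exons exon table of lncRNAs.
#' @param gene_exons exon table of coding genes.
#' @return data.frame: `lncrna_id`, `gene_id`, `mechanism` ("antisense"),
#'   `evidence` (overlap bp).
#' @export
antisense_pairs <- function(lnc_exons, gene_exons) {
  le <- exons_granges(lnc_exons)
  ge <- exons_granges(gene_exons)
  ov <- GenomicRanges::findOverlaps(le, ge, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  opp <- as.character(GenomicRanges::strand(le))[qh] !=
    as.character(GenomicRanges::strand(ge))[sh]
  if (!any(opp)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      mechanism = character(0), evidence = numeric(0)))
  }
  qh <- qh[opp]; sh <- sh[opp]
  bp <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(le)[qh], GenomicRanges::ranges(ge)[sh]))
  df <- data.frame(
    lncrna_id = S4Vectors::mcols(le)$transcript_id[qh],
    gene_id = S4Vectors::mcols(ge)$gene_id[sh],
    bp = bp, stringsAsFactors = FALSE)
  agg <- stats::aggregate(bp ~ lncrna_id + gene_id, df, sum)
  out <- data.frame(lncrna_id = agg$lncrna_id, gene_id = agg$gene_id,
                    mechanism = "antisense", evidence = agg$bp,
                    stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Cis lncRNA-gene pairs (neighborhood rule)
#'
#' A pair is emitted iff the gene body does not overlap the lncRNA and the
#' two lie on the same chromosome with fewer than `window_bp` intervening
#' bases (strict; either strand). Evidence is the distance in bp
#' (intervening bases; adjacent features have distance 0).
#'
#' @param lnc_exons exon table of lncRNAs.
#' @param gene_exons exon table of coding genes.
#' @param window_bp neighborhood window (default 100000, strict upper bound).
#' @return data.frame: `lncrna_id`, `gene_id`, `mechanism` ("cis"),
#'   `evidence` (distance bp).
#' @export
cis_pairs <- function(lnc_exons, gene_exons, window_bp = 100000) {
  lsum <- summarize_transcripts(lnc_exons)
  gsum <- summarize_transcripts(gene_exons)
  gsp <- split(seq_len(nrow(gsum)), gsum$gene_id)
  genes <- do.call(rbind, lapply(gsp, function(idx) {
    data.frame(gene_id = gsum$gene_id[idx[1]], chrom = gsum$chrom[idx[1]],
               start = min(gsum$tx_start[idx]), end = max(gsum$tx_end[idx]),
               stringsAsFactors = FALSE)
  }))
  lgr <- GenomicRanges::GRanges(lsum$chrom,
                                IRanges::IRanges(lsum$tx_start, lsum$tx_end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  # suppress the benign "no sequence levels in common" warning when the
  # two inputs live on disjoint chromosomes
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lgr, ggr, maxgap = window_bp,
                                ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- suppressWarnings(
    GenomicRanges::distance(lgr[qh], ggr[sh], ignore.strand = TRUE))
  # distance() is 0 both for overlap and adjacency; drop true overlaps
  ovl <- suppressWarnings(
    GenomicRanges::findOverlaps(lgr, ggr, ignore.strand = TRUE))
  ovl_key <- paste(S4Vectors::queryHits(ovl), S4Vectors::subjectHits(ovl))
  keep <- !(paste(qh, sh) %in% ovl_key) & !is.na(d) & d < window_bp
  if (!any(keep)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      mechanism = character(0), evidence = numeric(0)))
  }
  out <- data.frame(lncrna_id = lsum$transcript_id[qh[keep]],
                    gene_id = genes$gene_id[sh[keep]],
                    mechanism = "cis", evidence = d[keep],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Trans lncRNA-gene pairs (expression correlation)
#'
#' Pearson correlation of `log2(FPKM + 1)` (or raw FPKM) across all matched
#' samples; a pair is kept iff `|r| >= r_min`. Zero-variance series are
#' skipped with a message.
#'
#' @param lnc_fpkm,mrna_fpkm FPKM matrices with identical sample columns.
#' @param r_min absolute-correlation threshold (default 0.9, inclusive).
#' @param log_transform correlate on `log2(FPKM + 1)` (default TRUE).
#' @return data.frame: `lncrna_id`, `gene_id`, `mechanism` ("trans"),
#'   `evidence` (r), `sign` ("positive"/"negative").
#' @export
trans_pairs <- function(lnc_fpkm, mrna_fpkm, r_min = 0.9,
                        log_transform = TRUE) {
  stopifnot(identical(colnames(lnc_fpkm), colnames(mrna_fpkm)))
  if (ncol(lnc_fpkm) < 3) stop("need >= 3 samples for trans correlation")
  xl <- if (log_transform) log2p1(lnc_fpkm) else lnc_fpkm
  xm <- if (log_transform) log2p1(mrna_fpkm) else mrna_fpkm
  vl <- rowVars(xl); vm <- rowVars(xm)
  if (any(vl == 0) || any(vm == 0)) {
    message("skipping zero-variance series: ",
            paste(c(rownames(xl)[vl == 0], rownames(xm)[vm == 0]),
                  collapse = ", "))
    xl <- xl[vl > 0, , drop = FALSE]
    xm <- xm[vm > 0, , drop = FALSE]
  }
  if (!nrow(xl) || !nrow(xm)) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      mechanism = character(0), evidence = numeric(0),
                      sign = character(0)))
  }
  r <- cor(t(xl), t(xm))
  hit <- which(abs(r) >= r_min, arr.ind = TRUE)
  out <- data.frame(
    lncrna_id = rownames(xl)[hit[, 1]],
    gene_id = rownames(xm)[hit[, 2]],
    mechanism = "trans",
    evidence = r[hit],
    sign = ifelse(r[hit] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}
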