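# Novel-transcript filtering, consensus lncRNA calling and positional
# classification of lncRNAs relative to protein-coding genes.

#' Filter novel transcripts by length and exon number
#'
#' Retains transcripts with total exonic length >= `min_length` and exon
#' count >= `min_exons`. The defaults implement the length-200 / two-exon
#' rule; `min_exons = 3` gives the stricter "more than 2 exons" variant.
#'
#' @param exons transcript exon table.
#' @param min_length minimum spliced length in bp (default 200).
#' @param min_exons minimum exon count (default 2).
#' @return exon table restricted to retained transcripts.
#' @export
filter_novel_transcripts <- function(exons, min_length = 200, min_exons = 2) {
  s <- summarize_transcripts(exons)
  keep <- s$transcript_id[s$length >= min_length & s$n_exons >= min_exons]
  exons[exons$transcript_id %in% keep, , drop = FALSE]
}

#' Consensus lncRNA call from coding-potential verdicts
#'
#' A candidate is a lncRNA iff both coding-potential tools call it
#' non-coding and it has no protein-database hit (the intersection rule).
#'
#' @param calls data.frame with columns `transcript_id`, `cnci_noncoding`,
#'   `cpc_noncoding`, `swissprot_hit` (logicals).
#' @return character vector of lncRNA transcript ids.
#' @export
consensus_lncrna_call <- function(calls) {
  if (!nrow(calls)) return(character(0))
  if (anyDuplicated(calls$transcript_id)) {
    stop("duplicate transcript_id in coding-potential calls: ",
         paste(unique(calls$transcript_id[duplicated(calls$transcript_id)]),
               collapse = ", "))
  }
  keep <- calls$cnci_noncoding & calls$cpc_noncoding & !calls$swissprot_hit
  calls$transcript_id[keep]
}

#' Classify lncRNAs into positional categories
#'
#' Assigns each lncRNA exactly one of `intergenic`, `bidirectional`,
#' `intronic`, `antisense`, `sense_overlapping` or `other` by its geometry
#' relative to protein-coding genes. Rules are tested in a fixed precedence
#' (first match wins):
#'
#' 1. **intronic** — the whole lncRNA lies inside one intron of a coding
#'    gene, either strand;
#' 2. **antisense** — >= 1 bp exonic overlap with a coding gene on the
#'    opposite strand;
#' 3. **sense_overlapping** — >= 1 bp exonic overlap on the same strand,
#'    with the lncRNA not fully contained in the gene's exons;
#' 4. **bidirectional** — no gene-body overlap, transcription start sites
#'    within `bidirectional_window_bp` on opposite strands in divergent
#'    (head-to-head) orientation;
#' 5. **intergenic** — no gene-body overlap and not bidirectional;
#' 6. **other** — anything left (e.g. same-strand intron-only overlap).
#'
#' @param lnc_exons exon table of lncRNA transcripts.
#' @param gene_exons exon table of protein-coding transcripts.
#' @param bidirectional_window_bp divergent-promoter window (default 1000).
#' @return data.frame: `transcript_id`, `positional_class`,
#'   `partner_gene_id`, `partner_distance_bp` (NA for intergenic/other;
#'   0 for overlap classes; TSS distance for bidirectional).
#' @export
classify_lncrnas <- function(lnc_exons, gene_exons,
                             bidirectional_window_bp = 1000) {
  lnc_sum <- summarize_transcripts(lnc_exons)
  gene_sum <- summarize_transcripts(gene_exons)
  # collapse coding transcripts to genes: body span and TSS per gene
  gsp <- split(seq_len(nrow(gene_sum)), gene_sum$gene_id)
  genes <- do.call(rbind, lapply(gsp, function(idx) {
    data.frame(gene_id = gene_sum$gene_id[idx[1]],
               chrom = gene_sum$chrom[idx[1]],
               strand = gene_sum$strand[idx[1]],
               start = min(gene_sum$tx_start[idx]),
               end = max(gene_sum$tx_end[idx]),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  gene_body <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(genes$start, genes$end),
                                      strand = genes$strand,
                                      gene_id = genes$gene_id)
  gene_ex <- exons_granges(gene_exons)
  gene_intr <- introns_granges(gene_exons)
  lnc_span <- spans_granges(lnc_sum)
  lnc_ex <- exons_granges(lnc_exons)
  lnc_ids <- lnc_sum$transcript_id

  # exonic overlaps lnc-exon x gene-exon, strand ignored then split by strand
  ov <- GenomicRanges::findOverlaps(lnc_ex, gene_ex, ignore.strand = TRUE)
  ov_df <- data.frame(
    lnc = S4Vectors::mcols(lnc_ex)$transcript_id[S4Vectors::queryHits(ov)],
    gene = S4Vectors::mcols(gene_ex)$gene_id[S4Vectors::subjectHits(ov)],
    same = as.character(GenomicRanges::strand(lnc_ex))[S4Vectors::queryHits(ov)] ==
      as.character(GenomicRanges::strand(gene_ex))[S4Vectors::subjectHits(ov)],
    bp = GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(lnc_ex)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(gene_ex)[S4Vectors::subjectHits(ov)])),
    stringsAsFactors = FALSE
  )

  # containment within one intron (any strand)
  ov_in <- GenomicRanges::findOverlaps(lnc_span, gene_intr, type = "within",
                                       ignore.strand = TRUE)
  intronic_of <- split(
    S4Vectors::mcols(gene_intr)$gene_id[S4Vectors::subjectHits(ov_in)],
    lnc_ids[S4Vectors::queryHits(ov_in)])

  # gene-body overlap (any strand)
  ov_body <- GenomicRanges::findOverlaps(lnc_span, gene_body,
                                         ignore.strand = TRUE)
  body_of <- split(genes$gene_id[S4Vectors::subjectHits(ov_body)],
                   lnc_ids[S4Vectors::queryHits(ov_body)])

  # exon containment: lnc fully inside the union of a gene's exons
  contained_in_gene_exons <- function(lid, gid) {
    le <- lnc_ex[S4Vectors::mcols(lnc_ex)$transcript_id == lid]
    ge <- gene_ex[S4Vectors::mcols(gene_ex)$gene_id == gid]
    cov <- GenomicRanges::reduce(ge, ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(le, cov, type = "within",
                                        ignore.strand = TRUE)
    length(unique(S4Vectors::queryHits(hits))) == length(le)
  }

  classify_one <- function(i) {
    lid <- lnc_sum$transcript_id[i]
    lstrand <- lnc_sum$strand[i]
    ltss <- lnc_sum$tss[i]
    # (1) intronic
    hosts <- intronic_of[[lid]]
    if (!is.null(hosts) && length(hosts)) {
      return(list(class = "intronic", partner = sort(hosts)[1], dist = 0))
    }
    eo <- ov_df[ov_df$lnc == lid, , drop = FALSE]
    # (2) antisense: exonic overlap opposite strand; partner = max overlap bp
    as_ov <- eo[!eo$same, , drop = FALSE]
    if (nrow(as_ov)) {
      agg <- tapply(as_ov$bp, as_ov$gene, sum)
      best <- sort(names(agg)[agg == max(agg)])[1]
      return(list(class = "antisense", partner = best, dist = 0))
    }
    # (3) sense_overlapping: same strand, not contained in the gene's exons
    so_ov <- eo[eo$same, , drop = FALSE]
    if (nrow(so_ov)) {
      agg <- sort(tapply(so_ov$bp, so_ov$gene, sum), decreasing = TRUE)
      for (gid in names(agg)[order(-agg, names(agg))]) {
        if (!contained_in_gene_exons(lid, gid)) {
          return(list(class = "sense_overlapping", partner = gid, dist = 0))
        }
      }
      return(list(class = "other", partner = NA_character_, dist = NA_real_))
    }
    overlapped <- body_of[[lid]]
    if (is.null(overlapped) || !length(overlapped)) {
      # (4) bidirectional: divergent TSS within window, opposite strands
      cand <- genes[genes$chrom == lnc_sum$chrom[i] &
                    genes$strand != lstrand &
                    abs(genes$tss - ltss) <= bidirectional_window_bp, ,
                    drop = FALSE]
      if (nrow(cand)) {
        div <- if (lstrand == "-") cand$strand == "+" & ltss <= cand$tss
               else cand$strand == "-" & ltss >= cand$tss
        cand <- cand[div, , drop = FALSE]
        if (nrow(cand)) {
          d <- abs(cand$tss - ltss)
          best <- order(d, cand$gene_id)[1]
          return(list(class = "bidirectional", partner = cand$gene_id[best],
                      dist = d[best]))
        }
      }
      # (5) intergenic
      return(list(class = "intergenic", partner = NA_character_,
                  dist = NA_real_))
    }
    # (6) other: gene-body overlap that matched no rule above
    list(class = "other", partner = NA_character_, dist = NA_real_)
  }

  res <- lapply(seq_len(nrow(lnc_sum)), classify_one)
  data.frame(
    transcript_id = lnc_sum$transcript_id,
    positional_class = vapply(res, `[[`, character(1), "class"),
    partner_gene_id = vapply(res, `[[`, character(1), "partner"),
    partner_distance_bp = vapply(res, `[[`, numeric(1), "dist"),
    stringsAsFactors = FALSE
  )
}

#' Build a lncRNA catalog from annotation plus coding-potential calls
#'
#' Convenience wrapper: filter candidate transcripts by the novelty rule,
#' apply the consensus lncRNA call, then classify positionally against the
#' coding genes of the same annotation.
#'
#' @param exons exon table containing candidates and coding genes.
#' @param calls coding-potential call table (see [consensus_lncrna_call()]).
#' @param min_length,min_exons novelty filter thresholds.
#' @param bidirectional_window_bp see [classify_lncrnas()].
#' @return classification data.frame (see [classify_lncrnas()]).
#' @export
build_lncrna_catalog <- function(exons, calls, min_length = 200,
                                 min_exons = 2,
                                 bidirectional_window_bp = 1000) {
  coding <- exons[exons$biotype %in% "coding", , drop = FALSE]
  cand <- exons[exons$transcript_id %in% calls$transcript_id, , drop = FALSE]
  cand <- filter_novel_transcripts(cand, min_length, min_exons)
  ids <- consensus_lncrna_call(
    calls[calls$transcript_id %in% unique(cand$transcript_id), , drop = FALSE])
  lnc <- cand[cand$transcript_id %in% ids, , drop = FALSE]
  if (!nrow(lnc)) {
    return(data.frame(transcript_id = character(0),
                      positional_class = character(0),
                      partner_gene_id = character(0),
                      partner_distance_bp = numeric(0)))
  }
  classify_lncrnas(lnc, coding, bidirectional_window_bp)
}
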