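# Transcript models and GTF I/O.
#
# A transcript set is a plain data.frame with one row per exon and columns
#   transcript_id, gene_id, chrom, start, end, strand, biotype
# in 1-based closed coordinates (the GTF convention, shared by
# GenomicRanges). Exons of a transcript share chrom/strand and are kept
# sorted by start and disjoint.

#' Construct / validate a transcript exon table
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` and optionally `biotype`.
#' @return the validated, exon-sorted data.frame.
#' @export
transcript_set <- function(exons) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"biotype" %in% names(exons)) exons$biotype <- NA_character_
  bad <- which(exons$end < exons$start)
  if (length(bad)) {
    stop("end < start for exon row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  # exons of one transcript must be disjoint
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in sp) {
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] <= e[-length(e)])) {
        stop("overlapping exons in transcript ",
             exons$transcript_id[idx[1]])
      }
      if (length(unique(exons$chrom[idx])) > 1L ||
          length(unique(exons$strand[idx])) > 1L) {
        stop("exons of ", exons$transcript_id[idx[1]],
             " span multiple chromosomes/strands")
      }
    }
  }
  rownames(exons) <- NULL
  exons
}

#' Per-transcript summary of an exon table
#'
#' @param exons transcript exon table (see [transcript_set()]).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `n_exons`,
#'   `length` (sum of exon widths) and `tss` (strand-aware start).
#' @export
summarize_transcripts <- function(exons) {
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(
      transcript_id = exons$transcript_id[idx[1]],
      gene_id = exons$gene_id[idx[1]],
      chrom = exons$chrom[idx[1]],
      strand = exons$strand[idx[1]],
      tx_start = min(exons$start[idx]),
      tx_end = max(exons$end[idx]),
      n_exons = length(idx),
      length = sum(exons$end[idx] - exons$start[idx] + 1L),
      biotype = exons$biotype[idx[1]],
      stringsAsFactors = FALSE
    )
  }))
  out$tss <- ifelse(out$strand == "+", out$tx_start, out$tx_end)
  rownames(out) <- NULL
  out[order(out$transcript_id), , drop = FALSE]
}

# GRanges helpers ------------------------------------------------------------

exons_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
}

spans_granges <- function(tx_summary) {
  GenomicRanges::GRanges(
    seqnames = tx_summary$chrom,
    ranges = IRanges::IRanges(start = tx_summary$tx_start,
                              end = tx_summary$tx_end),
    strand = tx_summary$strand,
    transcript_id = tx_summary$transcript_id,
    gene_id = tx_summary$gene_id
  )
}

# introns of each transcript as a GRanges (may be empty)
introns_granges <- function(exons) {
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  rows <- lapply(sp, function(idx) {
    if (length(idx) < 2L) return(NULL)
    idx <- idx[order(exons$start[idx])]
    s <- exons$start[idx]; e <- exons$end[idx]
    data.frame(chrom = exons$chrom[idx[1]],
               start = e[-length(e)] + 1L, end = s[-1] - 1L,
               strand = exons$strand[idx[1]],
               transcript_id = exons$transcript_id[idx[1]],
               gene_id = exons$gene_id[idx[1]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, transcript_id = df$transcript_id,
    gene_id = df$gene_id
  )
}

# GTF I/O --------------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Uses rtracklayer's GTF importer and keeps exon features only. Records
#' lacking a `transcript_id` attribute are a hard error (the attribute is
#' required to group exons into transcripts).
#'
#' @param path GTF file.
#' @return a transcript exon table (see [transcript_set()]).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  if (is.null(md$transcript_id) || anyNA(tid)) {
    bad <- if (is.null(md$transcript_id)) seq_along(gr) else which(is.na(tid))
    stop("GTF exon record(s) without transcript_id attribute: record ",
         paste(head(bad, 5), collapse = ", "))
  }
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id) else tid
  bt <- if (!is.null(md$biotype)) as.character(md$biotype) else NA_character_
  transcript_set(data.frame(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = bt,
    stringsAsFactors = FALSE
  ))
}

#' Write transcript models to GTF
#'
#' Deterministic formatter (stable attribute order and line order), so that
#' identical models always produce byte-identical files.
#'
#' @param exons transcript exon table.
#' @param path output file.
#' @param source source field for column 2.
#' @return the path, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lncnet") {
  exons <- transcript_set(exons)
  ord <- order(exons$chrom, exons$start, exons$transcript_id)
  ex <- exons[ord, , drop = FALSE]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                   ex$gene_id, ex$transcript_id,
                   ifelse(is.na(ex$biotype), "",
                          sprintf(' biotype "%s";', ex$biotype)))
  lines <- paste(ex$chrom, source, "exon",
                 format(ex$start, scientific = FALSE, trim = TRUE),
                 format(ex$end, scientific = FALSE, trim = TRUE), ".",
                 ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
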