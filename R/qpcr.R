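# Relative quantification (2^-ddCt) and sequencing read-retention summaries.

#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates (multiple rows per sample) are averaged first.
#' `dCt = Ct_target - Ct_reference`; `ddCt = dCt_sample - dCt_calibrator`;
#' `RQ = 2^-ddCt`. The calibrator sample has RQ = 1 by construction.
#'
#' @param records data.frame with `sample_id`, `ct_target`, `ct_reference`
#'   and optionally `group`.
#' @param calibrator sample id of the calibrator.
#' @return data.frame: `sample_id` (and `group` if present), `dct`, `ddct`,
#'   `rq`.
#' @export
ddct_quantify <- function(records, calibrator) {
  if (anyNA(records$ct_reference)) {
    bad <- unique(records$sample_id[is.na(records$ct_reference)])
    stop("missing reference Ct for sample ", paste(bad, collapse = ", "))
  }
  if (anyNA(records$ct_target)) {
    bad <- unique(records$sample_id[is.na(records$ct_target)])
    stop("missing target Ct for sample ", paste(bad, collapse = ", "))
  }
  ct_t <- tapply(records$ct_target, records$sample_id, mean)
  ct_r <- tapply(records$ct_reference, records$sample_id, mean)
  if (!calibrator %in% names(ct_t)) {
    stop("calibrator sample not present: ", calibrator)
  }
  dct <- ct_t - ct_r
  ddct <- dct - dct[[calibrator]]
  out <- data.frame(sample_id = names(dct), dct = as.numeric(dct),
                    ddct = as.numeric(ddct), rq = 2^-as.numeric(ddct),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(records)) {
    grp <- tapply(as.character(records$group), records$sample_id,
                  function(g) g[1])
    out$group <- as.character(grp[out$sample_id])
    out <- out[, c("sample_id", "group", "dct", "ddct", "rq")]
  }
  rownames(out) <- NULL
  out
}

#' Sequencing read-retention summary
#'
#' Percentages are rounded half-up to two decimals, the convention used for
#' reporting retention figures (e.g. 720,475,082 / 730,797,538 -> 98.59).
#'
#' @param raw raw read count (optional, NA allowed).
#' @param clean clean read count after primary filtering.
#' @param hq high-quality read count (must be <= clean).
#' @param rrna_free reads not mapping to rRNA (optional).
#' @param mapped reads mapped to the genome (optional).
#' @return data.frame with the counts plus `retained_pct` (= 100*hq/clean)
#'   and, when inputs are given, `rrna_free_pct` (of hq) and `mapped_pct`
#'   (of rrna_free).
#' @export
summarize_read_stats <- function(raw = NA, clean, hq, rrna_free = NA,
                                 mapped = NA) {
  if (is.na(clean) || clean <= 0) stop("clean read count must be positive")
  if (hq > clean) stop("high-quality reads cannot exceed clean reads")
  pct <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    round_half_up(100 * num / den, 2)
  }
  data.frame(raw_reads = raw, clean_reads = clean, hq_reads = hq,
             retained_pct = pct(hq, clean),
             rrna_free_pct = pct(rrna_free, hq),
             mapped_pct = pct(mapped, rrna_free))
}
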