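# Competing-endogenous-RNA network: canonical seed-match miRNA target
# candidates, Spearman/Pearson coexpression filters, the shared-miRNA
# hypergeometric sponge test, and network assembly/export.

.seed_site_patterns <- function(mirna_seq) {
  s <- chartr("Uu", "Tt", toupper(mirna_seq))
  if (nchar(s) < 8) stop("miRNA shorter than 8 nt")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  m7m8 <- rc(substr(s, 2, 8))
  list(`8mer` = paste0(m7m8, "A"),
       `7mer-m8` = m7m8,
       `7mer-A1` = paste0(rc(substr(s, 2, 7)), "A"))
}

.check_alphabet <- function(seqs, label) {
  bad <- grepl("[^ACGTUacgtuNRYSWKMBDHVn]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in ", label, " sequence(s): ",
         paste(head(names(seqs)[bad], 5), collapse = ", "))
  }
}

.read_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    setNames(as.character(ss), names(ss))
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a FASTA path or a named character vector of sequences")
  }
}

#' Canonical seed-match miRNA target scan
#'
#' Scans each target for sites complementary to the miRNA seed
#' (positions 2-8): `8mer` (positions 2-8 matched, A opposite position 1),
#' `7mer-m8` (positions 2-8), `7mer-A1` (positions 2-7 plus A). One
#' candidate per (miRNA, target) is reported with the strongest site type
#' (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param mirna_fa FASTA path or named character vector of miRNA sequences
#'   (RNA or DNA alphabet).
#' @param target_fa FASTA path or named character vector of target
#'   sequences.
#' @param target_kind label recorded for the targets ("mRNA" or "lncRNA").
#' @return data.frame: `mirna_id`, `target_id`, `target_kind`, `site_type`,
#'   `n_sites`.
#' @export
seed_match <- function(mirna_fa, target_fa, target_kind = "mRNA") {
  mir <- .read_seqs(mirna_fa)
  tgt <- .read_seqs(target_fa)
  .check_alphabet(mir, "miRNA")
  .check_alphabet(tgt, "target")
  tgt_dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(tgt)))
  rows <- list()
  for (mid in names(mir)) {
    pats <- .seed_site_patterns(mir[[mid]])
    counts <- sapply(pats, function(p)
      Biostrings::vcountPattern(p, tgt_dna))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                               dimnames = list(NULL, names(pats)))
    for (i in seq_along(tgt)) {
      # a 7mer-m8 occurrence flanked by A is the same physical site as the
      # 8mer; count non-nested occurrences per type
      n8 <- counts[i, "8mer"]
      n7m8 <- counts[i, "7mer-m8"] - n8
      n7a1 <- counts[i, "7mer-A1"] - n8
      if (n8 > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, target_id = names(tgt)[i],
          target_kind = target_kind, site_type = "8mer",
          n_sites = n8 + n7m8 + n7a1, stringsAsFactors = FALSE)
      } else if (n7m8 > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, target_id = names(tgt)[i],
          target_kind = target_kind, site_type = "7mer-m8",
          n_sites = n7m8 + n7a1, stringsAsFactors = FALSE)
      } else if (n7a1 > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, target_id = names(tgt)[i],
          target_kind = target_kind, site_type = "7mer-A1",
          n_sites = n7a1, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), site_type = character(0),
                      n_sites = integer(0)))
  }
  do.call(rbind, rows)
}

.pair_cor <- function(x, y, method) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

#' Spearman filter for miRNA-target candidates
#'
#' Computes the Spearman rank correlation (average ranks on ties) between
#' each candidate's miRNA and target expression across matched samples and
#' keeps candidates with `scc < scc_max` (strict). Constant series are
#' dropped with a message.
#'
#' @param candidates data.frame with `mirna_id` and `target_id`.
#' @param mirna_expr expression matrix of miRNAs.
#' @param target_expr expression matrix covering all candidate targets.
#' @param scc_max threshold (default -0.7, strict).
#' @return surviving candidates with an `scc` column.
#' @export
scc_filter <- function(candidates, mirna_expr, target_expr, scc_max = -0.7) {
  stopifnot(identical(colnames(mirna_expr), colnames(target_expr)))
  if (ncol(mirna_expr) < 3) stop("need >= 3 matched samples")
  scc <- vapply(seq_len(nrow(candidates)), function(i) {
    .pair_cor(mirna_expr[candidates$mirna_id[i], ],
              target_expr[candidates$target_id[i], ], "spearman")
  }, numeric(1))
  if (anyNA(scc)) {
    message("dropping ", sum(is.na(scc)),
            " candidate(s) with constant expression")
  }
  candidates$scc <- scc
  candidates[!is.na(scc) & scc < scc_max, , drop = FALSE]
}

#' Pearson filter for lncRNA-mRNA pairs
#'
#' Keeps pairs with Pearson `r > pcc_min` (strict) on `log2(expr + 1)`.
#'
#' @param pairs data.frame with `lncrna_id` and `mrna_id`.
#' @param lnc_expr,mrna_expr expression matrices with matched samples.
#' @param pcc_min threshold (default 0.9, strict).
#' @param log_transform correlate on `log2(expr + 1)` (default TRUE).
#' @return surviving pairs with a `pcc` column.
#' @export
pcc_filter <- function(pairs, lnc_expr, mrna_expr, pcc_min = 0.9,
                       log_transform = TRUE) {
  stopifnot(identical(colnames(lnc_expr), colnames(mrna_expr)))
  xl <- if (log_transform) log2p1(lnc_expr) else lnc_expr
  xm <- if (log_transform) log2p1(mrna_expr) else mrna_expr
  pcc <- vapply(seq_len(nrow(pairs)), function(i) {
    .pair_cor(xl[pairs$lncrna_id[i], ], xm[pairs$mrna_id[i], ], "pearson")
  }, numeric(1))
  if (anyNA(pcc)) {
    message("dropping ", sum(is.na(pcc)), " pair(s) with constant expression")
  }
  pairs$pcc <- pcc
  pairs[!is.na(pcc) & pcc > pcc_min, , drop = FALSE]
}

#' Shared-miRNA sponge test
#'
#' Hypergeometric upper-tail test of the number of miRNAs shared by a
#' lncRNA and an mRNA: `K` miRNAs target the lncRNA, `n` target the mRNA,
#' `k` are shared, out of a universe of `M` miRNAs;
#' `p = P(X >= k), X ~ Hypergeometric(M, K, n)`.
#'
#' @param lncrna_mirnas character vector of miRNAs targeting the lncRNA.
#' @param mrna_mirnas character vector of miRNAs targeting the mRNA.
#' @param universe character vector, the miRNA universe.
#' @return list with `k`, `K`, `n`, `M`, `pvalue`.
#' @export
sponge_test <- function(lncrna_mirnas, mrna_mirnas, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty miRNA universe")
  lncrna_mirnas <- unique(lncrna_mirnas)
  mrna_mirnas <- unique(mrna_mirnas)
  if (length(setdiff(c(lncrna_mirnas, mrna_mirnas), universe))) {
    stop("miRNA set not contained in the universe")
  }
  K <- length(lncrna_mirnas)
  n <- length(mrna_mirnas)
  k <- length(intersect(lncrna_mirnas, mrna_mirnas))
  list(k = k, K = K, n = n, M = length(universe),
       pvalue = hypergeom_tail(k, K, n, length(universe)))
}

#' Assemble the ceRNA network
#'
#' Input candidates must already have passed the negative-coexpression
#' filter ([scc_filter()]). For every lncRNA-mRNA pair sharing at least one
#' miRNA, the pair is kept iff its Pearson coexpression exceeds `pcc_min`
#' (strict) and the sponge test p-value is below `sponge_p_max` (strict).
#' When `de_ids` is given, candidate edges are first restricted to those
#' transcripts (the differential subset). Isolated nodes are removed; every
#' surviving lncRNA-mRNA edge is certified by at least one shared miRNA
#' with both of its miRNA edges in the network.
#'
#' @param candidates scc-filtered candidate table (`mirna_id`, `target_id`,
#'   `target_kind`, `scc`).
#' @param lnc_expr,mrna_expr expression matrices (matched samples).
#' @param mirna_universe miRNA universe for the sponge test; defaults to
#'   all miRNAs in `candidates`.
#' @param pcc_min Pearson gate (default 0.9, strict).
#' @param sponge_p_max sponge-test gate (default 0.05, strict).
#' @param de_ids optional character vector of transcripts allowed as nodes.
#' @return object of class `cerna_network`: list with `nodes` (`id`,
#'   `kind`), `edges` (`from`, `to`, `relation`, `scc`, `pcc`, `pvalue`)
#'   and `pairs` (the sponge-pair table with k/K/n/M/pvalue/pcc).
#' @export
build_cerna_network <- function(candidates, lnc_expr, mrna_expr,
                                mirna_universe = NULL, pcc_min = 0.9,
                                sponge_p_max = 0.05, de_ids = NULL) {
  if (is.null(mirna_universe)) mirna_universe <- unique(candidates$mirna_id)
  if (!is.null(de_ids)) {
    candidates <- candidates[candidates$target_id %in% de_ids &
                             candidates$mirna_id %in% de_ids, , drop = FALSE]
  }
  empty <- function() {
    structure(list(
      nodes = data.frame(id = character(0), kind = character(0)),
      edges = data.frame(from = character(0), to = character(0),
                         relation = character(0), scc = numeric(0),
                         pcc = numeric(0), pvalue = numeric(0)),
      pairs = data.frame(lncrna_id = character(0), mrna_id = character(0),
                         shared_k = integer(0), K = integer(0),
                         n = integer(0), M = integer(0),
                         pvalue = numeric(0), pcc = numeric(0))),
      class = "cerna_network")
  }
  lc <- candidates[candidates$target_kind == "lncRNA", , drop = FALSE]
  mc <- candidates[candidates$target_kind == "mRNA", , drop = FALSE]
  if (!nrow(lc) || !nrow(mc)) {
    warning("empty ceRNA network: no surviving candidates on both sides")
    return(empty())
  }
  mir_of_lnc <- split(lc$mirna_id, lc$target_id)
  mir_of_mrna <- split(mc$mirna_id, mc$target_id)
  combos <- expand.grid(lncrna_id = names(mir_of_lnc),
                        mrna_id = names(mir_of_mrna),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    lm <- mir_of_lnc[[combos$lncrna_id[i]]]
    mm <- mir_of_mrna[[combos$mrna_id[i]]]
    if (!length(intersect(lm, mm))) return(NULL)
    st <- sponge_test(lm, mm, mirna_universe)
    data.frame(lncrna_id = combos$lncrna_id[i], mrna_id = combos$mrna_id[i],
               shared_k = st$k, K = st$K, n = st$n, M = st$M,
               pvalue = st$pvalue, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs)) {
    warning("empty ceRNA network: no lncRNA-mRNA pair shares a miRNA")
    return(empty())
  }
  pairs <- pcc_filter(pairs, lnc_expr, mrna_expr, pcc_min = pcc_min)
  pairs <- pairs[pairs$pvalue < sponge_p_max, , drop = FALSE]
  if (!nrow(pairs)) {
    warning("empty ceRNA network: no pair passes the PCC/sponge gates")
    return(empty())
  }
  pairs <- pairs[order(pairs$lncrna_id, pairs$mrna_id), , drop = FALSE]
  rownames(pairs) <- NULL

  edge_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lncrna_id[i]; m <- pairs$mrna_id[i]
    shared <- intersect(mir_of_lnc[[l]], mir_of_mrna[[m]])
    for (mi in shared) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        from = l, to = mi, relation = "lncRNA-miRNA",
        scc = lc$scc[lc$target_id == l & lc$mirna_id == mi][1],
        pcc = NA_real_, pvalue = NA_real_, stringsAsFactors = FALSE)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        from = mi, to = m, relation = "miRNA-mRNA",
        scc = mc$scc[mc$target_id == m & mc$mirna_id == mi][1],
        pcc = NA_real_, pvalue = NA_real_, stringsAsFactors = FALSE)
    }
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      from = l, to = m, relation = "lncRNA-mRNA", scc = NA_real_,
      pcc = pairs$pcc[i], pvalue = pairs$pvalue[i], stringsAsFactors = FALSE)
  }
  edges <- unique(do.call(rbind, edge_rows))
  edges <- edges[order(edges$relation, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  mirs <- sort(unique(edges$to[edges$relation == "lncRNA-miRNA"]))
  nodes <- rbind(
    data.frame(id = sort(unique(pairs$lncrna_id)), kind = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = mirs, kind = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = sort(unique(pairs$mrna_id)), kind = "mRNA",
               stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges, pairs = pairs),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) print(table(x$nodes$kind))
  invisible(x)
}

#' Export a ceRNA network as SIF
#'
#' Simple interaction format: `source <TAB> relation <TAB> target`.
#'
#' @param network `cerna_network` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_sif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$from, e$relation, e$to, sep = "\t"), path)
  invisible(path)
}

#' Export a ceRNA network as GraphML
#'
#' Typed node attribute `kind` and edge attributes `relation`, `scc`,
#' `pcc`, `pvalue`; loadable by standard graph viewers.
#'
#' @param network `cerna_network` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
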