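# Hypergeometric over-representation analysis and gene set enrichment
# analysis (signal-to-noise ranking, weighted running-sum statistic,
# class-label permutation null).

#' Read a GMT gene-set collection
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors (members, unique), with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  if (any(!lengths(sets))) stop("GMT set with no members: ",
                                paste(ids[!lengths(sets)], collapse = ", "))
  attr(sets, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2), ids)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; optional `description`
#'   attribute as produced by [read_gmt()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, tests whether the differential gene list is enriched in the
#' set relative to the background: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)` where `N` is the background size, `K` the
#' background genes in the set, `n` the differential genes and `k` the
#' overlap. Sets are intersected with the background before counting;
#' q-values come from [bh_adjust()] over the tested sets.
#'
#' @param de_genes character vector of differential gene ids (subset of
#'   `background`).
#' @param background character vector, the gene universe.
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @return data.frame: `set_id`, `k`, `K`, `n`, `N`, `pvalue`, `qvalue`.
#' @export
ora_hypergeometric <- function(de_genes, background, sets) {
  background <- unique(background)
  de_genes <- unique(de_genes)
  off <- setdiff(de_genes, background)
  if (length(off)) {
    stop("differential genes absent from background: ",
         paste(head(off, 10), collapse = ", "))
  }
  N <- length(background)
  n <- length(de_genes)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    k <- length(intersect(members, de_genes))
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               pvalue = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$qvalue <- bh_adjust(res$pvalue)
  res
}

#' GSEA significance gates
#'
#' A set is significant iff `|NES| > 1`, nominal `p < 0.05` and FDR
#' `q < 0.25` — all strict inequalities, so `|NES| = 1` exactly is not
#' significant.
#'
#' @param nes normalized enrichment scores.
#' @param nominal_p nominal permutation p-values.
#' @param fdr_q FDR q-values.
#' @return logical vector.
#' @export
gsea_gates <- function(nes, nominal_p, fdr_q) {
  is.finite(nes) & abs(nes) > 1 & nominal_p < 0.05 &
    !is.na(fdr_q) & fdr_q < 0.25
}

# signal-to-noise sigma floor of the canonical GSEA implementation
.snr_sigma <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)

#' Signal-to-noise gene ranking
#'
#' Metric `(mu_A - mu_B) / (sigma_A' + sigma_B')` on `log2(FPKM + 1)`, each
#' standard deviation floored at `max(0.2 * |mu|, 0.2)`. Sorted descending;
#' ties broken by transcript id.
#'
#' @param fpkm FPKM matrix.
#' @param design design data.frame (`sample_id`, `stage`).
#' @param stage_a,stage_b the two classes (A first).
#' @return named numeric vector of metric values in rank order.
#' @export
snr_rank <- function(fpkm, design, stage_a, stage_b) {
  sa <- design$sample_id[design$stage == stage_a]
  sb <- design$sample_id[design$stage == stage_b]
  if (!length(sa) || !length(sb)) stop("empty class: ",
                                       if (!length(sa)) stage_a else stage_b)
  if (length(sa) < 2 || length(sb) < 2) stop("need >= 2 replicates per class")
  la <- log2p1(fpkm[, sa, drop = FALSE])
  lb <- log2p1(fpkm[, sb, drop = FALSE])
  ma <- rowMeans(la); mb <- rowMeans(lb)
  s <- (ma - mb) / (.snr_sigma(sqrt(rowVars(la)), ma) +
                    .snr_sigma(sqrt(rowVars(lb)), mb))
  ids <- rownames(fpkm)
  o <- order(-s, ids)
  setNames(s[o], ids[o])
}

# Core running-sum walk from hit positions.
# pos: sorted 1-based ranks of the hits; w: matching weights (|metric|^p);
# n total genes. Returns es, index (into pos) of the extremum, sign.
.es_from_positions <- function(pos, w, n) {
  nh <- length(pos)
  nm <- n - nh
  if (nm == 0) return(list(es = 1, i = nh))  # degenerate: set == universe
  wsum <- sum(w)
  inc <- if (wsum > 0) cumsum(w) / wsum else seq_len(nh) / nh
  miss_before <- (pos - seq_len(nh)) / nm
  after_hit <- inc - miss_before        # running sum right after each hit
  before_hit <- c(0, inc[-nh]) - miss_before  # right before each hit
  i_max <- which.max(after_hit)
  i_min <- which.min(before_hit)
  if (after_hit[i_max] >= -before_hit[i_min]) {
    list(es = after_hit[i_max], i = i_max)
  } else {
    list(es = before_hit[i_min], i = i_min)
  }
}

#' GSEA enrichment score for one set
#'
#' Walks the ranked list; hits increment the running sum by
#' `|metric|^weight / sum_hits |metric|^weight`, misses decrement by
#' `1 / (N - N_hits)`. The enrichment score is the signed maximum deviation
#' from zero; the leading edge contains the hits up to the extremum (es > 0)
#' or from the extremum on (es < 0). `weight = 0` reduces to the classical
#' unweighted Kolmogorov-Smirnov statistic.
#'
#' @param ranked named numeric vector of metric values in descending rank
#'   order (as from [snr_rank()]).
#' @param set character vector of member ids.
#' @param weight exponent on `|metric|` (default 1).
#' @return list with `es`, `leading_edge` (character vector) and `size`.
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  hit <- names(ranked) %in% set
  if (!any(hit)) stop("gene set does not intersect the ranked list")
  pos <- which(hit)
  w <- abs(ranked[pos])^weight
  r <- .es_from_positions(pos, w, length(ranked))
  le <- if (r$es >= 0) names(ranked)[pos[seq_len(r$i)]]
        else names(ranked)[pos[r$i:length(pos)]]
  list(es = unname(r$es), leading_edge = le, size = length(pos))
}

# all / sampled label assignments for a two-class permutation null.
# Returns a list of integer vectors (indices of class-A samples), the
# observed assignment excluded; attr "exhaustive" records the regime.
.label_assignments <- function(n, na, observed, n_perm) {
  total <- choose(n, na)
  if (total <= n_perm + 1) {
    cols <- combn(n, na)
    keys <- apply(cols, 2, paste, collapse = ",")
    obs_key <- paste(sort(observed), collapse = ",")
    out <- lapply(which(keys != obs_key), function(j) cols[, j])
    attr(out, "exhaustive") <- TRUE
    attr(out, "n_assignments") <- total
    return(out)
  }
  seen <- character(0)
  out <- list()
  obs_key <- paste(sort(observed), collapse = ",")
  tries <- 0L
  while (length(out) < n_perm && tries < 50L * n_perm) {
    tries <- tries + 1L
    idx <- sort(sample.int(n, na))
    key <- paste(idx, collapse = ",")
    if (key == obs_key || key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- idx
  }
  attr(out, "exhaustive") <- FALSE
  attr(out, "n_assignments") <- total
  out
}

# signal-to-noise metric for one assignment of columns into A (idx) vs B
.snr_metric_cols <- function(lx, idx) {
  la <- lx[, idx, drop = FALSE]
  lb <- lx[, -idx, drop = FALSE]
  ma <- rowMeans(la); mb <- rowMeans(lb)
  (ma - mb) / (.snr_sigma(sqrt(rowVars(la)), ma) +
               .snr_sigma(sqrt(rowVars(lb)), mb))
}

#' GSEA with class-label permutation
#'
#' Ranks genes by signal to noise, computes the weighted running-sum
#' enrichment score per set, and assesses significance by permuting class
#' labels. When the number of distinct label assignments is at most
#' `n_perm` the null is enumerated exhaustively (e.g. 20 assignments for a
#' 3v3 design, giving a nominal-p floor of 0.05); otherwise assignments are
#' sampled without replacement. The observed assignment is excluded from
#' the null.
#'
#' Nominal p is `(1 + #same-sign permutation ES beyond observed) /
#' (1 + #same-sign permutations)`; NES divides the observed ES by the mean
#' |same-sign permutation ES| of the set. FDR q follows the sign-matched
#' tail-ratio of the pooled permutation NES distribution (`fdr_method =
#' "gsea"`) or BH over nominal p (`"bh"`). Significance gates: |NES| > 1,
#' p < 0.05, q < 0.25, all strict.
#'
#' @param fpkm FPKM matrix.
#' @param design design data.frame (`sample_id`, `stage`).
#' @param sets named list of gene-id vectors.
#' @param stage_a,stage_b the two classes.
#' @param n_perm maximum number of permutations (default 1000).
#' @param seed RNG seed for sampled permutations.
#' @param weight running-sum weight (default 1).
#' @param min_size,max_size set-size window after intersection with the
#'   expression matrix (defaults 15 and 500).
#' @param fdr_method `"gsea"` (default) or `"bh"`.
#' @return data.frame: `set_id`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `significant`, `leading_edge` (comma-separated). Attribute
#'   `n_assignments` records the size of the assignment space.
#' @export
gsea_permutation <- function(fpkm, design, sets, stage_a, stage_b,
                             n_perm = 1000, seed = 1, weight = 1,
                             min_size = 15, max_size = 500,
                             fdr_method = c("gsea", "bh")) {
  fdr_method <- match.arg(fdr_method)
  sa <- design$sample_id[design$stage == stage_a]
  sb <- design$sample_id[design$stage == stage_b]
  if (length(sa) < 2 || length(sb) < 2) stop("need >= 2 replicates per class")
  cols <- c(sa, sb)
  lx <- log2p1(fpkm[, cols, drop = FALSE])
  ids <- rownames(lx)
  n <- length(cols); na <- length(sa)
  observed <- seq_len(na)

  keep <- vapply(sets, function(s) {
    sz <- length(intersect(s, ids)); sz >= min_size && sz <= max_size
  }, logical(1))
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set within the size window")

  set.seed(seed)
  perms <- .label_assignments(n, na, observed, n_perm)
  if (length(perms) < 2) {
    stop("fewer than 2 distinct label permutations; ",
         "use gene-set permutation instead")
  }
  if (isTRUE(attr(perms, "exhaustive"))) {
    message("exhaustive class-label null: ", attr(perms, "n_assignments"),
            " assignments enumerated; minimum attainable p = ",
            signif(1 / (1 + length(perms)), 3))
  }

  es_one <- function(metric, set_ids) {
    o <- order(-metric, ids)
    hit <- ids[o] %in% set_ids
    pos <- which(hit)
    w <- abs(metric[o][pos])^weight
    .es_from_positions(pos, w, length(ids))$es
  }

  obs_metric <- .snr_metric_cols(lx, observed)
  obs <- lapply(sets, function(s) {
    gsea_es(setNames(obs_metric, ids)[order(-obs_metric, ids)], s, weight)
  })
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  perm_es <- matrix(NA_real_, nrow = length(sets), ncol = length(perms),
                    dimnames = list(names(sets), NULL))
  for (j in seq_along(perms)) {
    m <- .snr_metric_cols(lx, perms[[j]])
    for (s in seq_along(sets)) perm_es[s, j] <- es_one(m, sets[[s]])
  }

  nominal_p <- nes <- numeric(length(sets))
  pos_mean <- neg_mean <- rep(NA_real_, length(sets))
  for (s in seq_along(sets)) {
    pe <- perm_es[s, ]
    pos_mean[s] <- mean(pe[pe > 0])
    neg_mean[s] <- mean(abs(pe[pe < 0]))
    same <- if (es_obs[s] >= 0) pe[pe >= 0] else pe[pe < 0]
    nominal_p[s] <- (1 + sum(abs(same) >= abs(es_obs[s]))) / (1 + length(same))
    norm <- if (es_obs[s] >= 0) pos_mean[s] else neg_mean[s]
    nes[s] <- if (is.finite(norm) && norm > 0) es_obs[s] / norm else NA_real_
  }

  if (fdr_method == "bh") {
    fdr_q <- bh_adjust(nominal_p)
  } else {
    nes_perm <- perm_es
    for (s in seq_along(sets)) {
      pe <- perm_es[s, ]
      nes_perm[s, ] <- ifelse(pe >= 0, pe / pos_mean[s], pe / neg_mean[s])
    }
    pool <- nes_perm[is.finite(nes_perm)]
    fdr_q <- vapply(seq_along(sets), function(s) {
      v <- nes[s]
      if (!is.finite(v)) return(NA_real_)
      if (v >= 0) {
        pp <- pool[pool >= 0]; oo <- nes[is.finite(nes) & nes >= 0]
        num <- if (length(pp)) mean(pp >= v) else 0
        den <- mean(oo >= v)
      } else {
        pp <- pool[pool < 0]; oo <- nes[is.finite(nes) & nes < 0]
        num <- if (length(pp)) mean(pp <= v) else 0
        den <- mean(oo <= v)
      }
      min(1, num / den)
    }, numeric(1))
  }

  res <- data.frame(
    set_id = names(sets),
    size = vapply(obs, `[[`, numeric(1), "size"),
    es = unname(es_obs),
    nes = unname(nes),
    nominal_p = unname(nominal_p),
    fdr_q = unname(fdr_q),
    stringsAsFactors = FALSE
  )
  res$significant <- gsea_gates(res$nes, res$nominal_p, res$fdr_q)
  res$leading_edge <- vapply(obs, function(x)
    paste(x$leading_edge, collapse = ","), character(1))
  rownames(res) <- NULL
  attr(res, "n_assignments") <- attr(perms, "n_assignments")
  attr(res, "n_perm_used") <- length(perms)
  res
}
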