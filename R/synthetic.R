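# Synthetic-data generator with planted ground truth.
#
# Emulates a staged ovary RNA-seq design (three stages x three replicates by
# default): deterministic annotation geometry realizing every positional
# lncRNA class, negative-binomial counts with planted stage effects and
# latent-factor ceRNA coupling, transcript/miRNA sequences with planted
# seed-match sites and screened decoys, and qPCR plates with known fold
# changes. Every planted item is recorded in a truth ledger for recovery
# testing.

.slot_bp <- 400000L
.anchor_off <- 200000L

#' Synthetic dataset configuration
#'
#' @param seed integer RNG seed; drives counts, sequences and qPCR noise
#'   (annotation geometry is deterministic).
#' @param n_chrom number of chromosomes.
#' @param n_coding_genes number of protein-coding genes (one transcript
#'   each, three exons); must be at least `4 * n_lncrna_per_class` so each
#'   gene-attached lncRNA class gets its own host gene.
#' @param n_lncrna_per_class lncRNAs planted per positional class
#'   (intergenic, bidirectional, intronic, antisense, sense_overlapping).
#' @param n_mirna number of miRNA loci.
#' @param design data.frame with `stage` and `n_replicates`.
#' @param baseline_mean expected fragments per transcript (default 1000).
#' @param dispersion NB dispersion phi >= 0 in `Var = mu + phi mu^2`
#'   (default 0.1, a typical bulk RNA-seq value; 0 gives Poisson counts).
#' @param planted_de data.frame `transcript_id`, `comparison`
#'   (e.g. "IV_vs_V"), `log2fc`; the effect shifts the later stage and all
#'   stages after it.
#' @param planted_triplets data.frame `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `beta`; rows with `beta > 0` are coupled ceRNA triplets (a latent
#'   per-sample factor enters the miRNA log2 mean with -beta and the
#'   lncRNA/mRNA means with +beta); rows with `beta = 0` are decoys that
#'   get seed-match sites but no expression coupling.
#' @param cis_window_bp cis neighborhood used when placing features
#'   (default 100000).
#' @param bidirectional_window_bp divergent-promoter window (default 1000).
#' @param chrom_lengths optional numeric vector of chromosome lengths; an
#'   error names any chromosome too short for its features.
#' @param qpcr list: `folds` (named vector of true fold changes per group),
#'   `calibrator` (group with fold 1), `sigma` (Ct noise SD),
#'   `n_replicates` (technical replicates).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chrom = 3,
                             n_coding_genes = 50,
                             n_lncrna_per_class = 6,
                             n_mirna = 200,
                             design = data.frame(stage = c("IV", "V", "VI"),
                                                 n_replicates = 3),
                             baseline_mean = 1000,
                             dispersion = 0.1,
                             planted_de = NULL,
                             planted_triplets = NULL,
                             cis_window_bp = 100000,
                             bidirectional_window_bp = 1000,
                             chrom_lengths = NULL,
                             qpcr = list(folds = c(IV = 1, V = 2, VI = 8),
                                         calibrator = "IV", sigma = 0.1,
                                         n_replicates = 3)) {
  if (n_chrom < 1 || n_coding_genes < 1 || n_lncrna_per_class < 1 ||
      n_mirna < 1) stop("all feature counts must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (anyDuplicated(design$stage)) stop("stage labels must be unique")
  if (any(design$n_replicates < 2)) stop("every stage needs >= 2 replicates")
  if (n_coding_genes < 4 * n_lncrna_per_class) {
    stop("need n_coding_genes >= 4 * n_lncrna_per_class (one host gene per ",
         "gene-attached lncRNA)")
  }
  if (is.null(planted_de)) {
    planted_de <- .default_planted_de(n_coding_genes, n_lncrna_per_class,
                                      n_mirna)
  }
  if (is.null(planted_triplets)) {
    planted_triplets <- .default_triplets(n_coding_genes,
                                          n_lncrna_per_class, n_mirna)
  }
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              n_coding_genes = n_coding_genes,
              n_lncrna_per_class = n_lncrna_per_class, n_mirna = n_mirna,
              design = design, baseline_mean = baseline_mean,
              dispersion = dispersion, planted_de = planted_de,
              planted_triplets = planted_triplets,
              cis_window_bp = cis_window_bp,
              bidirectional_window_bp = bidirectional_window_bp,
              chrom_lengths = chrom_lengths, qpcr = qpcr)
  class(cfg) <- "synthetic_config"
  cfg
}

# defaults assume the default sizes (20 genes, 4 lncRNAs/class, 10 miRNAs);
# triplet members are also planted DE with coherent signs so that the
# paper-scale pipeline demo yields a nonempty differential ceRNA network.
# Demo defaults require room for planted structure (five lncRNA classes,
# eight miRNAs, a dozen plain genes); for smaller worlds nothing is planted
# and the caller supplies explicit planted_de / planted_triplets.
.default_planted_de <- function(ng, npc, nm) {
  if (npc < 4 || nm < 8 || ng < 4 * npc + 14) {
    return(data.frame(transcript_id = character(0),
                      comparison = character(0), log2fc = numeric(0)))
  }
  plain <- 4 * npc  # plain genes start after the attached hosts
  mr <- function(i) sprintf("mrna_%03d", plain + i)
  data.frame(
    transcript_id = c(mr(7), mr(8), mr(9), mr(10), mr(13), mr(14),
                      "lnc_intergenic_03", "lnc_intergenic_04",
                      mr(1), mr(2), mr(3), mr(4), mr(5), mr(6),
                      mr(11), mr(12),
                      "lnc_intergenic_01", "lnc_intergenic_02",
                      "lnc_bidirectional_01",
                      "mir_001", "mir_002", "mir_003", "mir_004"),
    comparison = c(rep("IV_vs_V", 8), rep("V_vs_VI", 15)),
    log2fc = c(4, -4, 4, -4, -4, -4, 4, -4,
               3, 3, -3, -3, -3, -3, 5, 5, 5, 5, -3,
               -5, -5, -5, -5),
    stringsAsFactors = FALSE
  )
}

# two coupled (lncRNA, mRNA) pairs, each sharing two miRNAs (so the sponge
# test sees k = 2 shared of K = n = 2 against the expressed-miRNA
# universe), plus four uncoupled decoy triplets that get seed-match sites
# but beta = 0
.default_triplets <- function(ng, npc, nm) {
  if (npc < 4 || nm < 8 || ng < 4 * npc + 14) {
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), beta = numeric(0)))
  }
  plain <- 4 * npc
  mr <- function(i) sprintf("mrna_%03d", plain + i)
  data.frame(
    lncrna_id = c("lnc_intergenic_01", "lnc_intergenic_01",
                  "lnc_intergenic_02", "lnc_intergenic_02",
                  "lnc_bidirectional_02", "lnc_bidirectional_03",
                  "lnc_intronic_01", "lnc_antisense_01"),
    mirna_id = c("mir_001", "mir_002", "mir_003", "mir_004",
                 "mir_005", "mir_006", "mir_007", "mir_008"),
    mrna_id = c(mr(11), mr(11), mr(12), mr(12),
                "mrna_001", "mrna_002", "mrna_003", "mrna_004"),
    beta = c(0.2, 0.2, 0.2, 0.2, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

.lnc_classes <- c("intergenic", "bidirectional", "intronic", "antisense",
                  "sense_overlapping")

# exon rows for one coding-gene cassette anchored at a
.gene_exons <- function(gid, tid, chrom, a, strand) {
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             start = c(a, a + 20000L, a + 40000L),
             end = c(a + 999L, a + 20999L, a + 40999L),
             strand = strand, biotype = "coding", stringsAsFactors = FALSE)
}

# exon rows for a lncRNA of the given class attached to a gene at anchor a
.lnc_exons <- function(tid, chrom, a, class, gene_strand) {
  flip <- function(s) if (s == "+") "-" else "+"
  geom <- switch(class,
    bidirectional = if (gene_strand == "+") {
      list(start = c(a - 1600L, a - 900L), end = c(a - 1200L, a - 401L),
           strand = "-")
    } else {
      list(start = c(a + 41400L, a + 42400L), end = c(a + 41900L, a + 42900L),
           strand = "+")
    },
    intronic = list(start = c(a + 3000L, a + 4200L),
                    end = c(a + 3400L, a + 4800L), strand = gene_strand),
    antisense = list(start = c(a + 20500L, a + 22000L),
                     end = c(a + 21400L, a + 22300L),
                     strand = flip(gene_strand)),
    sense_overlapping = list(start = c(a - 2500L, a - 1200L),
                             end = c(a - 2000L, a + 200L),
                             strand = gene_strand),
    intergenic = list(start = c(a, a + 1000L), end = c(a + 500L, a + 1500L),
                      strand = "+"),
    stop("unknown class: ", class))
  data.frame(transcript_id = tid, gene_id = tid, chrom = chrom,
             start = geom$start, end = geom$end, strand = geom$strand,
             biotype = "lncRNA", stringsAsFactors = FALSE)
}

#' Generate annotation with planted positional lncRNA classes
#'
#' Deterministic geometry: each coding gene, intergenic lncRNA and miRNA
#' locus occupies its own 400 kb slot (round-robin across chromosomes), so
#' features of different slots are > 100 kb apart and each planted lncRNA
#' satisfies exactly its class rule with margin. Gene-attached classes
#' (bidirectional, intronic, antisense, sense_overlapping) each use a
#' dedicated host gene.
#'
#' @param config a [synthetic_config()].
#' @return list with `exons` (transcript exon table), `truth` (ledger with
#'   `class_of`, `target_pairs`, `de_ids`, `triplets`, `design`) and
#'   `chrom_lengths`.
#' @export
generate_annotation <- function(config) {
  npc <- config$n_lncrna_per_class
  ng <- config$n_coding_genes
  gene_ids <- sprintf("gene_%03d", seq_len(ng))
  mrna_ids <- sprintf("mrna_%03d", seq_len(ng))
  mir_ids <- sprintf("mir_%03d", seq_len(config$n_mirna))
  # slot plan: coding genes first, then intergenic lncRNA slots, then miRNAs
  n_slots <- ng + npc + config$n_mirna
  slot_chrom <- ((seq_len(n_slots) - 1L) %% config$n_chrom) + 1L
  slot_pos <- (seq_len(n_slots) - 1L) %/% config$n_chrom
  chrom <- paste0("chr", slot_chrom)
  anchor <- slot_pos * .slot_bp + .anchor_off

  rows <- list()
  target_pairs <- list()
  class_rows <- list()
  # gene-attached lncRNA classes, one host gene per lncRNA
  attach_class <- rep(c("bidirectional", "intronic", "antisense",
                        "sense_overlapping"), each = npc)
  for (i in seq_len(ng)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    rows[[length(rows) + 1L]] <- .gene_exons(gene_ids[i], mrna_ids[i],
                                             chrom[i], anchor[i], strand)
    if (i <= length(attach_class)) {
      cls <- attach_class[i]
      idx <- ((i - 1L) %% npc) + 1L
      tid <- sprintf("lnc_%s_%02d", cls, idx)
      rows[[length(rows) + 1L]] <- .lnc_exons(tid, chrom[i], anchor[i], cls,
                                              strand)
      class_rows[[length(class_rows) + 1L]] <-
        data.frame(transcript_id = tid, positional_class = cls,
                   stringsAsFactors = FALSE)
      if (cls == "bidirectional") {
        target_pairs[[length(target_pairs) + 1L]] <-
          data.frame(lncrna_id = tid, gene_id = gene_ids[i],
                     mechanism = "cis", stringsAsFactors = FALSE)
      } else if (cls == "antisense") {
        target_pairs[[length(target_pairs) + 1L]] <-
          data.frame(lncrna_id = tid, gene_id = gene_ids[i],
                     mechanism = "antisense", stringsAsFactors = FALSE)
      }
    }
  }
  for (j in seq_len(npc)) {
    s <- ng + j
    tid <- sprintf("lnc_intergenic_%02d", j)
    rows[[length(rows) + 1L]] <- .lnc_exons(tid, chrom[s], anchor[s],
                                            "intergenic", "+")
    class_rows[[length(class_rows) + 1L]] <-
      data.frame(transcript_id = tid, positional_class = "intergenic",
                 stringsAsFactors = FALSE)
  }
  for (k in seq_len(config$n_mirna)) {
    s <- ng + npc + k
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = mir_ids[k], gene_id = mir_ids[k], chrom = chrom[s],
      start = anchor[s], end = anchor[s] + 21L, strand = "+",
      biotype = "miRNA", stringsAsFactors = FALSE)
  }
  exons <- transcript_set(do.call(rbind, rows))

  # chromosome sizing
  need <- tapply(exons$end, exons$chrom, max) + 50000
  if (!is.null(config$chrom_lengths)) {
    given <- config$chrom_lengths
    if (is.null(names(given))) names(given) <- paste0("chr",
                                                      seq_along(given))
    for (cn in names(need)) {
      if (!cn %in% names(given) || given[[cn]] < need[[cn]]) {
        stop("chromosome ", cn, " too short: need >= ", need[[cn]], " bp")
      }
    }
    chrom_lengths <- given
  } else {
    chrom_lengths <- need
  }

  all_ids <- unique(exons$transcript_id)
  planted_ids <- unique(c(config$planted_de$transcript_id,
                          config$planted_triplets$lncrna_id,
                          config$planted_triplets$mirna_id,
                          config$planted_triplets$mrna_id))
  missing <- setdiff(planted_ids, all_ids)
  if (length(missing)) {
    stop("planted ids absent from the generated annotation: ",
         paste(missing, collapse = ", "))
  }

  design <- config$design
  sample_ids <- unlist(lapply(seq_len(nrow(design)), function(i) {
    paste0(design$stage[i], "_", seq_len(design$n_replicates[i]))
  }))
  design_long <- data.frame(
    sample_id = sample_ids,
    stage = rep(design$stage, design$n_replicates),
    replicate = unlist(lapply(design$n_replicates, seq_len)),
    stringsAsFactors = FALSE)

  trip <- config$planted_triplets
  trans_pairs_truth <- if (!is.null(trip) && any(trip$beta > 0)) {
    list(unique(data.frame(lncrna_id = trip$lncrna_id[trip$beta > 0],
                           gene_id = trip$mrna_id[trip$beta > 0],
                           mechanism = "trans", stringsAsFactors = FALSE)))
  } else list()
  truth <- list(
    class_of = do.call(rbind, class_rows),
    target_pairs = do.call(rbind, c(target_pairs, trans_pairs_truth)),
    de_ids = config$planted_de,
    triplets = trip,
    design = design_long
  )
  list(exons = exons, truth = truth, chrom_lengths = chrom_lengths)
}

# per-stage cumulative log2 offsets from the planted DE table
.stage_offsets <- function(planted_de, stages, ids) {
  off <- matrix(0, nrow = length(ids), ncol = length(stages),
                dimnames = list(ids, stages))
  if (is.null(planted_de) || !nrow(planted_de)) return(off)
  for (i in seq_len(nrow(planted_de))) {
    cmp <- strsplit(planted_de$comparison[i], "_vs_")[[1]]
    if (length(cmp) != 2 || !all(cmp %in% stages)) {
      stop("bad comparison label: ", planted_de$comparison[i])
    }
    j <- match(cmp[2], stages)
    tid <- planted_de$transcript_id[i]
    off[tid, seq(j, length(stages))] <-
      off[tid, seq(j, length(stages))] + planted_de$log2fc[i]
  }
  off
}

#' Generate negative-binomial count matrices with planted structure
#'
#' Counts are `NB(mu, phi)` with `Var = mu + phi mu^2`. The log2 mean is
#' `log2(baseline_mean)` plus the cumulative planted stage effects, plus,
#' for each coupled triplet, a per-sample latent factor `z_s ~ N(0,1)`
#' entering the miRNA with coefficient `-beta` and the lncRNA/mRNA with
#' `+beta` — guaranteeing negative miRNA-target and positive lncRNA-mRNA
#' expected correlation.
#'
#' @param annotation result of [generate_annotation()].
#' @param config the [synthetic_config()].
#' @return list: `mrna_counts`, `lncrna_counts`, `mirna_counts` (integer
#'   matrices), `lengths` (named bp vector), `design` (long design table).
#' @export
generate_counts <- function(annotation, config) {
  if (config$dispersion < 0) stop("dispersion must be >= 0")
  set.seed(config$seed + .seed_offsets[["counts"]])
  txs <- summarize_transcripts(annotation$exons)
  design <- annotation$truth$design
  stages <- unique(design$stage)
  ids <- txs$transcript_id
  off <- .stage_offsets(config$planted_de, stages, ids)
  log2mu <- matrix(log2(config$baseline_mean), nrow = length(ids),
                   ncol = nrow(design),
                   dimnames = list(ids, design$sample_id))
  log2mu <- log2mu + off[, design$stage, drop = FALSE]

  trip <- config$planted_triplets
  if (!is.null(trip) && nrow(trip)) {
    z <- matrix(rnorm(nrow(trip) * nrow(design)), nrow = nrow(trip))
    for (i in seq_len(nrow(trip))) {
      b <- trip$beta[i]
      if (b == 0) next
      log2mu[trip$lncrna_id[i], ] <- log2mu[trip$lncrna_id[i], ] + b * z[i, ]
      log2mu[trip$mrna_id[i], ] <- log2mu[trip$mrna_id[i], ] + b * z[i, ]
      log2mu[trip$mirna_id[i], ] <- log2mu[trip$mirna_id[i], ] - b * z[i, ]
    }
  }
  mu <- 2^log2mu
  phi <- config$dispersion
  counts <- if (phi > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  }
  kind <- txs$biotype[match(ids, txs$transcript_id)]
  lengths <- setNames(txs$length, txs$transcript_id)
  list(mrna_counts = counts[kind == "coding", , drop = FALSE],
       lncrna_counts = counts[kind == "lncRNA", , drop = FALSE],
       mirna_counts = counts[kind == "miRNA", , drop = FALSE],
       lengths = lengths, design = design)
}

.rc_dna <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# 6mer core complementary to miRNA positions 2-7 (DNA alphabet); removing
# every occurrence kills all canonical site types
.seed_core <- function(mirna_seq) {
  .rc_dna(substr(chartr("Uu", "Tt", toupper(mirna_seq)), 2, 7))
}

#' Generate transcript and miRNA sequences with planted seed sites
#'
#' Each triplet's lncRNA and mRNA carry at least one exact 8mer site for
#' the triplet's miRNA (seed positions 2-8 plus A opposite position 1);
#' all other (miRNA, transcript) combinations are screened so no canonical
#' site (down to the 6mer core) remains, making seed-match recovery exact.
#'
#' @param annotation result of [generate_annotation()].
#' @param config the [synthetic_config()].
#' @return list: `transcript_seqs` (named DNA strings for mRNAs/lncRNAs),
#'   `mirna_seqs` (named RNA strings).
#' @export
generate_sequences <- function(annotation, config) {
  set.seed(config$seed + .seed_offsets[["sequences"]])
  txs <- summarize_transcripts(annotation$exons)
  tx <- txs[txs$biotype %in% c("coding", "lncRNA"), , drop = FALSE]
  mir_ids <- txs$transcript_id[txs$biotype == "miRNA"]

  # miRNA sequences with pairwise-distinct seed cores
  mir_seqs <- character(0)
  cores <- character(0)
  for (mid in mir_ids) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                 collapse = "")
      core <- .seed_core(s)
      if (!core %in% cores) break
    }
    mir_seqs[mid] <- s
    cores[mid] <- core
  }

  seqs <- setNames(vapply(tx$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)), tx$transcript_id)

  trip <- config$planted_triplets
  site_of <- list()  # target id -> named vector of 8mer sites by miRNA
  if (!is.null(trip) && nrow(trip)) {
    for (i in seq_len(nrow(trip))) {
      site <- paste0(.rc_dna(substr(chartr("Uu", "Tt",
                                           mir_seqs[[trip$mirna_id[i]]]),
                                    2, 8)), "A")
      for (t in c(trip$lncrna_id[i], trip$mrna_id[i])) {
        sv <- site_of[[t]]
        if (!trip$mirna_id[i] %in% names(sv)) {
          site_of[[t]] <- c(sv, setNames(site, trip$mirna_id[i]))
        }
      }
    }
  }

  insert_sites <- function(s, sites) {
    pos <- max(1L, nchar(s) %/% 3L)
    for (site in sites) {
      substr(s, pos, pos + nchar(site) - 1L) <- site
      pos <- pos + nchar(site) + 4L
    }
    s
  }
  for (t in names(site_of)) seqs[t] <- insert_sites(seqs[t], site_of[[t]])

  # detectable site patterns (7mer-m8 and 7mer-A1) per miRNA; removing both
  # leaves no canonical site for the matcher to find
  pats <- lapply(mir_seqs, function(s) {
    d <- chartr("Uu", "Tt", toupper(s))
    c(.rc_dna(substr(d, 2, 8)), paste0(.rc_dna(substr(d, 2, 7)), "A"))
  })
  site_ranges <- function(t) {
    # positions occupied by planted sites (protected from mutation)
    out <- integer(0)
    for (site in site_of[[t]] %||% character(0)) {
      m <- gregexpr(site, seqs[[t]], fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        for (p in m) out <- c(out, seq(p, p + nchar(site) - 1L))
      }
    }
    out
  }

  # screen: no foreign canonical site outside protected planted regions;
  # randomized middle-base mutation (seeded) avoids deterministic cycles
  for (iter in 1:100) {
    dirty <- FALSE
    for (t in names(seqs)) {
      protected <- site_ranges(t)
      own <- names(site_of[[t]] %||% character(0))
      for (mid in mir_ids) {
        if (mid %in% own) next
        for (pat in pats[[mid]]) {
          repeat {
            m <- gregexpr(pat, seqs[[t]], fixed = TRUE)[[1]]
            m <- m[m != -1L]
            m <- m[!vapply(m, function(p)
              any(seq(p, p + nchar(pat) - 1L) %in% protected), logical(1))]
            if (!length(m)) break
            dirty <- TRUE
            p <- m[1] + 3L
            b <- substr(seqs[[t]], p, p)
            substr(seqs[[t]], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1)
          }
        }
      }
    }
    # restore planted sites possibly clobbered by the screen
    for (t in names(site_of)) {
      missing <- vapply(site_of[[t]], function(site)
        regexpr(site, seqs[[t]], fixed = TRUE) == -1L, logical(1))
      if (any(missing)) {
        dirty <- TRUE
        seqs[t] <- insert_sites(seqs[t], site_of[[t]])
      }
    }
    if (!dirty) break
    if (iter == 100) stop("sequence screening did not converge")
  }
  list(transcript_seqs = seqs, mirna_seqs = mir_seqs)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (DNA or RNA alphabet).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Generate a qPCR Ct table with known relative quantities
#'
#' Ct values are built so that [ddct_quantify()] recovers the configured
#' fold change exactly when `sigma = 0`: the target Ct of each group is the
#' calibrator's minus `log2(fold)`, plus the group's reference-gene shift.
#'
#' @param config the [synthetic_config()] (uses its `qpcr` block and seed).
#' @param sigma override for the Ct noise SD.
#' @return data.frame: `sample_id`, `group`, `replicate`, `ct_target`,
#'   `ct_reference`.
#' @export
generate_qpcr <- function(config, sigma = NULL) {
  q <- config$qpcr
  sigma <- sigma %||% q$sigma
  set.seed(config$seed + .seed_offsets[["qpcr"]])
  rows <- lapply(names(q$folds), function(g) {
    nrep <- q$n_replicates
    ref <- 20 + rnorm(nrep, sd = sigma)
    tgt <- ref + 5 - log2(q$folds[[g]]) + rnorm(nrep, sd = sigma)
    data.frame(sample_id = paste0("q_", g), group = g,
               replicate = seq_len(nrep), ct_target = tgt,
               ct_reference = ref, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coding-potential call table for the synthetic annotation
#'
#' lncRNAs are flagged non-coding by both tools with no protein hit; coding
#' transcripts the opposite — so the consensus intersection rule recovers
#' exactly the planted lncRNAs.
#'
#' @param annotation result of [generate_annotation()].
#' @return data.frame: `transcript_id`, `cnci_noncoding`, `cpc_noncoding`,
#'   `swissprot_hit`.
#' @export
generate_coding_potential_calls <- function(annotation) {
  txs <- summarize_transcripts(annotation$exons)
  txs <- txs[txs$biotype %in% c("coding", "lncRNA"), , drop = FALSE]
  is_lnc <- txs$biotype == "lncRNA"
  data.frame(transcript_id = txs$transcript_id,
             cnci_noncoding = is_lnc,
             cpc_noncoding = is_lnc,
             swissprot_hit = !is_lnc,
             stringsAsFactors = FALSE)
}

#' Gene-set collection for the synthetic annotation
#'
#' Three deterministic sets over coding gene ids: the planted
#' stage-responsive genes, a same-size background-behaved set, and the full
#' gene universe — enough to exercise over-representation and GSEA.
#'
#' @param annotation result of [generate_annotation()].
#' @param config the [synthetic_config()].
#' @return named list of gene-id vectors with a `description` attribute.
#' @export
generate_gene_sets <- function(annotation, config) {
  txs <- summarize_transcripts(annotation$exons)
  coding <- txs[txs$biotype == "coding", , drop = FALSE]
  gene_of <- setNames(coding$gene_id, coding$transcript_id)
  de_mrna <- intersect(config$planted_de$transcript_id, names(gene_of))
  de_genes <- sort(unique(gene_of[de_mrna]))
  other <- sort(setdiff(coding$gene_id, de_genes))
  sets <- list(
    stage_response = de_genes,
    unrelated = head(other, max(length(de_genes), 3)),
    all_genes = sort(unique(coding$gene_id))
  )
  attr(sets, "description") <- c(
    stage_response = "genes with planted stage effects",
    unrelated = "genes with no planted effect",
    all_genes = "whole coding-gene universe")
  sets
}

#' Generate a complete synthetic dataset
#'
#' Runs annotation, counts, sequences, coding-potential calls, gene sets
#' and qPCR generation; optionally writes everything to `outdir`
#' (GTF, TSV count matrices, design table, FASTA, GMT, truth ledgers).
#'
#' @param config a [synthetic_config()].
#' @param outdir optional output directory.
#' @return list: `annotation`, `truth`, `counts`, `sequences`, `calls`,
#'   `gene_sets`, `qpcr`, `config` (and `files` when written).
#' @export
generate_dataset <- function(config = synthetic_config(), outdir = NULL) {
  ann <- generate_annotation(config)
  counts <- generate_counts(ann, config)
  seqs <- generate_sequences(ann, config)
  calls <- generate_coding_potential_calls(ann)
  sets <- generate_gene_sets(ann, config)
  qpcr <- generate_qpcr(config)
  out <- list(annotation = ann, truth = ann$truth, counts = counts,
              sequences = seqs, calls = calls, gene_sets = sets,
              qpcr = qpcr, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(outdir, x)
    write_gtf(ann$exons, f("annotation.gtf"))
    write_tsv(counts$design, f("design.tsv"))
    write_matrix_tsv(counts$mrna_counts, f("counts_mrna.tsv"))
    write_matrix_tsv(counts$lncrna_counts, f("counts_lncrna.tsv"))
    write_matrix_tsv(counts$mirna_counts, f("counts_mirna.tsv"))
    write_tsv(data.frame(transcript_id = names(counts$lengths),
                         length = as.integer(counts$lengths)),
              f("lengths.tsv"))
    write_fasta(seqs$transcript_seqs, f("transcripts.fa"))
    write_fasta(seqs$mirna_seqs, f("mirnas.fa"))
    write_tsv(calls, f("coding_potential.tsv"))
    write_gmt(sets, f("gene_sets.gmt"))
    write_tsv(qpcr, f("qpcr.tsv"))
    write_tsv(ann$truth$class_of, f("truth_classes.tsv"))
    write_tsv(ann$truth$target_pairs, f("truth_target_pairs.tsv"))
    write_tsv(ann$truth$de_ids, f("truth_de.tsv"))
    write_tsv(ann$truth$triplets, f("truth_triplets.tsv"))
    out$files <- list.files(outdir, full.names = TRUE)
  }
  out
}
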