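# Synthetic-data generator: determinism, planted structure, NB moments,
# sequence screening and qPCR plates.

small_cfg <- function(seed = 5, ...) {
  synthetic_config(seed = seed, n_coding_genes = 30,
                   n_lncrna_per_class = 4, n_mirna = 8, ...)
}

test_that("identical config and seed give byte-identical outputs", {
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  a1 <- generate_annotation(small_cfg())
  a2 <- generate_annotation(small_cfg())
  write_gtf(a1$exons, f1)
  write_gtf(a2$exons, f2)
  expect_identical(readLines(f1), readLines(f2))

  c1 <- generate_counts(a1, small_cfg())
  c2 <- generate_counts(a2, small_cfg())
  expect_identical(c1, c2)

  s1 <- generate_sequences(a1, small_cfg())
  s2 <- generate_sequences(a2, small_cfg())
  expect_identical(s1, s2)

  c3 <- generate_counts(a1, small_cfg(seed = 6))
  expect_false(identical(c1$mrna_counts, c3$mrna_counts))
})

test_that("config validation catches bad inputs", {
  expect_error(synthetic_config(dispersion = -0.1), "dispersion")
  expect_error(synthetic_config(n_coding_genes = 4,
                                n_lncrna_per_class = 4), "host gene")
  expect_error(synthetic_config(
    design = data.frame(stage = c("IV", "IV"), n_replicates = 3)),
    "unique")
  expect_error(synthetic_config(
    design = data.frame(stage = c("IV", "V"), n_replicates = c(3, 1))),
    "replicates")
  # chromosome sizing error names the chromosome
  expect_error(generate_annotation(small_cfg(chrom_lengths = c(1e5, 1e9,
                                                               1e9))),
               "chr1 too short")
  # planted ids must exist
  cfg <- small_cfg()
  cfg$planted_de <- data.frame(transcript_id = "nope",
                               comparison = "IV_vs_V", log2fc = 2)
  expect_error(generate_annotation(cfg), "nope")
})

test_that("one lncRNA per class yields exactly the five classes", {
  cfg <- synthetic_config(seed = 1, n_coding_genes = 4,
                          n_lncrna_per_class = 1, n_mirna = 1)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$truth$class_of), 5)
  expect_setequal(ann$truth$class_of$positional_class,
                  c("intergenic", "bidirectional", "intronic", "antisense",
                    "sense_overlapping"))
})

test_that("null counts match NB moments (column sums within 5 sd)", {
  cfg <- small_cfg(
    dispersion = 0.05,
    planted_de = data.frame(transcript_id = character(0),
                            comparison = character(0), log2fc = numeric(0)),
    planted_triplets = data.frame(lncrna_id = character(0),
                                  mirna_id = character(0),
                                  mrna_id = character(0),
                                  beta = numeric(0)))
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(ann, cfg)
  all_counts <- rbind(cnt$mrna_counts, cnt$lncrna_counts, cnt$mirna_counts)
  n_tx <- nrow(all_counts)
  mu <- cfg$baseline_mean
  sd_colsum <- sqrt(n_tx * (mu + 0.05 * mu^2))
  expect_true(all(abs(colSums(all_counts) - n_tx * mu) < 5 * sd_colsum))
})

test_that("uncoupled miRNA-mRNA pairs have null Spearman correlation", {
  cfg <- synthetic_config(
    seed = 12, n_coding_genes = 25, n_lncrna_per_class = 4, n_mirna = 8,
    dispersion = 0.05,
    planted_de = data.frame(transcript_id = character(0),
                            comparison = character(0), log2fc = numeric(0)),
    planted_triplets = data.frame(lncrna_id = character(0),
                                  mirna_id = character(0),
                                  mrna_id = character(0),
                                  beta = numeric(0)))
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(ann, cfg)
  pairs <- expand.grid(m = rownames(cnt$mirna_counts),
                       t = rownames(cnt$mrna_counts))[1:200, ]
  scc <- vapply(seq_len(nrow(pairs)), function(i)
    cor(cnt$mirna_counts[pairs$m[i], ], cnt$mrna_counts[pairs$t[i], ],
        method = "spearman"), numeric(1))
  expect_lt(abs(median(scc)), 0.15)
})

test_that("planted seed sites exist and decoys are screened", {
  cfg <- small_cfg(seed = 31)
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(ann, cfg)
  trip <- cfg$planted_triplets
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  for (i in seq_len(nrow(trip))) {
    m <- chartr("U", "T", seqs$mirna_seqs[[trip$mirna_id[i]]])
    site8 <- paste0(rc(substr(m, 2, 8)), "A")
    expect_true(grepl(site8, seqs$transcript_seqs[[trip$lncrna_id[i]]],
                      fixed = TRUE))
    expect_true(grepl(site8, seqs$transcript_seqs[[trip$mrna_id[i]]],
                      fixed = TRUE))
  }
  # no decoy transcript carries a 7mer-m8 for any planted miRNA
  planted_mirs <- unique(trip$mirna_id)
  targets_of <- split(c(trip$lncrna_id, trip$mrna_id),
                      rep(trip$mirna_id, 2))
  for (m in planted_mirs) {
    pat <- rc(substr(chartr("U", "T", seqs$mirna_seqs[[m]]), 2, 8))
    hits <- names(seqs$transcript_seqs)[
      vapply(seqs$transcript_seqs, grepl, logical(1), pattern = pat,
             fixed = TRUE)]
    expect_true(all(hits %in% targets_of[[m]]))
  }
})

test_that("qPCR plates invert exactly at sigma 0 and on average with noise", {
  cfg <- small_cfg()
  plate <- generate_qpcr(cfg, sigma = 0)
  rq <- ddct_quantify(plate, "q_IV")
  folds <- cfg$qpcr$folds
  expect_equal(rq$rq[match(paste0("q_", names(folds)), rq$sample_id)],
               unname(folds))

  cfg$qpcr$n_replicates <- 100
  noisy <- generate_qpcr(cfg, sigma = 0.1)
  rqn <- ddct_quantify(noisy, "q_IV")
  planted <- folds[sub("q_", "", rqn$sample_id)]
  expect_true(all(abs(rqn$rq / planted - 1) < 0.05))
})

test_that("generate_dataset writes the documented artifact set", {
  outdir <- withr::local_tempdir()
  ds <- generate_dataset(small_cfg(), outdir)
  files <- basename(ds$files)
  expect_true(all(c("annotation.gtf", "design.tsv", "counts_mrna.tsv",
                    "counts_lncrna.tsv", "counts_mirna.tsv",
                    "transcripts.fa", "mirnas.fa", "coding_potential.tsv",
                    "gene_sets.gmt", "qpcr.tsv", "truth_classes.tsv",
                    "truth_triplets.tsv") %in% files))
  m <- read_matrix_tsv(file.path(outdir, "counts_mrna.tsv"))
  expect_identical(m, ds$counts$mrna_counts + 0)
})
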