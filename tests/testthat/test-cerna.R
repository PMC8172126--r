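# Seed matching, coexpression filters, sponge test and network assembly.

test_that("seed_match classifies canonical site types", {
  mir <- c(miR1 = "UGGAAUGUAAAGAAGUAUGUA")
  # 8mer site: reverse complement of positions 2-8 plus A
  tgt8 <- c(t8 = paste0("GGGCCC", "ACAUUCCA", "GGGCCC"))
  res <- seed_match(mir, tgt8)
  expect_equal(res$site_type, "8mer")

  # full reverse complement contains at least a 7mer-m8
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir[[1]]))))
  res2 <- seed_match(mir, c(trc = paste0("AAA", rc, "AAA")))
  expect_equal(nrow(res2), 1)
  expect_true(res2$site_type %in% c("8mer", "7mer-m8"))

  # 7mer-m8 without the A1 anchor
  tgt7 <- c(t7 = paste0("GGGCCC", "ACAUUCCG", "GGGCCC"))
  expect_equal(seed_match(mir, tgt7)$site_type, "7mer-m8")
  # 7mer-A1: positions 2-7 plus A
  tgtA1 <- c(tA1 = paste0("GGGCCC", "CAUUCCA", "GGGCCC"))
  expect_equal(seed_match(mir, tgtA1)$site_type, "7mer-A1")

  expect_error(seed_match(mir, c(bad = "ACGTXQ")), "non-IUPAC")
})

test_that("generated sequences yield exactly the planted candidates", {
  cfg <- synthetic_config(seed = 21, n_coding_genes = 30,
                          n_lncrna_per_class = 4, n_mirna = 8)
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(ann, cfg)
  lnc_ids <- ann$truth$class_of$transcript_id
  cand <- rbind(
    seed_match(seqs$mirna_seqs,
               seqs$transcript_seqs[names(seqs$transcript_seqs) %in% lnc_ids],
               "lncRNA"),
    seed_match(seqs$mirna_seqs,
               seqs$transcript_seqs[!names(seqs$transcript_seqs) %in% lnc_ids],
               "mRNA"))
  trip <- cfg$planted_triplets
  want <- c(paste(trip$mirna_id, trip$lncrna_id),
            paste(trip$mirna_id, trip$mrna_id))
  expect_setequal(paste(cand$mirna_id, cand$target_id), want)
  expect_true(all(cand$site_type == "8mer"))
})

test_that("Spearman filter is strict and matches the closed form", {
  samples <- paste0("s", 1:5)
  mir <- matrix(c(1, 2, 3, 4, 5), nrow = 1,
                dimnames = list("m1", samples))
  # rank pattern with rho exactly -0.7: y ranks (5, 4, 2, 1, 3)
  tgt <- rbind(exact = c(50, 40, 20, 10, 30),
               mono = c(9, 7, 5, 3, 1))
  colnames(tgt) <- samples
  cand <- data.frame(mirna_id = "m1", target_id = c("exact", "mono"),
                     target_kind = "mRNA")
  kept <- scc_filter(cand, mir, tgt, scc_max = -0.7)
  expect_equal(kept$target_id, "mono")   # -0.7 exactly is dropped
  expect_equal(kept$scc, -1)

  set.seed(4)
  x <- rnorm(12)
  y <- rnorm(12)
  got <- scc_filter(data.frame(mirna_id = "m1", target_id = "t1",
                               target_kind = "mRNA"),
                    matrix(x, 1, dimnames = list("m1", 1:12)),
                    matrix(y, 1, dimnames = list("t1", 1:12)),
                    scc_max = 2)$scc
  expect_equal(got, spearman_closed_form(x, y), tolerance = 1e-12)

  # constant series dropped with a message
  expect_message(
    out <- scc_filter(cand[1, ], mir,
                      matrix(rep(2, 5), 1,
                             dimnames = list("exact", samples))),
    "constant")
  expect_equal(nrow(out), 0)
})

test_that("Pearson filter keeps r > threshold strictly", {
  samples <- paste0("s", 1:8)
  set.seed(8)
  x <- rgamma(8, 3, scale = 40)
  y <- x * 1.5 + rgamma(8, 2, scale = 10)
  lnc <- matrix(x, 1, dimnames = list("L1", samples))
  mrna <- matrix(y, 1, dimnames = list("M1", samples))
  pairs <- data.frame(lncrna_id = "L1", mrna_id = "M1")
  r_ach <- cor(log2(x + 1), log2(y + 1))
  # threshold set to the achieved correlation: strict > drops the pair
  expect_equal(nrow(pcc_filter(pairs, lnc, mrna, pcc_min = r_ach)), 0)
  kept <- pcc_filter(pairs, lnc, mrna, pcc_min = r_ach - 1e-9)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$pcc, r_ach)

  anti <- matrix(max(y) - y, 1, dimnames = list("M1", samples))
  expect_equal(nrow(pcc_filter(pairs, lnc, anti, pcc_min = 0.9)), 0)
})

test_that("sponge test reproduces closed-form examples", {
  u <- sprintf("m%02d", 1:10)
  res <- sponge_test(u[1:4], u[c(1, 2, 3, 5, 6)], u)
  expect_equal(res$k, 3)
  expect_equal(res$pvalue, 66 / 252, tolerance = 1e-12)

  res0 <- sponge_test(u[1:4], u[5:8], u)
  expect_equal(res0$k, 0)
  expect_equal(res0$pvalue, 1)

  resM <- sponge_test(u, u, u)
  expect_equal(resM$k, 10)
  expect_equal(resM$pvalue, 1)

  expect_error(sponge_test(u[1:2], u[1:2], character(0)), "empty")
  expect_error(sponge_test(c(u, "zz"), u, u), "universe")
})

# a minimal world with one genuine triplet and one broken one
minimal_network_inputs <- function() {
  samples <- paste0("s", 1:10)
  z <- 1:10
  lnc <- matrix(c(2 * z, rep(c(5, 9), 5)), nrow = 2, byrow = TRUE,
                dimnames = list(c("L1", "L2"), samples))
  mrna <- matrix(c(2 * z + 3, rep(c(8, 3), 5)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("M1", "M2"), samples))
  cand <- data.frame(
    mirna_id = c("m01", "m01"),
    target_id = c("L1", "M1"),
    target_kind = c("lncRNA", "mRNA"),
    scc = c(-0.95, -0.9))
  list(cand = cand, lnc = lnc, mrna = mrna,
       universe = sprintf("m%02d", 1:40))
}

test_that("a surviving triplet forms a 3-node, 3-edge network", {
  w <- minimal_network_inputs()
  net <- build_cerna_network(w$cand, w$lnc, w$mrna,
                             mirna_universe = w$universe)
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$edges$relation,
                  c("lncRNA-miRNA", "miRNA-mRNA", "lncRNA-mRNA"))
  # certification invariant: the lncRNA-mRNA edge has its shared miRNA
  lm <- net$edges[net$edges$relation == "lncRNA-mRNA", ]
  mir <- net$edges$to[net$edges$relation == "lncRNA-miRNA" &
                      net$edges$from == lm$from]
  expect_true(any(net$edges$relation == "miRNA-mRNA" &
                  net$edges$from %in% mir & net$edges$to == lm$to))
  # sponge arithmetic: k=K=n=1 of M=40
  expect_equal(net$pairs$pvalue, 1 / 40, tolerance = 1e-12)
})

test_that("removing the shared miRNA removes the lncRNA-mRNA edge", {
  w <- minimal_network_inputs()
  expect_warning(
    net <- build_cerna_network(w$cand[w$cand$target_id != "L1", ],
                               w$lnc, w$mrna, mirna_universe = w$universe),
    "empty ceRNA network")
  expect_equal(nrow(net$edges), 0)
})

test_that("network exports are readable (SIF lines, GraphML via igraph)", {
  w <- minimal_network_inputs()
  net <- build_cerna_network(w$cand, w$lnc, w$mrna,
                             mirna_universe = w$universe)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, sif)
  expect_equal(length(readLines(sif)), nrow(net$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "kind"), net$nodes$kind)
})
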