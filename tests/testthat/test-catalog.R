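# Novelty filter, consensus lncRNA call and positional classification.

test_that("novelty filter applies the length/exon rule at its boundaries", {
  ex <- make_exons(list(
    list(id = "keep_boundary", exons = list(c(1, 100), c(201, 300))),
    list(id = "short", exons = list(c(1, 66), c(101, 166), c(201, 267))),
    list(id = "monoexonic", exons = list(c(1, 5000)))))
  s <- summarize_transcripts(ex)
  expect_equal(s$length[s$transcript_id == "keep_boundary"], 200)
  expect_equal(s$length[s$transcript_id == "short"], 199)

  kept <- unique(filter_novel_transcripts(ex)$transcript_id)
  expect_equal(kept, "keep_boundary")

  # the stricter "more than 2 exons" reading drops the 2-exon transcript
  expect_equal(nrow(filter_novel_transcripts(ex, min_exons = 3)), 0)
})

test_that("consensus call keeps the noncoding intersection only", {
  calls <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    cnci_noncoding = c(TRUE, TRUE, FALSE, TRUE),
    cpc_noncoding = c(TRUE, FALSE, TRUE, TRUE),
    swissprot_hit = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(consensus_lncrna_call(calls), "a")
  expect_equal(consensus_lncrna_call(calls[0, ]), character(0))
  expect_error(consensus_lncrna_call(rbind(calls, calls[1, ])),
               "duplicate")
})

# geometry fixtures around a three-exon gene at anchor a = 100000
catalog_cases <- function(a = 100000) {
  list(
    intronic_same = list(id = "L_int_s", strand = "+",
                         exons = list(c(a + 3000, a + 3400),
                                      c(a + 4200, a + 4800))),
    intronic_opp = list(id = "L_int_o", strand = "-",
                        exons = list(c(a + 3000, a + 3400),
                                     c(a + 4200, a + 4800))),
    antisense = list(id = "L_as", strand = "-",
                     exons = list(c(a + 20500, a + 21400),
                                  c(a + 22000, a + 22300))),
    sense_ov = list(id = "L_so", strand = "+",
                    exons = list(c(a - 2500, a - 2000),
                                 c(a - 1200, a + 200))),
    bidir = list(id = "L_bid", strand = "-",
                 exons = list(c(a - 1600, a - 1200), c(a - 900, a - 501))),
    intergenic = list(id = "L_far", strand = "+",
                      exons = list(c(a + 500000, a + 500400),
                                   c(a + 501000, a + 501400))),
    other = list(id = "L_other", strand = "+",
                 exons = list(c(a + 1500, a + 1900),
                              c(a + 21500, a + 21900))))
}

test_that("each positional class is assigned by its rule", {
  gene <- fixture_gene(a = 100000, strand = "+")
  lnc <- make_exons(catalog_cases(), biotype = "lncRNA")
  cl <- classify_lncrnas(lnc, gene)
  got <- setNames(cl$positional_class, cl$transcript_id)
  expect_equal(got[["L_int_s"]], "intronic")
  expect_equal(got[["L_int_o"]], "intronic")   # any strand
  expect_equal(got[["L_as"]], "antisense")
  expect_equal(got[["L_so"]], "sense_overlapping")
  expect_equal(got[["L_bid"]], "bidirectional")
  expect_equal(got[["L_far"]], "intergenic")
  # same-strand overlap touching only introns falls through to "other":
  # L_other's second exon overlaps intron 2 but also gene exon 2? no --
  # c(21500, 21900) sits in intron 2 (21001..39999 + a)
  expect_equal(got[["L_other"]], "other")
  expect_equal(cl$partner_gene_id[cl$transcript_id == "L_bid"], "gA")
  expect_equal(cl$partner_distance_bp[cl$transcript_id == "L_bid"], 501)
})

test_that("the bidirectional window is an inclusive <= bound", {
  gene <- fixture_gene(a = 100000, strand = "+")
  at_window <- make_exons(list(list(
    id = "L1", strand = "-",
    exons = list(c(97500, 98000), c(98500, 99000)))), "lncRNA")
  # TSS (right end) at 99000, gene TSS 100000: distance exactly 1000
  expect_equal(classify_lncrnas(at_window, gene)$positional_class,
               "bidirectional")
  past_window <- make_exons(list(list(
    id = "L2", strand = "-",
    exons = list(c(97499, 97999), c(98499, 98999)))), "lncRNA")
  expect_equal(classify_lncrnas(past_window, gene)$positional_class,
               "intergenic")
  # same-strand (tandem) neighbor within the window is not bidirectional
  tandem <- make_exons(list(list(
    id = "L3", strand = "+",
    exons = list(c(99000, 99300), c(99500, 99900)))), "lncRNA")
  expect_equal(classify_lncrnas(tandem, gene)$positional_class,
               "intergenic")
})

test_that("classification is total and invariant to gene input order", {
  genes <- rbind(fixture_gene("gA", a = 100000, strand = "+"),
                 fixture_gene("gB", a = 900000, strand = "-"))
  lnc <- make_exons(catalog_cases(), biotype = "lncRNA")
  cl1 <- classify_lncrnas(lnc, genes)
  expect_true(all(cl1$positional_class %in%
    c("intergenic", "bidirectional", "intronic", "antisense",
      "sense_overlapping", "other")))
  expect_false(anyDuplicated(cl1$transcript_id) > 0)

  shuffled <- genes[rev(seq_len(nrow(genes))), ]
  cl2 <- classify_lncrnas(lnc, shuffled)
  expect_equal(cl1, cl2)
})

test_that("novelty filtering and classification commute", {
  gene <- fixture_gene(a = 100000)
  cases <- c(catalog_cases(),
             list(short = list(id = "L_short", strand = "+",
                               exons = list(c(500000, 500050),
                                            c(500100, 500150)))))
  lnc <- make_exons(cases, biotype = "lncRNA")
  filtered <- filter_novel_transcripts(lnc)
  a <- classify_lncrnas(filtered, gene)
  b <- classify_lncrnas(lnc, gene)
  b <- b[b$transcript_id %in% unique(filtered$transcript_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("planted classes from the generator are recovered exactly", {
  cfg <- synthetic_config(seed = 7, n_coding_genes = 8,
                          n_lncrna_per_class = 2, n_mirna = 2)
  ann <- generate_annotation(cfg)
  lnc <- ann$exons[ann$exons$biotype == "lncRNA", ]
  gen <- ann$exons[ann$exons$biotype == "coding", ]
  cl <- classify_lncrnas(lnc, gen)
  truth <- ann$truth$class_of
  m <- merge(cl, truth, by = "transcript_id")
  expect_equal(nrow(m), nrow(truth))
  expect_identical(m$positional_class.x, m$positional_class.y)
})

test_that("build_lncrna_catalog wires filter, consensus and classifier", {
  cfg <- synthetic_config(seed = 7, n_coding_genes = 8,
                          n_lncrna_per_class = 2, n_mirna = 2)
  ann <- generate_annotation(cfg)
  calls <- generate_coding_potential_calls(ann)
  cat_df <- build_lncrna_catalog(ann$exons, calls)
  expect_setequal(cat_df$transcript_id, ann$truth$class_of$transcript_id)
})
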