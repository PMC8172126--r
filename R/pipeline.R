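# End-to-end orchestration: synthetic data -> lncRNA catalog -> differential
# expression -> enrichment -> target prediction -> ceRNA network -> report.

#' Pipeline configuration
#'
#' Collects every stage threshold (the printed gates: FDR < 0.05, FC >= 2,
#' miRNA p < 0.05, cis window < 100 kb, trans |r| >= 0.9, SCC < -0.7,
#' PCC > 0.9, sponge p < 0.05, GSEA |NES| > 1 / p < 0.05 / q < 0.25) plus
#' the synthetic-data block and seed.
#'
#' @param seed integer seed, forwarded to the synthetic block.
#' @param synthetic a [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param fdr_max,fc_min,mirna_p_max differential-expression gates.
#' @param min_length,min_exons novelty filter.
#' @param bidirectional_window_bp classifier window.
#' @param cis_window_bp,trans_r_min target-prediction thresholds.
#' @param scc_max,pcc_min,sponge_p_max ceRNA thresholds.
#' @param gsea list: `n_perm`, `weight`, `min_size`, `max_size`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            synthetic = synthetic_config(seed = seed),
                            fdr_max = 0.05, fc_min = 2, mirna_p_max = 0.05,
                            min_length = 200, min_exons = 2,
                            bidirectional_window_bp = 1000,
                            cis_window_bp = 100000, trans_r_min = 0.9,
                            scc_max = -0.7, pcc_min = 0.9,
                            sponge_p_max = 0.05,
                            gsea = list(n_perm = 1000, weight = 1,
                                        min_size = 3, max_size = 500)) {
  synthetic$seed <- as.integer(seed)
  stopifnot(fdr_max > 0, fdr_max <= 1, fc_min >= 1, mirna_p_max > 0,
            cis_window_bp > 0, trans_r_min >= 0, trans_r_min <= 1,
            scc_max >= -1, scc_max <= 1, sponge_p_max > 0)
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 fdr_max = fdr_max, fc_min = fc_min,
                 mirna_p_max = mirna_p_max, min_length = min_length,
                 min_exons = min_exons,
                 bidirectional_window_bp = bidirectional_window_bp,
                 cis_window_bp = cis_window_bp, trans_r_min = trans_r_min,
                 scc_max = scc_max, pcc_min = pcc_min,
                 sponge_p_max = sponge_p_max, gsea = gsea),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Flat keys mirror [pipeline_config()] arguments; a `synthetic` block maps
#' to [synthetic_config()] arguments (scalar fields only).
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn_args <- js$synthetic %||% list()
  syn <- do.call(synthetic_config,
                 c(syn_args, list(seed = js$seed %||% 1)))
  args <- js[setdiff(names(js), c("synthetic"))]
  do.call(pipeline_config, c(args, list(synthetic = syn)))
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: synthetic data, lncRNA catalog, FPKM +
#' differential expression (per consecutive stage pair; FDR gate for
#' mRNA/lncRNA, p gate for miRNA), hypergeometric over-representation and
#' GSEA, antisense/cis/trans target prediction, ceRNA network, qPCR
#' quantification. All artifacts are written under `outdir`; a
#' machine-readable run report (JSON, deterministic for a given config and
#' seed) and a log with stage timers are produced.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return the run report, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  cat(sprintf("lncnet %s pipeline, seed %d\n",
              as.character(packageVersion("lncnet")), config$seed),
      file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg(sprintf("stage %-10s done in %.2fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  report <- list(package = "lncnet",
                 version = as.character(packageVersion("lncnet")),
                 seed = config$seed,
                 thresholds = config[setdiff(names(config),
                                             c("synthetic", "seed"))])

  syn_dir <- file.path(outdir, "synthetic")
  ds <- stage("synth", generate_dataset(config$synthetic, syn_dir))
  report$synthetic <- list(
    n_transcripts = nrow(summarize_transcripts(ds$annotation$exons)),
    n_samples = nrow(ds$counts$design))

  cat_dir <- file.path(outdir, "catalog")
  dir.create(cat_dir, showWarnings = FALSE)
  catalog <- stage("catalog", {
    exons <- read_gtf(file.path(syn_dir, "annotation.gtf"))
    cat_df <- build_lncrna_catalog(
      exons, ds$calls, min_length = config$min_length,
      min_exons = config$min_exons,
      bidirectional_window_bp = config$bidirectional_window_bp)
    write_tsv(cat_df, file.path(cat_dir, "lncrna_catalog.tsv"))
    cat_df
  })
  report$catalog <- list(
    n_lncrna = nrow(catalog),
    per_class = as.list(table(catalog$positional_class)))

  expr_dir <- file.path(outdir, "expression")
  dir.create(expr_dir, showWarnings = FALSE)
  de <- stage("de", {
    design <- ds$counts$design
    stages <- unique(design$stage)
    # FPKM against the full library (all kinds pooled), as per-sample
    # mapped-fragment totals would be in a real run
    all_counts <- rbind(ds$counts$mrna_counts, ds$counts$lncrna_counts,
                        ds$counts$mirna_counts)
    all_fpkm <- compute_fpkm(all_counts, ds$counts$lengths)
    fp <- lapply(list(mrna = ds$counts$mrna_counts,
                      lncrna = ds$counts$lncrna_counts,
                      mirna = ds$counts$mirna_counts),
                 function(m) all_fpkm[rownames(m), , drop = FALSE])
    for (kind in names(fp)) {
      write_matrix_tsv(fp[[kind]],
                       file.path(expr_dir, paste0("fpkm_", kind, ".tsv")))
    }
    tabs <- list()
    for (i in seq_len(length(stages) - 1)) {
      a <- stages[i]; b <- stages[i + 1]
      for (kind in names(fp)) {
        rec <- run_de(fp[[kind]], design, a, b,
                      fc_min = config$fc_min, fdr_max = config$fdr_max,
                      use_pvalue = kind == "mirna",
                      p_max = config$mirna_p_max)
        rec$kind <- kind
        tabs[[paste(kind, a, b)]] <- rec
      }
    }
    de_all <- do.call(rbind, tabs)
    rownames(de_all) <- NULL
    write_tsv(de_all, file.path(expr_dir, "de_records.tsv"))
    list(fpkm = fp, records = de_all)
  })
  de_counts <- lapply(split(de$records,
                            paste(de$records$kind, de$records$comparison)),
                      function(d) list(up = sum(d$status == "up"),
                                       down = sum(d$status == "down")))
  report$de <- de_counts

  enr_dir <- file.path(outdir, "enrichment")
  dir.create(enr_dir, showWarnings = FALSE)
  enrich <- stage("enrichment", {
    txs <- summarize_transcripts(ds$annotation$exons)
    gene_of <- setNames(txs$gene_id, txs$transcript_id)
    de_m <- de$records[de$records$kind == "mrna" &
                       de$records$status != "ns", ]
    de_genes <- sort(unique(gene_of[de_m$transcript_id]))
    background <- sort(unique(txs$gene_id[txs$biotype == "coding"]))
    ora <- ora_hypergeometric(de_genes, background, ds$gene_sets)
    write_tsv(ora, file.path(enr_dir, "ora.tsv"))
    # GSEA at gene level (one transcript per gene in the synthetic world)
    gfpkm <- de$fpkm$mrna
    rownames(gfpkm) <- unname(gene_of[rownames(gfpkm)])
    stages <- unique(ds$counts$design$stage)
    gsea_tabs <- list()
    for (i in seq_len(length(stages) - 1)) {
      g <- gsea_permutation(gfpkm, ds$counts$design, ds$gene_sets,
                            stages[i], stages[i + 1],
                            n_perm = config$gsea$n_perm,
                            seed = config$seed,
                            weight = config$gsea$weight,
                            min_size = config$gsea$min_size,
                            max_size = config$gsea$max_size)
      g$comparison <- paste0(stages[i], "_vs_", stages[i + 1])
      gsea_tabs[[i]] <- g
    }
    gsea <- do.call(rbind, gsea_tabs)
    write_tsv(gsea, file.path(enr_dir, "gsea.tsv"))
    list(ora = ora, gsea = gsea)
  })
  report$enrichment <- list(
    n_sets_tested = nrow(enrich$ora),
    ora_significant = sum(enrich$ora$pvalue < 0.05),
    gsea_significant = sum(enrich$gsea$significant))

  tgt_dir <- file.path(outdir, "targets")
  dir.create(tgt_dir, showWarnings = FALSE)
  targets <- stage("targets", {
    exons <- ds$annotation$exons
    lnc_ex <- exons[exons$transcript_id %in% catalog$transcript_id, ]
    gene_ex <- exons[exons$biotype == "coding", ]
    res <- list(
      antisense = antisense_pairs(lnc_ex, gene_ex),
      cis = cis_pairs(lnc_ex, gene_ex, window_bp = config$cis_window_bp),
      trans = trans_pairs(de$fpkm$lncrna, de$fpkm$mrna,
                          r_min = config$trans_r_min))
    for (nm in names(res)) {
      write_tsv(res[[nm]], file.path(tgt_dir, paste0(nm, "_pairs.tsv")))
    }
    res
  })
  report$targets <- lapply(targets, nrow)

  cer_dir <- file.path(outdir, "cerna")
  dir.create(cer_dir, showWarnings = FALSE)
  net <- stage("cerna", {
    lnc_ids <- catalog$transcript_id
    cand <- rbind(
      seed_match(ds$sequences$mirna_seqs,
                 ds$sequences$transcript_seqs[
                   names(ds$sequences$transcript_seqs) %in% lnc_ids],
                 target_kind = "lncRNA"),
      seed_match(ds$sequences$mirna_seqs,
                 ds$sequences$transcript_seqs[
                   !names(ds$sequences$transcript_seqs) %in% lnc_ids],
                 target_kind = "mRNA"))
    de_ids <- unique(de$records$transcript_id[de$records$status != "ns"])
    cand <- cand[cand$target_id %in% de_ids & cand$mirna_id %in% de_ids, ]
    write_tsv(cand, file.path(cer_dir, "candidates.tsv"))
    # universe: all expressed miRNAs (the DE-filtered candidate universe
    # degenerates at demo scale; see the methods vignette)
    universe <- rownames(de$fpkm$mirna)
    target_expr <- rbind(de$fpkm$lncrna, de$fpkm$mrna)
    surv <- if (nrow(cand)) {
      scc_filter(cand, de$fpkm$mirna, target_expr, scc_max = config$scc_max)
    } else cand
    network <- build_cerna_network(surv, de$fpkm$lncrna, de$fpkm$mrna,
                                   mirna_universe = universe,
                                   pcc_min = config$pcc_min,
                                   sponge_p_max = config$sponge_p_max)
    write_tsv(network$nodes, file.path(cer_dir, "nodes.tsv"))
    write_tsv(network$edges, file.path(cer_dir, "edges.tsv"))
    write_tsv(network$pairs, file.path(cer_dir, "sponge_pairs.tsv"))
    export_sif(network, file.path(cer_dir, "network.sif"))
    export_graphml(network, file.path(cer_dir, "network.graphml"))
    network
  })
  report$cerna <- list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                       n_pairs = nrow(net$pairs))

  qpcr_dir <- file.path(outdir, "qpcr")
  dir.create(qpcr_dir, showWarnings = FALSE)
  rq <- stage("qpcr", {
    cal <- paste0("q_", config$synthetic$qpcr$calibrator)
    r <- ddct_quantify(ds$qpcr, cal)
    write_tsv(r, file.path(qpcr_dir, "relative_quantity.tsv"))
    r
  })
  report$qpcr <- list(n_samples = nrow(rq))

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c(sprintf("lncnet pipeline report (seed %d)", config$seed),
           sprintf("transcripts: %d", report$synthetic$n_transcripts),
           sprintf("lncRNAs: %d (%s)", report$catalog$n_lncrna,
                   paste(names(report$catalog$per_class),
                         unlist(report$catalog$per_class),
                         sep = "=", collapse = ", ")),
           vapply(names(report$de), function(k)
             sprintf("DE %s: up %d / down %d", k, report$de[[k]]$up,
                     report$de[[k]]$down), character(1)),
           sprintf("ORA significant sets (p<0.05): %d / %d",
                   report$enrichment$ora_significant,
                   report$enrichment$n_sets_tested),
           sprintf("GSEA significant sets: %d",
                   report$enrichment$gsea_significant),
           sprintf("target pairs: antisense %d, cis %d, trans %d",
                   report$targets$antisense, report$targets$cis,
                   report$targets$trans),
           sprintf("ceRNA network: %d nodes, %d edges",
                   report$cerna$n_nodes, report$cerna$n_edges))
  writeLines(txt, file.path(outdir, "run_report.txt"))
  logmsg("pipeline complete")
  invisible(report)
}
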