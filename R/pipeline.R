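# Pipeline orchestration: each stage reads its upstream artifacts from the
# output directory, runs one module, and writes deterministically ordered
# TSV/JSON artifacts plus a JSON-lines log entry carrying the config hash,
# RNG seed and input checksums. Reruns with the same config and seed are
# byte-identical.

PIPELINE_STAGES <- c("simulate", "quantify", "differential", "link", "grn",
                     "hierarchy", "disease", "de", "gsea", "motif")

stage_requirements <- list(
  simulate = character(),
  quantify = c("catalogue.bed", "counts_ATAC.tsv"),
  differential = c("normalized_ATAC.tsv", "counts_ATAC.tsv", "samples.tsv"),
  link = c("catalogue.bed", "genes.tsv", "normalized_ATAC.tsv"),
  grn = c("catalogue.bed", "genes.tsv", "normalized_ATAC.tsv",
          "normalized_H3K27ac.tsv", "motif_hits.tsv",
          "expression_counts.tsv", "samples.tsv"),
  hierarchy = c("network_A.json", "network_B.json", "network_REF.json"),
  disease = c("tf_peaks", "genes.tsv", "disease_genes.txt"),
  de = c("expression_counts.tsv", "samples.tsv", "genes.tsv"),
  gsea = c("de_A_vs_B.tsv", "program_A_genes.txt"),
  motif = c("motif_hits.tsv", "differential_cres.tsv", "de_A_vs_B.tsv",
            "expression_counts.tsv")
)

stage_provider <- c(
  catalogue.bed = "simulate", counts_ATAC.tsv = "simulate",
  samples.tsv = "simulate", genes.tsv = "simulate",
  motif_hits.tsv = "simulate", expression_counts.tsv = "simulate",
  disease_genes.txt = "simulate", tf_peaks = "simulate",
  program_A_genes.txt = "simulate",
  normalized_ATAC.tsv = "quantify", normalized_H3K27ac.tsv = "quantify",
  differential_cres.tsv = "differential",
  network_A.json = "grn", network_B.json = "grn", network_REF.json = "grn",
  de_A_vs_B.tsv = "de"
)

check_stage_inputs <- function(stage, out_dir) {
  req <- stage_requirements[[stage]]
  missing <- req[!file.exists(file.path(out_dir, req))]
  if (length(missing)) {
    first <- stage_provider[missing[1L]]
    stop("stage '", stage, "' is missing artifact '", missing[1L],
         "'; run stage '", first, "' first")
  }
  invisible(TRUE)
}

log_stage <- function(out_dir, stage, cfg, seed, inputs = character()) {
  sums <- if (length(inputs)) {
    paths <- file.path(out_dir, inputs)
    paths <- paths[file.exists(paths) & !dir.exists(paths)]
    as.list(tools::md5sum(paths))
  } else list()
  entry <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                config_hash = config_hash(cfg), seed = seed,
                input_md5 = sums)
  cat(as.character(jsonlite::toJSON(entry, auto_unbox = TRUE)), "\n",
      sep = "", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order (`simulate`,
#' `quantify`, `differential`, `link`, `grn`, `hierarchy`, `disease`,
#' `de`, `gsea`, `motif`), each writing its artifacts into `out_dir`. A
#' stage whose upstream artifact is missing raises an error naming the
#' stage to run first. Reruns with identical config and seed produce
#' byte-identical numeric artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param stages subset of stages to run (default: all).
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] used by the `simulate` stage; its
#'   `rng_seed` is overridden by `cfg$rng_seed`.
#' @return invisibly, the vector of stages run.
#' @export
run_pipeline <- function(cfg = pipeline_config(), stages = PIPELINE_STAGES,
                         out_dir = "regcircuit_out",
                         sim = sim_config()) {
  validate_config(cfg)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in stages) {
    check_stage_inputs(stage, out_dir)
    fun <- get(paste0("stage_", stage), mode = "function")
    fun(cfg, out_dir, sim)
    log_stage(out_dir, stage, cfg, cfg$rng_seed, stage_requirements[[stage]])
  }
  invisible(stages)
}

marks4 <- c("ATAC", "H3K4me3", "H3K27ac", "H3K27me3")

stage_simulate <- function(cfg, out_dir, sim) {
  sim$rng_seed <- cfg$rng_seed
  land <- simulate_landscape(sim)
  expr <- simulate_expression(sim, land$truth)
  pk <- simulate_tf_peaks(sim, land)
  g <- land$genes
  write_table_tsv(g[, .(gene, chrom, start, end, strand)],
                  file.path(out_dir, "genes.tsv"))
  fwrite(land$catalogue[, .(chrom, start = summit, end = summit + 1L,
                            name = cre, score = 0, strand = ".")],
         file.path(out_dir, "catalogue.bed"), sep = "\t", col.names = FALSE)
  for (mk in marks4)
    write_matrix_tsv(land$counts[[mk]]$values,
                     file.path(out_dir, paste0("counts_", mk, ".tsv")),
                     id_col = "cre")
  write_matrix_tsv(land$motif_hits, file.path(out_dir, "motif_hits.tsv"),
                   id_col = "cre")
  write_matrix_tsv(expr$counts, file.path(out_dir, "expression_counts.tsv"),
                   id_col = "gene")
  write_matrix_tsv(expr$tpm, file.path(out_dir, "expression_tpm.tsv"),
                   id_col = "gene")
  write_table_tsv(expr$samples, file.path(out_dir, "samples.tsv"))
  write_gene_list(pk$disease_genes, file.path(out_dir, "disease_genes.txt"))
  prog_a <- unique(land$truth$edges[label == "A-specific", target])
  write_gene_list(prog_a, file.path(out_dir, "program_A_genes.txt"))
  pk_dir <- file.path(out_dir, "tf_peaks")
  dir.create(pk_dir, showWarnings = FALSE)
  for (tf in names(pk$tf_peaks))
    write_table_tsv(pk$tf_peaks[[tf]],
                    file.path(pk_dir, paste0(tf, ".tsv")))
  writeLines(pk$disease_tf, file.path(out_dir, "disease_tf.txt"))
  truth <- land$truth
  write_json_artifact(list(
    cre_labels = truth$cre_labels, tf_classes = truth$tf_classes,
    edges = truth$edges, n_differential_per_mark = truth$n_differential_per_mark,
    disease_genes = pk$disease_genes, disease_tf = pk$disease_tf),
    file.path(out_dir, "ground_truth.json"))
  invisible(NULL)
}

read_states <- function(out_dir) {
  s <- read_table_tsv(file.path(out_dir, "samples.tsv"))
  setNames(s$state, s$sample)
}

load_mark <- function(out_dir, mk, normalized = FALSE, states = NULL) {
  f <- file.path(out_dir, paste0(if (normalized) "normalized_" else "counts_",
                                 mk, ".tsv"))
  signal_matrix(read_matrix_tsv(f), mark = mk,
                window = c(ATAC = 200L, H3K4me3 = 2000L, H3K27ac = 2000L,
                           H3K27me3 = 5000L)[[mk]],
                normalized = normalized, states = states)
}

read_catalogue <- function(out_dir) {
  b <- fread(file.path(out_dir, "catalogue.bed"), header = FALSE)
  setnames(b, 1:6, c("chrom", "start", "end", "name", "score", "strand"))
  data.table(cre = b$name, chrom = b$chrom, summit = b$start)
}

stage_quantify <- function(cfg, out_dir, sim) {
  for (mk in marks4) {
    sm <- load_mark(out_dir, mk)
    norm <- normalize_signal(sm)
    write_matrix_tsv(norm$values,
                     file.path(out_dir, paste0("normalized_", mk, ".tsv")),
                     id_col = "cre")
  }
  invisible(NULL)
}

stage_differential <- function(cfg, out_dir, sim) {
  states <- read_states(out_dir)
  tabs <- list()
  for (mk in c("ATAC", "H3K27ac")) {
    sm <- load_mark(out_dir, mk, states = states)
    tabs[[mk]] <- differential_count_test(
      sm, padj_threshold = cfg$cre_padj_threshold)
  }
  for (mk in c("H3K4me3", "H3K27me3")) {
    sm <- load_mark(out_dir, mk, normalized = TRUE, states = states)
    tabs[[mk]] <- threshold_variance_select(
      sm, activity_cutoff = cfg$activity_cutoff,
      variance_quantile = cfg$variance_select_quantile)
  }
  all_tab <- rbindlist(tabs)
  setorder(all_tab, mark, cre)
  write_table_tsv(all_tab, file.path(out_dir, "differential_cres.tsv"))
  frac <- differential_cre_fraction(tabs, nrow(read_catalogue(out_dir)))
  write_json_artifact(frac, file.path(out_dir, "differential_summary.json"))
  invisible(NULL)
}

stage_link <- function(cfg, out_dir, sim) {
  catalogue <- read_catalogue(out_dir)
  genes <- gene_annotation(read_table_tsv(file.path(out_dir, "genes.tsv")))
  links <- link_closest_tss(catalogue, genes, cfg$promoter_link_max_bp)
  write_table_tsv(links, file.path(out_dir, "links_promoter.tsv"))
  wf <- weight_function(cfg$full_weight_radius_bp,
                        cfg$half_weight_distance_bp, cfg$enhancer_window_bp)
  for (mk in marks4) {
    sm <- load_mark(out_dir, mk, normalized = TRUE)
    agg <- aggregate_enhancer_signal(catalogue, sm, genes, wf)
    write_matrix_tsv(agg$summary,
                     file.path(out_dir, paste0("gene_summary_", mk, ".tsv")),
                     id_col = "gene")
  }
  invisible(NULL)
}

grn_networks_from_artifacts <- function(cfg, out_dir) {
  states <- read_states(out_dir)
  catalogue <- read_catalogue(out_dir)
  genes <- gene_annotation(read_table_tsv(file.path(out_dir, "genes.tsv")))
  activity <- list(ATAC = load_mark(out_dir, "ATAC", TRUE, states),
                   H3K27ac = load_mark(out_dir, "H3K27ac", TRUE, states))
  hits <- read_matrix_tsv(file.path(out_dir, "motif_hits.tsv"))
  wf <- weight_function(cfg$full_weight_radius_bp,
                        cfg$half_weight_distance_bp, cfg$enhancer_window_bp)
  nets <- lapply(c(A = "A", B = "B", REF = "REF"), function(st)
    build_binding_network(hits, activity, catalogue, genes, st, states, wf))
  list(nets = nets, genes = genes, states = states, hits = hits)
}

stage_grn <- function(cfg, out_dir, sim) {
  ctx <- grn_networks_from_artifacts(cfg, out_dir)
  for (st in names(ctx$nets))
    write_json_artifact(ctx$nets[[st]]$edges,
                        file.path(out_dir, paste0("network_", st, ".json")))
  counts <- read_matrix_tsv(file.path(out_dir, "expression_counts.tsv"))
  meta <- read_table_tsv(file.path(out_dir, "samples.tsv"))
  filt <- filter_genes(counts, min_counts = cfg$min_gene_counts)
  de_a <- de_test(filt, setNames(meta$state, meta$sample)[colnames(filt)],
                  state_a = "A", state_b = "REF",
                  padj_threshold = cfg$de_padj_threshold,
                  lfc_threshold = cfg$de_abs_log2fc_threshold)
  de_b <- de_test(filt, setNames(meta$state, meta$sample)[colnames(filt)],
                  state_a = "B", state_b = "REF",
                  padj_threshold = cfg$de_padj_threshold,
                  lfc_threshold = cfg$de_abs_log2fc_threshold)
  infl_a <- differential_influence(ctx$nets$REF, ctx$nets$A, de_a,
                                   max_edges = cfg$max_differential_edges,
                                   de_padj_threshold = cfg$de_padj_threshold)
  infl_b <- differential_influence(ctx$nets$REF, ctx$nets$B, de_b,
                                   max_edges = cfg$max_differential_edges,
                                   de_padj_threshold = cfg$de_padj_threshold)
  write_table_tsv(infl_a, file.path(out_dir, "influence_REF_A.tsv"))
  write_table_tsv(infl_b, file.path(out_dir, "influence_REF_B.tsv"))
  cls <- classify_tfs(infl_a, infl_b, cfg$influence_shared_threshold,
                      cfg$influence_low_threshold)
  write_table_tsv(cls, file.path(out_dir, "tf_classification.tsv"))
  invisible(NULL)
}

stage_hierarchy <- function(cfg, out_dir, sim) {
  nets <- lapply(c(A = "A", B = "B", REF = "REF"), function(st) {
    e <- as.data.table(read_json_artifact(
      file.path(out_dir, paste0("network_", st, ".json"))))
    structure(list(state = st, edges = e), class = "binding_network")
  })
  tfs <- read_matrix_tsv(file.path(out_dir, "motif_hits.tsv"))
  hier <- classify_edge_regulation(nets$REF, nets$A, nets$B,
                                   tfs = colnames(tfs))
  write_table_tsv(hier, file.path(out_dir, "hierarchy_edges.tsv"))
  invisible(NULL)
}

stage_disease <- function(cfg, out_dir, sim) {
  genes <- gene_annotation(read_table_tsv(file.path(out_dir, "genes.tsv")))
  pk_dir <- file.path(out_dir, "tf_peaks")
  files <- list.files(pk_dir, pattern = "\\.tsv$", full.names = TRUE)
  tf_peaks <- lapply(files, read_table_tsv)
  names(tf_peaks) <- sub("\\.tsv$", "", basename(files))
  lists <- list(disease = read_gene_list(file.path(out_dir,
                                                   "disease_genes.txt")))
  wf <- weight_function(cfg$full_weight_radius_bp,
                        cfg$half_weight_distance_bp, cfg$enhancer_window_bp)
  res <- disease_enrichment_scan(tf_peaks, genes, lists, wf,
                                 cfg$enrichment_fdr_threshold)
  write_table_tsv(res, file.path(out_dir, "disease_enrichment.tsv"))
  invisible(NULL)
}

stage_de <- function(cfg, out_dir, sim) {
  counts <- read_matrix_tsv(file.path(out_dir, "expression_counts.tsv"))
  meta <- read_table_tsv(file.path(out_dir, "samples.tsv"))
  genes <- read_table_tsv(file.path(out_dir, "genes.tsv"))
  filt <- filter_genes(counts, genes, min_counts = cfg$min_gene_counts)
  st <- setNames(meta$state, meta$sample)[colnames(filt)]
  de <- de_test(filt, st, state_a = "A", state_b = "B",
                padj_threshold = cfg$de_padj_threshold,
                lfc_threshold = cfg$de_abs_log2fc_threshold)
  write_table_tsv(de, file.path(out_dir, "de_A_vs_B.tsv"))
  ab <- meta$state %in% c("A", "B")
  vis <- remove_batch_for_visualization(
    log_normalize_counts(filt[, meta$sample[ab], drop = FALSE]),
    batch = meta$batch[ab], condition = meta$state[ab])
  write_matrix_tsv(vis, file.path(out_dir, "expression_batchfree_log2.tsv"),
                   id_col = "gene")
  invisible(NULL)
}

stage_gsea <- function(cfg, out_dir, sim) {
  de <- read_table_tsv(file.path(out_dir, "de_A_vs_B.tsv"))
  metric <- setNames(de$log2fc, de$gene)
  gs <- read_gene_list(file.path(out_dir, "program_A_genes.txt"))
  res <- preranked_gsea(metric, gs,
                        n_permutations = cfg$gsea_permutations,
                        seed = cfg$rng_seed)
  write_table_tsv(data.table(set = "program_A", es = res$es, p = res$p,
                             direction = res$direction, n_set = res$n_set),
                  file.path(out_dir, "gsea.tsv"))
  invisible(NULL)
}

stage_motif <- function(cfg, out_dir, sim) {
  hits <- read_matrix_tsv(file.path(out_dir, "motif_hits.tsv"))
  diff <- read_table_tsv(file.path(out_dir, "differential_cres.tsv"))
  de <- read_table_tsv(file.path(out_dir, "de_A_vs_B.tsv"))
  counts <- read_matrix_tsv(file.path(out_dir, "expression_counts.tsv"))
  tfs <- colnames(hits)
  motifs <- paste0("m_", tfs)
  colnames(hits) <- motifs
  # variable CREs: classed by the ATAC direction
  atac <- diff[mark == "ATAC" & class != "nonvariable"]
  cls <- setNames(atac$class, atac$cre)
  enr <- differential_motif_enrichment(hits, cls)
  vari <- motif_variability(enr)
  cand <- data.table(motif = motifs, tf = tfs)
  totals <- rowSums(counts)[tfs]
  names(totals) <- tfs
  totals[is.na(totals)] <- 0
  lfc <- setNames(de$log2fc, de$gene)[tfs]
  names(lfc) <- tfs
  lfc[is.na(lfc)] <- 0
  assign <- filter_and_assign_motifs(cand, totals, lfc, vari,
                                     min_counts = 10)
  out <- merge(enr, assign, by = "motif")
  setorder(out, motif, cls)
  write_table_tsv(out, file.path(out_dir, "motif_enrichment.tsv"))
  invisible(NULL)
}
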