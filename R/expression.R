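# Differential expression with the pipeline's filters and thresholds,
# least-squares batch removal for visualization, and preranked GSEA.

#' Filter an expression count table
#'
#' Removes genes on chromosome X or Y (sex differences between donors) and
#' genes with fewer than `min_counts` total counts. Idempotent.
#'
#' @param counts count matrix, genes x samples.
#' @param annotation gene annotation (`gene`, `chrom`); genes missing from
#'   it are kept (no chromosome evidence to drop them on).
#' @param min_counts row-total cutoff; rows with total `< min_counts` are
#'   dropped (default 10).
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, annotation = NULL, min_counts = 10) {
  m <- as.matrix(counts)
  keep <- rowSums(m) >= min_counts
  if (!is.null(annotation)) {
    ann <- as.data.table(annotation)
    sex <- ann$gene[tolower(sub("^chr", "", ann$chrom)) %in% c("x", "y")]
    keep <- keep & !(rownames(m) %in% sex)
  }
  m[keep, , drop = FALSE]
}

#' Differential expression test between two states
#'
#' NB Wald test (see [nb_wald_test()]) of `state_a` vs `state_b`; genes
#' pass at `padj <= padj_threshold` AND `|log2fc| >= lfc_threshold` and
#' are classed `A-high` / `B-high` by sign, otherwise `ns`.
#'
#' @param counts filtered raw count matrix, genes x samples.
#' @param condition character/factor of per-sample state labels.
#' @param state_a,state_b the two states compared (`log2fc` is A vs B).
#' @param batch optional blocking factor (enters the model additively).
#' @param padj_threshold default 0.01.
#' @param lfc_threshold default 0.58 (fold change 1.5).
#' @return `data.table` (`gene`, `baseMean`, `log2fc`, `p`, `padj`,
#'   `class`).
#' @export
de_test <- function(counts, condition, state_a = "A", state_b = "B",
                    batch = NULL, padj_threshold = 0.01,
                    lfc_threshold = 0.58) {
  m <- as.matrix(counts)
  keep <- condition %in% c(state_a, state_b)
  cond <- factor(condition[keep], levels = c(state_b, state_a))
  res <- nb_wald_test(m[, keep, drop = FALSE], cond,
                      batch = if (is.null(batch)) NULL else batch[keep])
  out <- data.table(gene = res$feature, baseMean = res$baseMean,
                    log2fc = res$log2fc, p = res$p)
  out[, padj := p.adjust(p, method = "BH")]
  out[, class := "ns"]
  out[padj <= padj_threshold & log2fc >= lfc_threshold, class := "A-high"]
  out[padj <= padj_threshold & log2fc <= -lfc_threshold, class := "B-high"]
  out[]
}

#' Remove a batch effect from a log-scale matrix for visualization
#'
#' Least-squares removal of an additive batch factor while preserving the
#' condition effect (the condition-term fitted values are unchanged).
#' Backed by `limma::removeBatchEffect` with an explicit full-rank check;
#' use only for visualization, never before testing.
#'
#' @param logmat log-scale expression matrix, genes x samples.
#' @param batch per-sample batch labels.
#' @param condition per-sample condition labels (protected from removal).
#' @return the adjusted matrix.
#' @export
remove_batch_for_visualization <- function(logmat, batch, condition) {
  batch <- as.factor(batch)
  condition <- as.factor(condition)
  design <- model.matrix(~condition)
  full <- cbind(design, model.matrix(~batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full))
    stop("condition and batch are confounded (design not full rank)")
  limma::removeBatchEffect(as.matrix(logmat), batch = batch, design = design)
}

#' Size-factor log2 normalization for visualization
#'
#' `log2(count / size_factor + 1)`; the package's stand-in for a
#' variance-stabilizing transform.
#'
#' @param counts raw count matrix.
#' @return log2-scale matrix.
#' @export
log_normalize_counts <- function(counts) {
  m <- as.matrix(counts)
  sf <- size_factors(m)
  log2(sweep(m, 2L, sf, "/") + 1)
}

#' Preranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Genes are ranked by a signed metric (typically log2FC, descending).
#' The running sum increments by `|metric|^1 / sum(|metric| of members)`
#' at set members and decrements by `1 / (N - Nh)` elsewhere; ES is the
#' extreme deviation (signed). The permutation p-value draws random gene
#' sets of the same size: `p = (1 + #{|ES*| >= |ES|}) / (1 + n_perm)`.
#'
#' @param metric named numeric vector (gene -> ranking metric).
#' @param gene_set character vector; must intersect the ranked universe.
#' @param n_permutations default 1000 (>= 100 enforced).
#' @param seed RNG seed for the permutation null.
#' @return list (`es`, `p`, `direction` ("up"/"down"), `n_set`).
#' @export
preranked_gsea <- function(metric, gene_set, n_permutations = 1000,
                           seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  metric <- sort(metric, decreasing = TRUE)
  inset <- names(metric) %in% gene_set
  if (!any(inset)) stop("gene set does not intersect the ranked universe")
  es_obs <- gsea_es(metric, inset)
  nh <- sum(inset)
  set.seed(seed)
  null_abs <- replicate(n_permutations, {
    idx <- sample.int(length(metric), nh)
    flag <- logical(length(metric)); flag[idx] <- TRUE
    abs(gsea_es(metric, flag))
  })
  p <- (1 + sum(null_abs >= abs(es_obs))) / (1 + n_permutations)
  list(es = es_obs, p = p,
       direction = if (es_obs >= 0) "up" else "down", n_set = nh)
}

# Running-sum enrichment score for a pre-sorted metric and membership flag.
gsea_es <- function(sorted_metric, inset) {
  w <- abs(sorted_metric)
  nr <- sum(w[inset])
  n <- length(sorted_metric)
  nh <- sum(inset)
  if (nr == 0) {
    # degenerate all-zero weights inside the set: fall back to equal weights
    step_hit <- ifelse(inset, 1 / nh, 0)
  } else {
    step_hit <- ifelse(inset, w / nr, 0)
  }
  step_miss <- ifelse(inset, 0, 1 / (n - nh))
  run <- cumsum(step_hit - step_miss)
  run[which.max(abs(run))]
}
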