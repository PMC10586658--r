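# Motif <-> TF assignment and differential motif enrichment across CRE
# classes. Motif scanning itself is out of scope: hits arrive as a 0/1
# CRE x motif matrix. Enrichment per class is a signed z score from the
# normal approximation of the hypergeometric (class hits vs all variable
# CREs), the transparent stand-in for an ensemble motif-activity method.

#' Resolve a many-to-many motif <-> TF candidate map
#'
#' TFs expressed below `min_counts` total are dropped. When several motifs
#' map to one TF the motif with the largest cross-class enrichment
#' variability is kept; when several TFs map to one motif the TF with the
#' largest absolute expression log2FC is kept. Ties break
#' lexicographically; the result is one-to-one.
#'
#' @param candidates `data.table`/data.frame with columns `motif`, `tf`.
#' @param tf_total_counts named numeric vector, total expression counts
#'   per TF.
#' @param tf_log2fc named numeric vector, between-state expression log2FC
#'   per TF (missing TFs treated as 0).
#' @param motif_variability named numeric vector, cross-class variability
#'   per motif (e.g. variance of class z scores; missing motifs 0).
#' @param min_counts expression filter (default 10).
#' @return `data.table` (`motif`, `tf`, `tf_log2fc`, `variability`).
#' @export
filter_and_assign_motifs <- function(candidates, tf_total_counts,
                                     tf_log2fc, motif_variability,
                                     min_counts = 10) {
  cand <- as.data.table(candidates)[, .(motif = as.character(motif),
                                        tf = as.character(tf))]
  expressed <- names(tf_total_counts)[tf_total_counts >= min_counts]
  cand <- cand[tf %in% expressed]
  if (!nrow(cand))
    return(data.table(motif = character(), tf = character(),
                      tf_log2fc = numeric(), variability = numeric()))
  cand[, variability := ifelse(is.na(motif_variability[motif]), 0,
                               motif_variability[motif])]
  lfc <- tf_log2fc[cand$tf]
  cand[, tf_log2fc := ifelse(is.na(lfc), 0, lfc)]
  # TF -> motif: keep the most variable motif per TF
  setorder(cand, tf, -variability, motif)
  cand <- cand[, head(.SD, 1L), by = tf]
  # motif -> TF: keep the most differential TF per motif
  cand[, abs_lfc := abs(tf_log2fc)]
  setorder(cand, motif, -abs_lfc, tf)
  cand <- cand[, head(.SD, 1L), by = motif]
  cand[, abs_lfc := NULL]
  setorder(cand, motif)
  cand[, .(motif, tf, tf_log2fc, variability)]
}

#' Differential motif enrichment across CRE classes
#'
#' For each motif and CRE class: hypergeometric enrichment of motif-bearing
#' CREs in the class against all variable CREs, as a signed z score
#' `(x - mean) / sd` with the hypergeometric mean `n K / N` and variance
#' `n (K/N) (1 - K/N) (N - n)/(N - 1)`; plus the percentage of class CREs
#' containing the motif.
#'
#' @param motif_hits 0/1 matrix, CREs x motifs.
#' @param cre_classes named character vector CRE id -> class label; only
#'   CREs present here (the variable CREs) are considered.
#' @return `data.table` (`motif`, `cls`, `z`, `pct_cres`, `n_class`,
#'   `n_hits_class`).
#' @export
differential_motif_enrichment <- function(motif_hits, cre_classes) {
  hits <- as.matrix(motif_hits)
  cres <- intersect(rownames(hits), names(cre_classes))
  if (!length(cres)) stop("no classified CREs found in the hit matrix")
  hits <- hits[cres, , drop = FALSE] > 0
  cls <- cre_classes[cres]
  N <- length(cres)
  K <- colSums(hits)           # motif-bearing CREs overall
  rows <- list()
  for (cl in sort(unique(cls))) {
    idx <- cls == cl
    n <- sum(idx)
    if (n == 0L) { warning("empty class ", cl, " skipped"); next }
    x <- colSums(hits[idx, , drop = FALSE])
    mu <- n * K / N
    v <- n * (K / N) * (1 - K / N) * (N - n) / max(N - 1, 1)
    z <- ifelse(v > 0, (x - mu) / sqrt(v), 0)
    rows[[length(rows) + 1L]] <- data.table(
      motif = colnames(hits), cls = cl, z = z,
      pct_cres = 100 * x / n, n_class = n, n_hits_class = as.integer(x))
  }
  out <- rbindlist(rows)
  setorder(out, motif, cls)
  out[]
}

#' Cross-class variability of motif enrichment
#'
#' Variance of the per-class z scores per motif; the "most variable motif"
#' criterion used by [filter_and_assign_motifs()].
#'
#' @param enrichment result of [differential_motif_enrichment()].
#' @return named numeric vector, motif -> variance of z.
#' @export
motif_variability <- function(enrichment) {
  v <- as.data.table(enrichment)[, .(v = var(z)), by = motif]
  out <- setNames(v$v, v$motif)
  out[is.na(out)] <- 0
  out
}
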