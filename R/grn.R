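# TF -> gene binding networks and differential influence.
#
# A transparent binding proxy replaces trained TF-binding models: per CRE,
# motif-hit indicator times min-max-scaled mean of ATAC and H3K27ac signal
# in the cell state; per (TF, gene) edge, the distance-weighted sum of that
# proxy over CREs within the enhancer window of the gene's TSS, min-max
# scaled across the network so binding scores live in [0, 1]. The
# reference-anchored comparison design, the 0.5 shared-TF rule and the
# delta-binding hierarchy classification operate on top of this score.

#' Build a TF -> gene binding network for one cell state
#'
#' @param motif_hits 0/1 matrix, CREs x TFs (rownames = catalogue CRE ids).
#' @param activity named list of two normalized `signal_matrix` objects,
#'   `ATAC` and `H3K27ac`, with columns restricted (via `states`) to the
#'   samples of this state.
#' @param catalogue CRE catalogue (`cre`, `chrom`, `summit`).
#' @param genes gene annotation (`gene`, `chrom`, `tss`).
#' @param state state label stored on the network.
#' @param states named sample -> state vector used to pick this state's
#'   columns from the signal matrices.
#' @param wf a [weight_function()] bounding the enhancer window.
#' @return object of class `binding_network`: `data.table` of edges
#'   (`tf`, `gene`, `binding` in `[0, 1]`) plus the state label.
#' @export
build_binding_network <- function(motif_hits, activity, catalogue, genes,
                                  state, states, wf = weight_function()) {
  stopifnot(all(c("ATAC", "H3K27ac") %in% names(activity)))
  catalogue <- as.data.table(catalogue)
  genes <- as.data.table(genes)
  pick_state <- function(sm) {
    cols <- intersect(colnames(sm$values), names(states)[states == state])
    if (!length(cols)) stop("no samples of state ", state, " in ", sm$mark)
    rowMeans(sm$values[catalogue$cre, cols, drop = FALSE])
  }
  act <- (pick_state(activity$ATAC) + pick_state(activity$H3K27ac)) / 2
  act <- minmax_scale(act)
  hits <- as.matrix(motif_hits)[catalogue$cre, , drop = FALSE]
  # per-CRE, per-TF proxy = hit * activity; aggregate to genes with the
  # same weighted-window machinery as enhancer signal
  proxy <- hits * act
  proxy_sm <- signal_matrix(proxy, mark = "binding_proxy", window = 0L,
                            normalized = TRUE)
  agg <- aggregate_enhancer_signal(catalogue, proxy_sm, genes, wf)$summary
  scaled <- minmax_scale(agg)
  edges <- data.table(gene = rep(rownames(scaled), ncol(scaled)),
                      tf = rep(colnames(scaled), each = nrow(scaled)),
                      binding = as.vector(scaled))
  edges <- edges[binding > 0]
  setorder(edges, tf, gene)
  structure(list(state = state, edges = edges[, .(tf, gene, binding)]),
            class = "binding_network")
}

minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[2L] == rng[1L]) return(x * 0)
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' @export
print.binding_network <- function(x, ...) {
  cat(sprintf("binding_network[%s]: %d edges, %d TFs\n", x$state,
              nrow(x$edges), length(unique(x$edges$tf))))
  invisible(x)
}

# Full (tf, gene) join of two edge tables; missing edges score 0.
edge_join <- function(net_source, net_target) {
  a <- net_source$edges; b <- net_target$edges
  merged <- merge(a, b, by = c("tf", "gene"), all = TRUE,
                  suffixes = c("_source", "_target"))
  merged[is.na(merged)] <- 0
  merged
}

#' Differential TF influence between two networks
#'
#' Edge differential score = `max(0, B_target - B_source)`; the top
#' `max_edges` such edges are kept. A TF's raw influence is the sum over
#' its kept edges of edge score times `max(0, log2FC)` of the target gene,
#' restricted to significantly differential genes; influence is scaled so
#' the top TF scores 1.
#'
#' @param net_source,net_target `binding_network`s (e.g. REF and A).
#' @param de differential-expression table (`gene`, `log2fc`, `padj`)
#'   computed target-vs-source.
#' @param max_edges number of differential edges retained (default 500000).
#' @param de_padj_threshold significance gate for target genes.
#' @return `data.table` (`tf`, `influence`, `n_targets`) sorted by
#'   descending influence.
#' @export
differential_influence <- function(net_source, net_target, de,
                                   max_edges = 500000,
                                   de_padj_threshold = 0.05) {
  stopifnot(max_edges >= 1)
  de <- as.data.table(de)
  merged <- edge_join(net_source, net_target)
  merged[, edge_score := pmax(binding_target - binding_source, 0)]
  merged <- merged[edge_score > 0]
  setorder(merged, -edge_score, tf, gene)
  merged <- head(merged, max_edges)
  sig <- de[padj < de_padj_threshold & log2fc > 0, .(gene, log2fc)]
  tfs <- sort(unique(c(net_source$edges$tf, net_target$edges$tf)))
  if (!nrow(sig)) {
    warning("no differentially up-regulated genes; all influences are 0")
    return(data.table(tf = tfs, influence = 0, n_targets = 0L))
  }
  merged <- merge(merged, sig, by = "gene")
  merged[, contrib := edge_score * log2fc]
  raw <- merged[contrib > 0, .(raw = sum(contrib), n_targets = .N), by = tf]
  out <- merge(data.table(tf = tfs), raw, by = "tf", all.x = TRUE)
  out[is.na(raw), `:=`(raw = 0, n_targets = 0L)]
  mx <- max(out$raw)
  out[, influence := if (mx > 0) raw / mx else 0]
  out[, raw := NULL]
  setorder(out, -influence, tf)
  out[, .(tf, influence, n_targets)]
}

#' Classify TFs as shared or cell-type-specific from two influence runs
#'
#' Shared: influence above `shared_threshold` in both reference-anchored
#' comparisons. A-specific: above threshold in REF->A and at most
#' `low_threshold` (low or undetected) in REF->B; symmetrically for B.
#' Everything else is "neither". Missing TFs count as influence 0.
#'
#' @param infl_ref_a,infl_ref_b influence tables from
#'   [differential_influence()] for REF->A and REF->B.
#' @param shared_threshold default 0.5.
#' @param low_threshold default 0.2.
#' @return `data.table` (`tf`, `influence_ref_a`, `influence_ref_b`,
#'   `class`).
#' @export
classify_tfs <- function(infl_ref_a, infl_ref_b, shared_threshold = 0.5,
                         low_threshold = 0.2) {
  a <- as.data.table(infl_ref_a)[, .(tf, influence_ref_a = influence)]
  b <- as.data.table(infl_ref_b)[, .(tf, influence_ref_b = influence)]
  m <- merge(a, b, by = "tf", all = TRUE)
  m[is.na(m)] <- 0
  m[, class := "neither"]
  m[influence_ref_a > shared_threshold & influence_ref_b > shared_threshold,
    class := "shared-epithelial"]
  m[influence_ref_a > shared_threshold & influence_ref_b <= low_threshold,
    class := "A-specific"]
  m[influence_ref_b > shared_threshold & influence_ref_a <= low_threshold,
    class := "B-specific"]
  setorder(m, tf)
  m[]
}

#' Classify TF -> TF regulation by delta binding score
#'
#' For each TF -> target-TF edge (expression excluded; binding scores
#' only): `dB(REF->A) = B_A - B_REF`, `dB(REF->B) = B_B - B_REF`, direct
#' `d = B_A - B_B`. If the mean of the two reference-anchored deltas is >=
#' `|d|` the regulation is shared by both states; otherwise the state whose
#' network gains the edge names it (A-specific when d > 0, B-specific when
#' d < 0; an exact zero direct delta defaults to shared).
#'
#' @param net_ref,net_a,net_b `binding_network`s restricted (by `tfs`) to
#'   TF -> TF edges.
#' @param tfs character vector of TF ids; only edges whose target gene is
#'   itself a TF are classified.
#' @return `data.table` (`tf`, `target`, `delta_ref_a`, `delta_ref_b`,
#'   `delta_direct`, `label`).
#' @export
classify_edge_regulation <- function(net_ref, net_a, net_b, tfs) {
  sub <- function(net) {
    e <- net$edges[gene %in% tfs]
    setnames(e, "binding", "b")
    e
  }
  m <- merge(merge(sub(net_ref), sub(net_a), by = c("tf", "gene"),
                   all = TRUE, suffixes = c("_ref", "_a")),
             sub(net_b), by = c("tf", "gene"), all = TRUE)
  setnames(m, "b", "b_b")
  for (col in c("b_ref", "b_a", "b_b")) m[is.na(get(col)), (col) := 0]
  m[, `:=`(delta_ref_a = b_a - b_ref,
           delta_ref_b = b_b - b_ref,
           delta_direct = b_a - b_b)]
  m[, label := classify_delta(delta_ref_a, delta_ref_b, delta_direct)]
  setnames(m, "gene", "target")
  setorder(m, tf, target)
  m[, .(tf, target, delta_ref_a, delta_ref_b, delta_direct, label)]
}

#' Delta-binding classification rule
#'
#' Vectorized core of [classify_edge_regulation()], exposed for direct
#' grid evaluation.
#'
#' @param delta_ref_a,delta_ref_b,delta_direct numeric vectors.
#' @return character vector of labels
#'   (`shared`, `A-specific`, `B-specific`).
#' @export
classify_delta <- function(delta_ref_a, delta_ref_b, delta_direct) {
  mean_ref <- (delta_ref_a + delta_ref_b) / 2
  ifelse(mean_ref >= abs(delta_direct) | delta_direct == 0, "shared",
         ifelse(delta_direct > 0, "A-specific", "B-specific"))
}
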