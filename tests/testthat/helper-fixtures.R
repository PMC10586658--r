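# Shared fixtures, built in code. tiny_sim() keeps the synthetic world small
# enough for fast per-module tests; acceptance tests use the full defaults.

tiny_sim <- function(seed = 1L, ...) {
  sim_config(rng_seed = seed, n_genes = 200L, n_cres = 600L,
             chrom_length_bp = 10000000L, n_tfs = 12L,
             n_shared_tfs = 2L, tf_target_fanout = 10L,
             cres_per_target = 3L, n_disease_genes = 12L, ...)
}

# deterministic fake peak table
make_peaks <- function(chrom, summit, score = seq_along(summit)) {
  data.table::data.table(chrom = chrom, summit = as.integer(summit),
                         score = score)
}

# gene annotation straight from coordinates (plus strand handling)
make_genes <- function(chrom, tss, gene = sprintf("g%03d", seq_along(tss)),
                       strand = "+") {
  tss <- as.integer(tss)
  strand <- rep_len(strand, length(tss))
  regcircuit::gene_annotation(data.table::data.table(
    gene = gene, chrom = chrom,
    start = ifelse(strand == "+", tss, tss - 999L),
    end = ifelse(strand == "+", tss + 1000L, tss + 1L),
    strand = strand))
}

# brute-force O(genes x CREs) oracle for distance-weighted aggregation
brute_force_aggregate <- function(catalogue, values, genes, wf) {
  out <- matrix(0, nrow(genes), ncol(values),
                dimnames = list(genes$gene, colnames(values)))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(catalogue))) {
      if (genes$chrom[i] != catalogue$chrom[j]) next
      d <- abs(genes$tss[i] - catalogue$summit[j])
      if (d > wf$dmax) next
      out[i, ] <- out[i, ] + distance_weight(d, wf) * values[catalogue$cre[j], ]
    }
  }
  out
}

# exhaustive-enumeration oracle for the one-sided Mann-Whitney p
brute_force_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool, ties.method = "average")
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pool), n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs - 1e-9)
}
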