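# Small controlled world used by several network tests.
toy_network_world <- function() {
  genes <- make_genes("chr1", c(100000, 300000, 500000),
                      gene = c("g1", "g2", "g3"))
  cat <- data.table::data.table(cre = c("c1", "c2", "c3", "c4"),
                                chrom = "chr1",
                                summit = c(100000L, 150000L, 300000L, 500000L))
  samples <- c(A_1 = "A", A_2 = "A", R_1 = "REF", R_2 = "REF")
  mk <- function(vals) {
    m <- matrix(rep(vals, 4), 4, 4, dimnames = list(cat$cre, names(samples)))
    signal_matrix(m, "ATAC", 200L, normalized = TRUE, states = samples)
  }
  list(genes = genes, cat = cat, samples = samples, mk = mk)
}

test_that("binding network scales edges to [0,1] and zero-hit TFs get no edges", {
  w <- toy_network_world()
  act <- list(ATAC = w$mk(c(2, 1, 0.5, 0)), H3K27ac = w$mk(c(2, 1, 0.5, 0)))
  hits <- matrix(c(1, 1, 1, 0,   0, 0, 0, 0), 4, 2,
                 dimnames = list(w$cat$cre, c("tf1", "tf2")))
  net <- build_binding_network(hits, act, w$cat, w$genes, "A", w$samples)
  expect_true(all(net$edges$binding >= 0 & net$edges$binding <= 1))
  expect_false("tf2" %in% net$edges$tf)      # zero motif hits -> no edges
  expect_equal(max(net$edges$binding), 1)    # max edge scales to exactly 1

  # hand-computed pre-scale ratio: g1 gets w(0)*a(c1) + w(50k)*a(c2);
  # activities min-max scale to c(1, 0.5, 0.25, 0); g2 gets w(0)*0.25
  s_g1 <- 1 * 1 + 0.5 * 0.5
  s_g2 <- 0.25
  e <- net$edges
  expect_equal(e[e$gene == "g2", binding] / e[e$gene == "g1", binding],
               s_g2 / s_g1, tolerance = 1e-9)
})

test_that("differential influence follows its contract on constructed networks", {
  mk_net <- function(state, edges) structure(list(state = state, edges = edges),
                                             class = "binding_network")
  up_genes <- sprintf("u%d", 1:5)
  other <- sprintf("o%d", 1:5)
  src <- mk_net("REF", data.table::data.table(tf = character(),
                                              gene = character(),
                                              binding = numeric()))
  tgt <- mk_net("A", data.table::data.table(
    tf = rep(c("tfU", "tfO"), each = 5),
    gene = c(up_genes, other),
    binding = rep(0.8, 10)))
  de <- data.table::data.table(gene = c(up_genes, other),
                               log2fc = rep(c(2, -2), each = 5),
                               padj = 0.001)
  infl <- differential_influence(src, tgt, de, max_edges = 100)
  expect_equal(infl$influence[infl$tf == "tfU"], 1)   # targets all up genes
  expect_equal(infl$tf[1], "tfU")
  expect_equal(infl$influence[infl$tf == "tfO"], 0)   # targets only down genes
  expect_true(all(infl$influence >= 0 & infl$influence <= 1))
  expect_equal(infl$n_targets[infl$tf == "tfU"], 5L)

  # no differential genes -> all zero, warning
  de0 <- data.table::data.table(gene = up_genes, log2fc = 2, padj = 0.9)
  expect_warning(i0 <- differential_influence(src, tgt, de0), "no differentially")
  expect_true(all(i0$influence == 0))

  # invariance under gene relabelling
  perm <- setNames(sprintf("x%02d", 1:10), c(up_genes, other))
  tgt2 <- mk_net("A", data.table::data.table(tf = tgt$edges$tf,
                                             gene = perm[tgt$edges$gene],
                                             binding = tgt$edges$binding))
  de2 <- data.table::data.table(gene = perm[de$gene], log2fc = de$log2fc,
                                padj = de$padj)
  infl2 <- differential_influence(src, tgt2, de2, max_edges = 100)
  expect_equal(infl$influence, infl2$influence)

  # max_edges truncation keeps the largest differential edges
  infl3 <- differential_influence(src, tgt, de, max_edges = 3)
  expect_lte(max(infl3$n_targets), 3L)
})

test_that("TF classification applies the shared/specific thresholds", {
  mk <- function(tf, infl) data.table::data.table(tf = tf, influence = infl,
                                                  n_targets = 1L)
  cls <- classify_tfs(mk(c("t1", "t2", "t3", "t4"), c(0.8, 0.8, 0.3, 0.8)),
                      mk(c("t1", "t2", "t3", "t4"), c(0.7, 0.0, 0.2, 0.35)))
  expect_equal(cls[cls$tf == "t1", class], "shared-epithelial")  # > 0.5 both
  expect_equal(cls[cls$tf == "t2", class], "A-specific")         # undetected in B
  expect_equal(cls[cls$tf == "t3", class], "neither")
  expect_equal(cls[cls$tf == "t4", class], "neither")            # 0.35 not low enough
  # missing TFs count as influence 0
  cls2 <- classify_tfs(mk("t9", 0.9), mk("tX", 0.9))
  expect_equal(cls2[cls2$tf == "t9", class], "A-specific")
  expect_equal(cls2[cls2$tf == "tX", class], "B-specific")
})

test_that("delta-binding rule matches direct evaluation on an exhaustive grid", {
  g <- seq(-0.8, 0.8, by = 0.2)
  grid <- expand.grid(da = g, db = g, dd = g)
  got <- classify_delta(grid$da, grid$db, grid$dd)
  want <- apply(grid, 1L, function(r) {
    mean_ref <- (r[["da"]] + r[["db"]]) / 2
    if (mean_ref >= abs(r[["dd"]]) || r[["dd"]] == 0) "shared"
    else if (r[["dd"]] > 0) "A-specific" else "B-specific"
  })
  expect_identical(got, unname(want))

  # worked examples
  expect_equal(classify_delta(0.6, 0.5, 0.2), "shared")        # 0.55 >= 0.2
  expect_equal(classify_delta(0.7, 0.05, 0.65), "A-specific")  # 0.375 < 0.65
  expect_equal(classify_delta(0.05, 0.7, -0.65), "B-specific")

  # antisymmetry: swapping states A<->B negates the direct delta and swaps labels
  swapped <- classify_delta(grid$db, grid$da, -grid$dd)
  map <- c(shared = "shared", `A-specific` = "B-specific",
           `B-specific` = "A-specific")
  expect_identical(swapped, unname(map[got]))
})

test_that("classify_edge_regulation labels every TF->TF edge exactly once", {
  mk_net <- function(state, tf, gene, b)
    structure(list(state = state,
                   edges = data.table::data.table(tf = tf, gene = gene,
                                                  binding = b)),
              class = "binding_network")
  tfs <- c("t1", "t2")
  ref <- mk_net("REF", "t1", "t2", 0.1)
  a <- mk_net("A", c("t1", "t2"), c("t2", "t1"), c(0.9, 0.4))
  b <- mk_net("B", "t1", "t2", 0.3)
  res <- classify_edge_regulation(ref, a, b, tfs)
  expect_equal(nrow(res), 2L)                       # union of edges
  expect_true(all(res$label %in% c("shared", "A-specific", "B-specific")))
  # t1->t2: dA = 0.8, dB = 0.2, direct = 0.6: mean 0.5 < 0.6, direct > 0
  expect_equal(res[res$tf == "t1" & res$target == "t2", label], "A-specific")
  # t2->t1 exists only in A: dA = 0.4, dB = 0, direct = 0.4: mean 0.2 < 0.4
  expect_equal(res[res$tf == "t2" & res$target == "t1", label], "A-specific")
})

test_that("planted regulators are recovered from the synthetic landscape", {
  # one seed in the unit suite; the 20-seed sweep lives in the acceptance test
  cfg <- sim_config(rng_seed = 5)
  land <- simulate_landscape(cfg)
  expr <- simulate_expression(cfg, land$truth)
  act <- list(ATAC = normalize_signal(land$counts$ATAC),
              H3K27ac = normalize_signal(land$counts$H3K27ac))
  nets <- lapply(c(A = "A", B = "B", REF = "REF"), function(st)
    build_binding_network(land$motif_hits, act, land$catalogue, land$genes,
                          st, land$states))
  st <- setNames(expr$samples$state, expr$samples$sample)
  filt <- filter_genes(expr$counts, min_counts = 10)
  de_a <- de_test(filt, st[colnames(filt)], state_a = "A", state_b = "REF")
  de_b <- de_test(filt, st[colnames(filt)], state_a = "B", state_b = "REF")
  ia <- differential_influence(nets$REF, nets$A, de_a, de_padj_threshold = 0.01)
  ib <- differential_influence(nets$REF, nets$B, de_b, de_padj_threshold = 0.01)
  cls <- classify_tfs(ia, ib)
  master <- land$truth$a_tfs[1]
  expect_lte(which(ia$tf == master), 3L)
  expect_equal(cls[cls$tf == master, class], "A-specific")
  expect_true(all(cls[cls$tf %in% land$truth$shared_tfs, class] ==
                    "shared-epithelial"))
})
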