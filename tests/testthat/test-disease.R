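test_that("binding scores follow the weighted-sum definition", {
  wf <- weight_function()
  genes <- make_genes("chr1", c(200000, 900000), gene = c("g1", "gFar"))
  # normalized intensity v at the TSS: score = v
  pk <- data.table::data.table(chrom = "chr1", summit = 200000L,
                               intensity = 9)
  sc <- score_tf_binding(pk, genes, wf)
  expect_equal(sc[sc$gene == "g1", score], log10(10), tolerance = 1e-12)
  expect_equal(sc[sc$gene == "gFar", score], 0)       # no peak within 100 kb
  expect_equal(sc[sc$gene == "gFar", n_peaks], 0L)

  # two peaks at w = 1 and w = 0.5 with normalized intensities 2 and 3
  pk2 <- data.table::data.table(chrom = "chr1",
                                summit = c(200000L, 250000L),
                                intensity = c(99, 999))
  sc2 <- score_tf_binding(pk2, genes, wf)
  expect_equal(sc2[sc2$gene == "g1", score], 2 * 1 + 3 * 0.5, tolerance = 1e-9)

  # adding a peak never decreases any gene's score
  pk3 <- rbind(pk2, data.table::data.table(chrom = "chr1", summit = 260000L,
                                           intensity = 5))
  sc3 <- score_tf_binding(pk3, genes, wf)
  expect_true(all(sc3$score >= sc2$score - 1e-12))
})

test_that("Mann-Whitney enrichment matches worked examples and the enumeration oracle", {
  genes <- sprintf("g%d", 1:6)
  sc <- data.table::data.table(gene = genes, score = c(3, 4, 5, 0, 1, 2))
  r <- mannwhitney_enrichment(sc, genes[1:3])
  expect_equal(r$p, 0.05)                      # 1 / C(6,3)
  expect_equal(r$statistic, 9)
  expect_equal(r$top_bound_genes, c("g3", "g2", "g1"))

  r2 <- mannwhitney_enrichment(data.table::data.table(gene = genes,
                                                      score = c(0, 1, 2, 3, 4, 5)),
                               genes[1:3])
  expect_equal(r2$p, 1.0)                      # least extreme in the greater tail

  # oracle: all partitions with n1 + n2 <= 10, tied and untied data
  set.seed(10)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    n1 <- sample(2:(n - 2), 1)
    pool <- if (rep %% 2 == 0) sample(0:3, n, TRUE) else rnorm(n)
    p_fast <- regcircuit:::mw_one_sided_p(pool[1:n1], pool[(n1 + 1):n])
    p_oracle <- brute_force_mw_p(pool[1:n1], pool[(n1 + 1):n])
    expect_equal(p_fast, p_oracle, tolerance = 1e-12)
  }

  expect_warning(
    mannwhitney_enrichment(sc, c(genes[1:2], "absent")), "dropped")
  expect_error(suppressWarnings(mannwhitney_enrichment(sc, c("g1", "nope"))),
               ">= 2")
})

test_that("Fisher nearest-TSS enrichment matches the hypergeometric tail", {
  # 6 far-apart genes; peaks exactly at the TSS of the mapped ones
  genes <- make_genes("chr1", seq(1e6, 6e6, by = 1e6))
  disease <- genes$gene[1:3]
  pk <- data.table::data.table(chrom = "chr1",
                               summit = genes$tss[1:3], intensity = 1)
  r <- fisher_nearest_enrichment(pk, genes, disease)
  expect_equal(r$p, 0.05)                      # 1 / C(6,3)
  expect_equal(unname(r$table["mapped", "disease"]), 3)

  # no peaks -> nothing mapped -> p = 1
  r0 <- fisher_nearest_enrichment(pk[0], genes, disease)
  expect_equal(r0$p, 1)

  # equal mapping rates -> odds ratio 1
  pk_eq <- data.table::data.table(chrom = "chr1",
                                  summit = genes$tss[c(1, 4)], intensity = 1)
  expect_equal(fisher_nearest_enrichment(pk_eq, genes, disease)$statistic, 1)

  # all genes mapped -> p = 1, odds ratio undefined
  pk_all <- data.table::data.table(chrom = "chr1", summit = genes$tss,
                                   intensity = 1)
  r_all <- fisher_nearest_enrichment(pk_all, genes, disease)
  expect_equal(r_all$p, 1)
  expect_true(r_all$odds_ratio_undefined)

  # dual route: p equals fisher.test one-sided over a grid of tables N <= 30
  set.seed(11)
  for (rep in 1:25) {
    N <- sample(6:30, 1)
    K <- sample(2:(N - 2), 1)               # disease genes
    n <- sample(1:(N - 1), 1)               # mapped genes
    x <- sample(max(0, K + n - N):min(K, n), 1)
    gg <- make_genes("chr1", seq(1e6, N * 1e6, by = 1e6))
    disease <- gg$gene[1:K]
    mapped <- c(gg$gene[seq_len(x)],
                setdiff(gg$gene, disease)[seq_len(n - x)])
    pkx <- data.table::data.table(chrom = "chr1",
                                  summit = gg$tss[match(mapped, gg$gene)],
                                  intensity = 1)
    r <- fisher_nearest_enrichment(pkx, gg, disease)
    ft <- fisher.test(matrix(c(x, K - x, n - x, N - K - (n - x)), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("bh_fdr applies the step-up rule with monotonicity", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("planted disease binding is detected by both tests and nulls stay null", {
  cfg <- tiny_sim(seed = 21)
  land <- simulate_landscape(cfg)
  pk <- simulate_tf_peaks(cfg, land)
  set.seed(99)
  rnd <- sort(sample(setdiff(land$genes$gene, c(pk$disease_genes,
                                                land$truth$tf_classes$tf)),
                     cfg$n_disease_genes))
  res <- disease_enrichment_scan(pk$tf_peaks, land$genes,
                                 list(disease = pk$disease_genes,
                                      random = rnd))
  planted <- res[res$tf == pk$disease_tf & res$list_name == "disease", ]
  expect_true(all(planted$fdr < 0.1))
  expect_true(all(planted$significant))
  expect_true(all(res$fdr >= res$p))
  expect_true(all(lengths(strsplit(res$top_bound_genes, ";")) <= 5))
  # the top bound genes belong to the tested list
  expect_true(all(unlist(strsplit(planted$top_bound_genes, ";")) %in%
                    pk$disease_genes))
})

test_that("zero-peak TFs round-trip as empty sets", {
  cfg <- tiny_sim(seed = 3, peak_rate = 0)
  land <- simulate_landscape(cfg)
  pk <- simulate_tf_peaks(cfg, land)
  expect_true(all(vapply(pk$tf_peaks, nrow, 0L) == 0L))
  f <- withr::local_tempfile()
  write_narrowpeak(pk$tf_peaks[[1]], f)
  expect_equal(nrow(read_narrowpeak(f)), 0L)
})
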