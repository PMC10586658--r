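test_that("merge_top_peaks merges overlapping summit windows transitively", {
  pk <- list(A = make_peaks("chr1", c(100, 150)), B = make_peaks("chr1", integer()))
  cat <- suppressWarnings(merge_top_peaks(pk, top_n = 10, merge_radius = 200))
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$summit, 125L)             # rounded mean of members

  pk <- list(A = make_peaks("chr1", c(100, 400)))
  cat <- suppressWarnings(merge_top_peaks(pk, top_n = 10, merge_radius = 200))
  expect_equal(cat$summit, c(100L, 400L))    # disjoint windows stay apart

  # top_n selection by score before merging
  pk <- list(A = make_peaks("chr1", c(1000, 5000, 9000, 13000, 17000),
                            score = c(5, 4, 3, 2, 1)))
  cat <- merge_top_peaks(pk, top_n = 3, merge_radius = 200)
  expect_equal(cat$summit, c(1000L, 5000L, 9000L))

  # chain merge: 100-250-400 all chained although 100 and 400 are far apart
  pk <- list(A = make_peaks("chr1", c(100, 250, 400)))
  cat <- suppressWarnings(merge_top_peaks(pk, top_n = 10, merge_radius = 200))
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$summit, 250L)

  # provenance records which states contributed
  pk <- list(A = make_peaks("chr1", 100), B = make_peaks("chr1", 150))
  cat <- suppressWarnings(merge_top_peaks(pk, top_n = 10, merge_radius = 200))
  expect_equal(cat$sources, "A,B")

  expect_warning(merge_top_peaks(list(A = make_peaks("chr1", integer())),
                                 top_n = 5, merge_radius = 200), "empty|no peaks")
})

test_that("catalogue construction is deterministic and order-independent", {
  set.seed(42)
  base <- make_peaks(sample(c("chr1", "chr2"), 80, TRUE),
                     sample.int(100000, 80), score = runif(80))
  pk1 <- list(A = base, B = base[sample(.N)])
  pk2 <- list(A = base[sample(.N)], B = base[sample(.N)])
  c1 <- merge_top_peaks(pk1, top_n = 80, merge_radius = 300)
  c2 <- merge_top_peaks(pk2, top_n = 80, merge_radius = 300)
  expect_identical(c1, c2)
})

test_that("quantify_windows counts any-overlap fragments in half-open windows", {
  cat <- data.table::data.table(cre = "c1", chrom = "chr1", summit = 1000L)
  frags <- list(s1 = genomic_intervals(
    rep("chr1", 4), c(950L, 1090L, 1200L, 1100L), c(1000L, 1200L, 1300L, 1150L)))
  sm <- quantify_windows(cat, frags, mark = "ATAC", window = 200L)
  # window [900,1100): [950,1000) and [1090,1200) overlap; [1100,1150) abuts
  expect_equal(unname(sm$values["c1", "s1"]), 2L)

  sm0 <- quantify_windows(cat, list(s1 = genomic_intervals("chr1", 1L, 2L)),
                          mark = "ATAC", window = 200L)
  expect_equal(unname(sm0$values["c1", "s1"]), 0L)

  expect_warning(
    quantify_windows(cat, list(s1 = genomic_intervals("chrUn", 950L, 1000L)),
                     mark = "ATAC", window = 200L),
    "skipped")
})

test_that("quantile normalization matches the hand example and its invariants", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 6, 5))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 4.5, 3.5))

  # identical columns are a fixed point
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)

  # tie-free random matrices: all columns share the same sorted values
  set.seed(1)
  m3 <- matrix(rnorm(600), 100, 6)
  q3 <- quantile_normalize(m3)
  sorted <- apply(q3, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # ties receive the mean of their rank positions' reference values
  m4 <- cbind(c(1, 1, 5), c(10, 20, 30))
  q4 <- quantile_normalize(m4)
  ref <- rowMeans(apply(m4, 2, sort))
  expect_equal(unname(q4[1:2, 1]), rep(mean(ref[1:2]), 2))
})

test_that("normalize_signal log-transforms then quantile-normalizes", {
  counts <- matrix(c(0L, 9L, 99L, 0L, 9L, 99L), 3, 2,
                   dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  sm <- signal_matrix(counts, "ATAC", 200L)
  norm <- normalize_signal(sm)
  expect_true(norm$normalized)
  expect_equal(unname(norm$values[, 1]), c(0, 1, 2))  # log10(x+1), identical cols
  expect_error(normalize_signal(norm), "already")
  one <- signal_matrix(counts[, 1, drop = FALSE], "ATAC", 200L)
  expect_warning(n1 <- normalize_signal(one), "single-column")
  expect_equal(unname(n1$values[, 1]), c(0, 1, 2))
})

test_that("differential_count_test calls no class on flat data and recovers planted effects", {
  counts <- matrix(50L, 20, 8,
                   dimnames = list(sprintf("c%02d", 1:20), sprintf("s%d", 1:8)))
  states <- setNames(rep(c("A", "B"), each = 4), colnames(counts))
  sm <- signal_matrix(counts, "ATAC", 200L, states = states)
  res <- differential_count_test(sm)
  expect_true(all(res$class == "nonvariable"))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$padj >= res$p))

  # planted 4-fold effects, n = 4, dispersion 0.1
  land <- simulate_landscape(tiny_sim(seed = 11))
  res <- differential_count_test(land$counts$ATAC)
  truth <- land$truth$cre_labels
  m <- merge(res, truth, by = "cre")
  expect_gt(m[label == "A-high", mean(class == "A-high")], 0.9)
  expect_gt(m[label == "B-high", mean(class == "B-high")], 0.9)
  expect_lt(m[label == "shared", mean(class != "nonvariable")], 0.05)
  # exactly one class per CRE, partition adds up
  expect_equal(nrow(res), nrow(land$catalogue))
  expect_equal(sum(table(res$class)), nrow(land$catalogue))
  expect_error(differential_count_test(
    signal_matrix(counts[, 1:3], "ATAC", 200L,
                  states = states[1:3])), "2 samples")
})

test_that("BH q-values are monotone in p", {
  set.seed(2)
  p <- runif(200)^2
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("otsu_threshold matches a brute-force variance-minimizing split", {
  set.seed(3)
  x <- c(rnorm(150, 0.1, 0.05), rnorm(100, 3, 0.4))
  th <- otsu_threshold(x)
  # brute force over all candidate midpoints
  xs <- sort(x)
  cands <- (xs[-1] + xs[-length(xs)]) / 2
  wcv <- vapply(cands, function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    (length(lo) - 1) * var(lo) + (length(hi) - 1) * var(hi)
  }, 0)
  expect_equal(th, cands[which.min(wcv)], tolerance = 1e-9)
  expect_true(th > 0.3 && th < 3)
})

test_that("threshold_variance_select drops low-activity CREs then selects variable ones", {
  # bimodal: low mode at 0.1 discarded by the activity cutoff
  set.seed(4)
  n_lo <- 30; n_hi <- 30
  vals <- rbind(matrix(rnorm(n_lo * 8, 0.1, 0.02), n_lo, 8),
                matrix(rnorm(n_hi * 8, 3.0, 0.1), n_hi, 8))
  # a minority of the high rows get a planted between-state difference
  # (the q = 0.75 variance rule can select at most the top quartile)
  vals[1:5 + n_lo, 1:4] <- vals[1:5 + n_lo, 1:4] + 1.5
  rownames(vals) <- sprintf("c%02d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("s%d", 1:8)
  states <- setNames(rep(c("A", "B"), each = 4), colnames(vals))
  sm <- signal_matrix(vals, "H3K4me3", 2000L, normalized = TRUE, states = states)
  res <- threshold_variance_select(sm)
  low <- sprintf("c%02d", 1:n_lo)
  expect_true(all(res[cre %in% low, class] == "nonvariable"))
  planted <- sprintf("c%02d", n_lo + 1:5)
  expect_gt(res[cre %in% planted, mean(class == "A-high")], 0.8)
  # flat rows: at most a stray false selection (rank-sum p < 0.05 occurs by
  # chance in ~3% of rows at n = 4 vs 4)
  flat <- sprintf("c%02d", n_lo + 6:30)
  expect_lte(sum(res[cre %in% flat, class] != "nonvariable"), 1L)

  # all-zero matrix -> nothing selected
  z <- signal_matrix(matrix(0, 5, 8, dimnames = list(paste0("z", 1:5),
                                                     names(states))),
                     "H3K4me3", 2000L, normalized = TRUE, states = states)
  expect_true(all(suppressWarnings(threshold_variance_select(z))$class == "nonvariable"))

  # zero between-state difference is never selected
  same <- matrix(rep(c(3, 3.1, 2.9, 3, 3, 3.1, 2.9, 3), each = 6), 6, 8,
                 byrow = FALSE, dimnames = list(paste0("s", 1:6), names(states)))
  smf <- signal_matrix(same, "H3K4me3", 2000L, normalized = TRUE, states = states)
  expect_true(all(threshold_variance_select(smf)$class == "nonvariable"))
})

test_that("differential fraction reporting uses union semantics", {
  d1 <- data.table::data.table(cre = c("c1", "c2", "c3"), class = c("A-high", "B-high", "nonvariable"))
  d2 <- data.table::data.table(cre = c("c1", "c4"), class = c("B-high", "A-high"))
  fr <- differential_cre_fraction(list(d1, d2), n_total = 10)
  expect_equal(fr$n_differential, 3L)     # c1 counted once
  expect_equal(fr$percent, 30)
  expect_error(percent_of_total(1, 0), "positive")
})
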