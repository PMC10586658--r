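# CRE catalogue construction and per-mark epigenetic-state classification.
#
# The catalogue is built from accessibility peak summits: the top-N peaks
# per cell state are pooled and summits whose merge-radius windows overlap
# are merged transitively. Signal per mark is counted in a mark-specific
# window around each summit, log10-transformed and quantile normalized.
# Classification between the two states uses an NB Wald test for the
# count-like marks (ATAC, H3K27ac) and an activity-threshold + variance
# selection for H3K4me3 / H3K27me3.

#' Merge top peaks per state into a unified CRE catalogue
#'
#' Keeps the `top_n` highest-scoring peaks from each state, pools the
#' summits, and transitively merges summits whose `merge_radius`-wide
#' centred windows overlap (equivalently: summits on the same chromosome
#' closer than `merge_radius`). The merged summit is the rounded mean of
#' the member summits; source states are recorded.
#'
#' @param peaks_by_state named list (state -> peak table as returned by
#'   [read_narrowpeak()], needing `chrom`, `summit`, `score`).
#' @param top_n number of peaks to keep per state, by descending score.
#' @param merge_radius window width in bp for the transitive summit merge.
#' @return a catalogue `data.table` with `cre`, `chrom`, `summit`,
#'   `sources` (comma-joined state labels), sorted by (chrom, summit, cre).
#' @export
merge_top_peaks <- function(peaks_by_state, top_n, merge_radius) {
  stopifnot(is.list(peaks_by_state), !is.null(names(peaks_by_state)))
  pooled <- rbindlist(lapply(names(peaks_by_state), function(st) {
    pk <- as.data.table(peaks_by_state[[st]])
    if (!nrow(pk)) return(NULL)
    if (nrow(pk) < top_n)
      warning("state ", st, ": only ", nrow(pk), " peaks available (top_n = ",
              top_n, "); taking all")
    kept <- head(pk[order(-score)], top_n)
    data.table(chrom = kept$chrom, summit = kept$summit, state = st)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    warning("no peaks supplied; returning empty catalogue")
    return(data.table(cre = character(), chrom = character(),
                      summit = integer(), sources = character()))
  }
  setorder(pooled, chrom, summit, state)
  # transitive chain merge: adjacent summits on one chromosome closer than
  # merge_radius share an overlapping window
  pooled[, cluster := {
    gap <- c(TRUE, diff(summit) >= merge_radius)
    cumsum(gap)
  }, by = chrom]
  cat <- pooled[, .(summit = as.integer(round(mean(summit))),
                    sources = paste(sort(unique(state)), collapse = ",")),
                by = .(chrom, cluster)]
  cat[, cluster := NULL]
  setorder(cat, chrom, summit)
  cat[, cre := sprintf("CRE%05d", .I)]
  setcolorder(cat, c("cre", "chrom", "summit", "sources"))
  cat[]
}

#' Count fragments in mark-specific windows around CRE summits
#'
#' Counts, per sample, fragments overlapping the half-open window
#' `[summit - window/2, summit + window/2)` by at least one base.
#'
#' @param catalogue CRE catalogue from [merge_top_peaks()].
#' @param fragments named list (sample id -> interval table with `chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param mark mark label stored on the result.
#' @param window window width in bp.
#' @return a `signal_matrix` (counts matrix CRE x sample plus metadata).
#' @export
quantify_windows <- function(catalogue, fragments, mark, window) {
  stopifnot(is.list(fragments), !is.null(names(fragments)))
  win <- centered_windows(catalogue$chrom, catalogue$summit, window)
  gr_win <- intervals_to_granges(win)
  known <- unique(catalogue$chrom)
  counts <- matrix(0L, nrow(catalogue), length(fragments),
                   dimnames = list(catalogue$cre, names(fragments)))
  skipped <- 0L
  for (s in names(fragments)) {
    fr <- as.data.table(fragments[[s]])
    if (!nrow(fr)) next
    unknown <- !(fr$chrom %in% known)
    if (any(unknown)) {
      skipped <- skipped + sum(unknown)
      fr <- fr[!unknown]
    }
    if (!nrow(fr)) next
    gr_fr <- intervals_to_granges(fr[, .(chrom, start, end)])
    counts[, s] <- GenomicRanges::countOverlaps(gr_win, gr_fr)
  }
  if (skipped > 0L)
    warning(skipped, " fragment(s) on chromosomes absent from the catalogue were skipped")
  signal_matrix(counts, mark = mark, window = window, normalized = FALSE)
}

#' Signal matrix container
#'
#' @param counts numeric matrix, CREs (or genes) x samples.
#' @param mark mark label (e.g. "ATAC").
#' @param window quantification window in bp.
#' @param normalized logical; raw counts are integer >= 0.
#' @param states optional named character vector sample id -> state label.
#' @return an object of class `signal_matrix`.
#' @export
signal_matrix <- function(counts, mark, window, normalized = FALSE,
                          states = NULL) {
  m <- as.matrix(counts)
  if (!normalized && any(m < 0))
    stop("raw counts must be non-negative")
  structure(list(values = m, mark = mark, window = as.integer(window),
                 normalized = normalized, states = states),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %s (%d bp window), %d features x %d samples, %s\n",
              x$mark, x$window, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Quantile normalization across columns
#'
#' Replaces the value at rank r in each column by the mean over columns of
#' the rank-r values; tied values receive the mean of the reference values
#' at their tied rank positions.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape; every column's sorted values are
#'   identical afterwards.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) return(m)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    sorted <- m[o, j]
    # tied values share the mean of the reference values at their positions
    grp <- cumsum(c(TRUE, sorted[-1L] != sorted[-length(sorted)]))
    out[o, j] <- stats::ave(ref, grp)
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Normalize a raw signal matrix (log10 then quantile)
#'
#' `log10(count + 1)` per cell followed by cross-sample quantile
#' normalization. A single-column matrix is only log-transformed (with a
#' warning): quantile normalization needs >= 2 columns.
#'
#' @param sm a raw `signal_matrix`.
#' @param method `"log10_quantile"` (default) or `"log10"` (no quantile step).
#' @return a normalized `signal_matrix`.
#' @export
normalize_signal <- function(sm, method = c("log10_quantile", "log10")) {
  method <- match.arg(method)
  stopifnot(is(sm, "signal_matrix"))
  if (sm$normalized) stop("signal_matrix is already normalized")
  v <- log10(sm$values + 1)
  if (method == "log10_quantile") {
    if (ncol(v) < 2L)
      warning("single-column matrix: quantile step skipped, log transform only")
    else v <- quantile_normalize(v)
  }
  signal_matrix(v, mark = sm$mark, window = sm$window, normalized = TRUE,
                states = sm$states)
}

#' Differential CRE test for count-like marks (ATAC, H3K27ac)
#'
#' NB Wald test of state A vs state B on raw window counts (see
#' [nb_wald_test()]); BH adjustment; CREs with `padj < padj_threshold` are
#' classed `A-high` or `B-high` by the sign of the A-vs-B log2 fold change,
#' all others `nonvariable`.
#'
#' @param sm raw `signal_matrix` with per-sample states attached (or pass
#'   `states`).
#' @param states named character vector sample id -> state; exactly two
#'   states among the columns used.
#' @param state_a,state_b labels of the two states being compared; `log2fc`
#'   is A relative to B.
#' @param padj_threshold BH-adjusted significance cutoff (default 0.05).
#' @return a `data.table` with `cre`, `mark`, `log2fc`, `p`, `padj`, `class`.
#' @export
differential_count_test <- function(sm, states = sm$states,
                                    state_a = "A", state_b = "B",
                                    padj_threshold = 0.05) {
  stopifnot(is(sm, "signal_matrix"))
  if (sm$normalized) stop("differential_count_test requires raw counts")
  if (is.null(states)) stop("sample states are required")
  keep <- names(states)[states %in% c(state_a, state_b)]
  keep <- intersect(colnames(sm$values), keep)
  cond <- factor(states[keep], levels = c(state_b, state_a))
  tab <- table(cond)
  if (any(tab < 2L)) stop("need >= 2 samples per state")
  res <- nb_wald_test(sm$values[, keep, drop = FALSE], cond)
  out <- data.table(cre = res$feature, mark = sm$mark, log2fc = res$log2fc,
                    p = res$p)
  out[, padj := p.adjust(p, method = "BH")]
  out[, class := "nonvariable"]
  out[padj < padj_threshold & log2fc > 0, class := "A-high"]
  out[padj < padj_threshold & log2fc < 0, class := "B-high"]
  out[]
}

#' Two-class variance-minimizing (Otsu) threshold
#'
#' Brute-force search over midpoints between consecutive sorted unique
#' values for the split minimizing the weighted within-class variance.
#'
#' @param x numeric vector.
#' @return the threshold; values >= threshold fall in the "high" class.
#' @export
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  ux <- unique(x)
  if (length(ux) < 2L) return(ux[1L])
  n <- length(x)
  csum <- cumsum(x); csq <- cumsum(x^2)
  # candidate split after position k: classes x[1..k] / x[(k+1)..n]
  k <- seq_len(n - 1L)
  v1 <- csq[k] - csum[k]^2 / k
  v2 <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
  # only splits at value boundaries are meaningful
  boundary <- x[k] != x[k + 1L]
  wcv <- v1 + v2
  wcv[!boundary] <- Inf
  kbest <- which.min(wcv)
  (x[kbest] + x[kbest + 1L]) / 2
}

#' Activity-threshold + variance selection for H3K4me3 / H3K27me3
#'
#' Two steps on normalized signal: (1) discard CREs whose maximum
#' normalized signal falls below an activity cutoff (default: two-class
#' variance-minimizing split of the pooled signal distribution; an absolute
#' override may be supplied); (2) among retained CREs, select those whose
#' between-state |mean difference| exceeds the `q`-th quantile of the
#' retained CREs' |differences| AND whose two-sided rank-sum p < 0.05.
#' Selected CREs are classed by the sign of the A-minus-B difference.
#'
#' @param sm normalized `signal_matrix`.
#' @param states named character vector sample id -> state.
#' @param state_a,state_b the two states compared.
#' @param activity_cutoff absolute override for step 1 (NA = data-driven).
#' @param variance_quantile step-2 quantile of |mean differences| (default 0.75).
#' @param p_threshold rank-sum p cutoff (default 0.05).
#' @return a `data.table` with `cre`, `mark`, `log2fc` (mean difference of
#'   normalized signal, A minus B), `p`, `padj` (= BH over tested CREs),
#'   `class`.
#' @export
threshold_variance_select <- function(sm, states = sm$states,
                                      state_a = "A", state_b = "B",
                                      activity_cutoff = NA_real_,
                                      variance_quantile = 0.75,
                                      p_threshold = 0.05) {
  stopifnot(is(sm, "signal_matrix"))
  if (!sm$normalized) stop("threshold_variance_select requires normalized signal")
  if (is.null(states)) stop("sample states are required")
  keep <- intersect(colnames(sm$values), names(states)[states %in% c(state_a, state_b)])
  v <- sm$values[, keep, drop = FALSE]
  st <- states[keep]
  empty <- data.table(cre = character(), mark = character(),
                      log2fc = numeric(), p = numeric(), padj = numeric(),
                      class = character())
  if (!nrow(v)) { warning("empty signal matrix"); return(empty) }
  cutoff <- if (is.finite(activity_cutoff)) activity_cutoff else otsu_threshold(as.vector(v))
  active <- apply(v, 1L, max) >= cutoff
  if (!any(active)) {
    warning("all CREs fall below the activity cutoff (", signif(cutoff, 4), ")")
    return(empty)
  }
  va <- v[active, , drop = FALSE]
  ma <- rowMeans(va[, st == state_a, drop = FALSE])
  mb <- rowMeans(va[, st == state_b, drop = FALSE])
  diffs <- ma - mb
  qcut <- quantile(abs(diffs), variance_quantile, names = FALSE)
  pvals <- apply(va, 1L, function(row)
    suppressWarnings(wilcox.test(row[st == state_a], row[st == state_b]))$p.value)
  pvals[!is.finite(pvals)] <- 1
  padj <- p.adjust(pvals, method = "BH")
  sel <- abs(diffs) > qcut & pvals < p_threshold & diffs != 0
  out <- data.table(cre = rownames(va), mark = sm$mark, log2fc = diffs,
                    p = pvals, padj = padj, class = "nonvariable")
  out[sel & diffs > 0, class := "A-high"]
  out[sel & diffs < 0, class := "B-high"]
  # CREs removed in step 1 are reported as nonvariable with p = NA
  if (any(!active)) {
    out <- rbind(out, data.table(cre = rownames(v)[!active], mark = sm$mark,
                                 log2fc = NA_real_, p = NA_real_,
                                 padj = NA_real_, class = "nonvariable"))
  }
  out[match(rownames(v), cre)][]
}

#' Percentage of the catalogue with differential epigenetic signal
#'
#' Union semantics: a CRE counts once however many marks flag it.
#'
#' @param diff_tables one differential table (or a list of per-mark tables)
#'   with columns `cre` and `class`.
#' @param n_total catalogue size.
#' @return list with `n_differential`, `n_total`, `percent`.
#' @export
differential_cre_fraction <- function(diff_tables, n_total) {
  if (is.data.frame(diff_tables)) diff_tables <- list(diff_tables)
  diff_ids <- unique(unlist(lapply(diff_tables, function(d)
    d$cre[d$class %in% c("A-high", "B-high")])))
  list(n_differential = length(diff_ids), n_total = as.integer(n_total),
       percent = percent_of_total(length(diff_ids), n_total))
}

#' Percentage reporting utility
#'
#' @param n_part,n_total counts.
#' @return `100 * n_part / n_total`.
#' @export
percent_of_total <- function(n_part, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * n_part / n_total
}
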