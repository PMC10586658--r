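# CRE-to-gene association: promoter links (closest TSS within 20 kb) and
# enhancer aggregates (distance-weighted sums of all CREs within 100 kb of
# a TSS). The weight curve is a logistic decay anchored so that a CRE at
# the half-weight distance (default 50 kb) contributes half its signal,
# with a full-weight promoter radius (default 2 kb) and a hard zero beyond
# the enhancer window.

#' Distance weight function
#'
#' @param full_weight_radius_bp distance up to which weight is exactly 1
#'   (promoter-proximal CREs count fully; default 2000).
#' @param half_weight_distance_bp distance at which weight is exactly 0.5
#'   (default 50000).
#' @param max_distance_bp hard cutoff; weight 0 beyond it (default 100000).
#' @return an object of class `weight_function`, callable via
#'   [distance_weight()].
#' @export
weight_function <- function(full_weight_radius_bp = 2000,
                            half_weight_distance_bp = 50000,
                            max_distance_bp = 100000) {
  if (half_weight_distance_bp <= full_weight_radius_bp)
    stop("half_weight_distance_bp must exceed full_weight_radius_bp")
  if (max_distance_bp < half_weight_distance_bp)
    stop("max_distance_bp must be >= half_weight_distance_bp")
  # solve 2 exp(-mu x) / (1 + exp(-mu x)) = 1/2 at x = half - r0:
  # exp(-mu x) = 1/3, so mu = log(3) / (half - r0)
  mu <- log(3) / (half_weight_distance_bp - full_weight_radius_bp)
  structure(list(r0 = full_weight_radius_bp,
                 half = half_weight_distance_bp,
                 dmax = max_distance_bp, mu = mu),
            class = "weight_function")
}

#' Evaluate the distance weight
#'
#' w(d) = 1 for d <= r0; 2 exp(-mu (d - r0)) / (1 + exp(-mu (d - r0))) for
#' r0 < d <= dmax (mu anchored so w(half-weight distance) = 0.5); 0 beyond
#' dmax. Monotone non-increasing, values in [0, 1].
#'
#' @param d non-negative distance(s) in bp.
#' @param wf a [weight_function()].
#' @return numeric vector of weights in `[0, 1]`.
#' @export
distance_weight <- function(d, wf = weight_function()) {
  if (any(d < 0)) stop("distance must be non-negative")
  x <- pmax(d - wf$r0, 0)
  e <- exp(-wf$mu * x)
  w <- 2 * e / (1 + e)
  w[d <= wf$r0] <- 1
  w[d > wf$dmax] <- 0
  w
}

#' Link each CRE to its closest TSS within a distance cap
#'
#' Distance is |TSS - summit|; ties are broken by the lexicographically
#' smaller gene id; CREs with no TSS within `max_bp` are omitted.
#'
#' @param catalogue CRE catalogue (`cre`, `chrom`, `summit`).
#' @param genes gene annotation (`gene`, `chrom`, `tss`).
#' @param max_bp maximum link distance (default 20000).
#' @return a `data.table` with `cre`, `gene`, `distance` (signed,
#'   TSS - summit), sorted by (chrom, summit, cre).
#' @export
link_closest_tss <- function(catalogue, genes, max_bp = 20000) {
  catalogue <- as.data.table(catalogue)
  genes <- as.data.table(genes)
  if (!nrow(catalogue) || !nrow(genes))
    return(data.table(cre = character(), gene = character(),
                      distance = integer()))
  g <- genes[order(chrom, tss, gene)]
  out <- vector("list", 0L)
  for (ch in unique(catalogue$chrom)) {
    cc <- catalogue[chrom == ch]
    gg <- g[chrom == ch]
    if (!nrow(gg)) next
    # nearest TSS by binary search over the sorted TSS vector; a tie between
    # the two flanking TSSs resolves to the smaller gene id
    pos <- findInterval(cc$summit, gg$tss)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, nrow(gg))
    dlo <- abs(cc$summit - gg$tss[lo]); dhi <- abs(cc$summit - gg$tss[hi])
    # remap to the first gene at each TSS so equal-TSS duplicates resolve to
    # the lexicographically smaller id (table is sorted by tss then gene)
    lo <- match(gg$tss[lo], gg$tss); hi <- match(gg$tss[hi], gg$tss)
    pick <- ifelse(dlo < dhi, lo,
            ifelse(dhi < dlo, hi,
                   ifelse(gg$gene[lo] <= gg$gene[hi], lo, hi)))
    d <- gg$tss[pick] - cc$summit
    keep <- abs(d) <= max_bp
    if (any(keep))
      out[[length(out) + 1L]] <- data.table(cre = cc$cre[keep],
                                            gene = gg$gene[pick][keep],
                                            distance = as.integer(d[keep]),
                                            chrom = ch,
                                            summit = cc$summit[keep])
  }
  if (!length(out))
    return(data.table(cre = character(), gene = character(),
                      distance = integer()))
  res <- rbindlist(out)
  setorder(res, chrom, summit, cre)
  res[, .(cre, gene, distance)]
}

#' Distance-weighted enhancer signal per gene
#'
#' For every gene and sample, sums `w(|TSS - summit|) * signal` over all
#' catalogue CREs within `wf$dmax` of the TSS. Genes with no CRE in range
#' get 0 (and `n_cres` 0).
#'
#' @param catalogue CRE catalogue (`cre`, `chrom`, `summit`).
#' @param sm normalized `signal_matrix` whose rows cover the catalogue.
#' @param genes gene annotation (`gene`, `chrom`, `tss`).
#' @param wf a [weight_function()].
#' @return list with `summary` (matrix genes x samples of weighted sums)
#'   and `n_cres` (named integer vector of contributing CREs per gene).
#' @export
aggregate_enhancer_signal <- function(catalogue, sm, genes,
                                      wf = weight_function()) {
  stopifnot(is(sm, "signal_matrix"))
  catalogue <- as.data.table(catalogue)
  genes <- as.data.table(genes)
  v <- sm$values[catalogue$cre, , drop = FALSE]
  out <- matrix(0, nrow(genes), ncol(v),
                dimnames = list(genes$gene, colnames(v)))
  ncre <- setNames(integer(nrow(genes)), genes$gene)
  if (nrow(catalogue)) {
    gr_tss <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = pmax(genes$tss - wf$dmax, 0L) + 1L,
                                end = genes$tss + wf$dmax + 1L))
    gr_sum <- points_to_granges(catalogue$chrom, catalogue$summit)
    hits <- GenomicRanges::findOverlaps(gr_tss, gr_sum)
    if (length(hits)) {
      gi <- S4Vectors::queryHits(hits)
      ci <- S4Vectors::subjectHits(hits)
      d <- abs(genes$tss[gi] - catalogue$summit[ci])
      keep <- d <= wf$dmax
      gi <- gi[keep]; ci <- ci[keep]; d <- d[keep]
      w <- distance_weight(d, wf)
      contrib <- v[ci, , drop = FALSE] * w
      agg <- rowsum(contrib, gi)           # rows named by gene index
      ridx <- as.integer(rownames(agg))
      out[ridx, ] <- out[ridx, , drop = FALSE] + agg
      tab <- table(gi)
      ncre[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  list(summary = out, n_cres = ncre)
}
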