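# Coordinate conventions
#
# All interval logic in this package is 0-based half-open [start, end), the
# BED convention. Bioconductor's IRanges/GenomicRanges are 1-based closed;
# the two converters below are the only place that shift happens, so every
# overlap, nearest and distance computation funnels through one tested
# boundary.

#' Construct a validated genomic interval table
#'
#' Intervals are 0-based half-open `[start, end)`. This is the package-wide
#' convention; text formats that use other conventions are converted at the
#' reader/writer boundary.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand strand of each interval, one of `"+"`, `"-"`, `"."`.
#' @return a `data.table` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)))
  validate_intervals(dt)
  dt
}

validate_intervals <- function(dt) {
  if (any(!nzchar(dt$chrom)) || anyNA(dt$chrom))
    stop("interval chrom must be non-empty")
  if (anyNA(dt$start) || anyNA(dt$end))
    stop("interval start/end must be non-missing integers")
  if (any(dt$start < 0L))
    stop("interval start must be >= 0")
  if (any(dt$start >= dt$end))
    stop("intervals must satisfy start < end (0-based half-open)")
  bad <- setdiff(unique(dt$strand), c("+", "-", "."))
  if (length(bad))
    stop("invalid strand value(s): ", paste(bad, collapse = ", "))
  invisible(dt)
}

#' Convert a 0-based half-open interval table to GRanges
#'
#' The single place where the +1 shift to Bioconductor's 1-based closed
#' convention happens.
#'
#' @param dt a table with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `strand`.
#' @return a [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(dt) {
  strand <- if ("strand" %in% names(dt)) ifelse(dt$strand == ".", "*", dt$strand) else "*"
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = strand
  )
}

#' Convert GRanges back to a 0-based half-open interval table
#'
#' Inverse of [intervals_to_granges()].
#'
#' @param gr a `GRanges` object.
#' @return a `data.table` with `chrom`, `start`, `end`, `strand`.
#' @export
granges_to_intervals <- function(gr) {
  st <- as.character(GenomicRanges::strand(gr))
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(st == "*", ".", st)
  )
}

# Point positions (summits, TSSs) as width-1 intervals.
points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}

# Mark-specific window [pos - w/2, pos + w/2) around a 0-based point,
# clipped at 0. Even widths are centred per the summit-window convention.
centered_windows <- function(chrom, pos, window) {
  half <- window %/% 2L
  s <- pmax(0L, as.integer(pos) - half)
  e <- as.integer(pos) + (window - half)
  data.table(chrom = as.character(chrom), start = s, end = e, strand = ".")
}
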