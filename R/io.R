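# Readers and writers for the plain-text formats the pipeline consumes:
# ENCODE narrowPeak, BED6/TSV gene annotation, TSV signal matrices
# (header = sample ids, first column = feature id), plain gene lists, and
# JSON for network edges. All writers emit deterministically ordered,
# full-precision output so identical runs are byte-identical.

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4; column 10 is the summit offset from `start`
#' (-1 when no summit was called, in which case the interval midpoint is
#' used). Coordinates are 0-based half-open as in BED.
#'
#' @param path path to a narrowPeak file.
#' @return a `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `pvalue`, `qvalue`, `summit_offset` and
#'   the derived absolute `summit`. Input order is preserved.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), signal = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      summit_offset = integer(), summit = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L))
    stop("malformed narrowPeak line ", which(nf < 10L)[1L],
         ": expected >= 10 tab-separated columns, found ", nf[nf < 10L][1L])
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  dt <- data.table(
    chrom = m[, 1L],
    start = suppressWarnings(as.integer(m[, 2L])),
    end = suppressWarnings(as.integer(m[, 3L])),
    name = m[, 4L],
    score = suppressWarnings(as.numeric(m[, 5L])),
    strand = m[, 6L],
    signal = suppressWarnings(as.numeric(m[, 7L])),
    pvalue = suppressWarnings(as.numeric(m[, 8L])),
    qvalue = suppressWarnings(as.numeric(m[, 9L])),
    summit_offset = suppressWarnings(as.integer(m[, 10L]))
  )
  bad <- which(is.na(dt$start) | is.na(dt$end) | is.na(dt$summit_offset))
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], ": non-numeric coordinate")
  validate_intervals(dt[, .(chrom, start, end, strand)])
  over <- which(dt$summit_offset >= dt$end - dt$start)
  if (length(over))
    stop("narrowPeak line ", over[1L], ": summit offset ",
         dt$summit_offset[over[1L]], " >= peak length ",
         (dt$end - dt$start)[over[1L]])
  if (any(dt$summit_offset < -1L))
    stop("narrowPeak summit offset must be >= -1")
  dt[, summit := ifelse(summit_offset == -1L,
                        as.integer(floor((start + end) / 2)),
                        start + summit_offset)]
  dt[]
}

#' Write peaks as narrowPeak
#'
#' @param peaks a table with at least `chrom`, `start`, `end`; missing
#'   optional columns are filled with narrowPeak placeholders.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  dt <- as.data.table(peaks)
  n <- nrow(dt)
  fill <- function(col, default) if (col %in% names(dt)) dt[[col]] else rep(default, n)
  out <- data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = fill("name", "."), score = fill("score", 0),
    strand = fill("strand", "."), signal = fill("signal", 0),
    pvalue = fill("pvalue", -1), qvalue = fill("qvalue", -1),
    summit_offset = if ("summit" %in% names(dt) && !"summit_offset" %in% names(dt))
      dt$summit - dt$start else fill("summit_offset", -1L)
  )
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation with strand-aware TSS
#'
#' Accepts BED6 (`chrom start end gene score strand`) or a 5-column TSV
#' (`gene chrom start end strand`), both 0-based half-open. The TSS is the
#' first transcribed base: `start` on the + strand, `end - 1` on the -
#' strand.
#'
#' @param path file path.
#' @return a `data.table` with `gene`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, keyed by gene id.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) == 6L && is.numeric(dt[[2L]]) && is.numeric(dt[[3L]])) {
    setnames(dt, 1:6, c("chrom", "start", "end", "gene", "score", "strand"))
  } else if (ncol(dt) >= 5L && is.numeric(dt[[3L]]) && is.numeric(dt[[4L]])) {
    dt <- dt[, 1:5]
    setnames(dt, 1:5, c("gene", "chrom", "start", "end", "strand"))
  } else {
    stop("gene annotation must be BED6 or a 5-column TSV (gene chrom start end strand)")
  }
  dt[, `:=`(gene = as.character(gene), chrom = as.character(chrom),
            start = as.integer(start), end = as.integer(end),
            strand = as.character(strand))]
  gene_annotation(dt)
}

#' Build a validated gene annotation table
#'
#' @param dt a table with `gene`, `chrom`, `start`, `end`, `strand`.
#' @return the table with a derived `tss` column, sorted by (chrom, tss, gene).
#' @export
gene_annotation <- function(dt) {
  dt <- as.data.table(dt)
  if (anyNA(dt$strand) || !all(dt$strand %in% c("+", "-")))
    stop("gene annotation requires strand '+' or '-' for every gene")
  validate_intervals(dt[, .(chrom, start, end, strand)])
  if (anyDuplicated(dt$gene))
    stop("duplicate gene id(s): ",
         paste(unique(dt$gene[duplicated(dt$gene)]), collapse = ", "))
  dt[, tss := ifelse(strand == "+", start, end - 1L)]
  setorder(dt, chrom, tss, gene)
  dt[]
}

#' Read / write a signal matrix TSV
#'
#' Layout: header row of sample ids, first column the feature id. Values
#' are written at full precision; write-then-read round-trips exactly.
#'
#' @param path file path.
#' @return `read_matrix_tsv()` returns a numeric matrix with feature
#'   rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m a numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param id_col name for the feature-id column in the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  dt <- data.table(id = rownames(m))
  setnames(dt, "id", id_col)
  dt <- cbind(dt, as.data.table(m))
  fwrite(format_full_precision(dt), path, sep = "\t", quote = FALSE)
  invisible(path)
}

# %.17g renders doubles so that read-back reproduces the exact binary value
format_full_precision <- function(dt) {
  dt <- copy(as.data.table(dt))
  for (col in names(dt)) {
    x <- dt[[col]]
    if (is.double(x)) dt[, (col) := sprintf("%.17g", x)]
  }
  dt
}

#' Read / write a plain-text gene list (one id per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write / read a generic TSV table at full precision
#' @param dt a data.frame / data.table.
#' @param path file path.
#' @export
write_table_tsv <- function(dt, path) {
  fwrite(format_full_precision(dt), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  fread(path, header = TRUE, sep = "\t")
}

#' Write / read network edges or structured results as JSON
#' @param x a list or data.frame.
#' @param path file path.
#' @export
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_json_artifact
#' @export
read_json_artifact <- function(path) {
  if (!file.exists(path)) stop("JSON artifact not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
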