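#' Default pipeline configuration
#'
#' Returns the full set of tunable pipeline parameters with their defaults.
#' Window sizes follow the mark-specific quantification widths (ATAC 200 bp
#' around the summit; H3K4me3 and H3K27ac 2 kb; the broad repressive
#' H3K27me3 mark 5 kb). Promoter links use the closest TSS within 20 kb;
#' enhancer aggregation uses a 100 kb window with logistic distance decay.
#'
#' @param ... named overrides for any default field.
#' @return a named list of class `regcircuit_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(top_n_peaks = 1000)
#' cfg$window_bp_by_mark$ATAC
pipeline_config <- function(...) {
  cfg <- list(
    window_bp_by_mark = list(ATAC = 200L, H3K4me3 = 2000L,
                             H3K27ac = 2000L, H3K27me3 = 5000L),
    top_n_peaks = 100000L,
    merge_radius_bp = 200L,
    promoter_link_max_bp = 20000L,
    enhancer_window_bp = 100000L,
    full_weight_radius_bp = 2000L,
    half_weight_distance_bp = 50000L,
    cre_padj_threshold = 0.05,
    variance_select_quantile = 0.75,
    activity_cutoff = NA_real_,   # NA = two-class variance-minimizing split
    de_padj_threshold = 0.01,
    de_abs_log2fc_threshold = 0.58,
    min_gene_counts = 10L,
    influence_shared_threshold = 0.5,
    influence_low_threshold = 0.2,
    max_differential_edges = 500000L,
    enrichment_fdr_threshold = 0.1,
    gsea_permutations = 10000L,
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg <- normalize_config_types(cfg)
  validate_config(cfg)
  class(cfg) <- c("regcircuit_config", "list")
  cfg
}

normalize_config_types <- function(cfg) {
  ints <- c("top_n_peaks", "merge_radius_bp", "promoter_link_max_bp",
            "enhancer_window_bp", "full_weight_radius_bp",
            "half_weight_distance_bp", "min_gene_counts",
            "max_differential_edges", "gsea_permutations", "rng_seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$window_bp_by_mark <- lapply(cfg$window_bp_by_mark, as.integer)
  reals <- c("cre_padj_threshold", "variance_select_quantile",
             "activity_cutoff", "de_padj_threshold",
             "de_abs_log2fc_threshold", "influence_shared_threshold",
             "influence_low_threshold", "enrichment_fdr_threshold")
  for (f in reals) {
    v <- as.numeric(cfg[[f]])
    cfg[[f]] <- if (length(v)) v else NA_real_   # JSON null -> NA
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a configuration list from [pipeline_config()] or [read_config()].
#' @return the config, invisibly; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (any(unlist(cfg$window_bp_by_mark) <= 0L))
    stop("all mark windows must be > 0")
  for (f in c("top_n_peaks", "merge_radius_bp", "promoter_link_max_bp",
              "enhancer_window_bp", "max_differential_edges",
              "min_gene_counts"))
    if (cfg[[f]] <= 0L) stop(f, " must be > 0")
  for (f in c("cre_padj_threshold", "de_padj_threshold",
              "enrichment_fdr_threshold", "variance_select_quantile")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop(f, " must lie in (0, 1)")
  }
  if (cfg$de_abs_log2fc_threshold < 0)
    stop("de_abs_log2fc_threshold must be >= 0")
  for (f in c("influence_shared_threshold", "influence_low_threshold")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$half_weight_distance_bp <= cfg$full_weight_radius_bp)
    stop("half_weight_distance_bp must exceed full_weight_radius_bp")
  invisible(cfg)
}

#' Read / write a pipeline configuration (JSON)
#'
#' The config file is a flat declarative JSON document; round-trips are
#' lossless (`write_config()` then `read_config()` reproduces every field).
#'
#' @param path file path.
#' @return `read_config()` returns a validated `regcircuit_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$window_bp_by_mark <- as.list(raw$window_bp_by_mark)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a `regcircuit_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# Stable hash of a config for the stage log: md5 of its canonical JSON text.
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                          na = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}
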