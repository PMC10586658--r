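# Synthetic two-state (plus reference) regulatory landscape with planted
# effects. The generator emulates the statistical structure the analysis
# assumes -- a miniature genome with genes, CREs carrying negative-binomial
# per-mark counts with planted shared/differential elements, TF expression
# programs with planted shared and cell-type-specific regulators, motif
# hits concentrated in the planted regulators' active CREs, and TF peak
# sets with planted excess binding near a disease gene list -- so that
# every pipeline stage can be exercised against known ground truth.
#
# Negative-binomial parameterization throughout: Var = mu + alpha mu^2.

#' Simulation configuration
#'
#' Defaults describe a miniature of the real design: two chromosomes of
#' 50 Mb holding 1000 genes (about one gene per 100 kb, the human-genome
#' density, so planted programs stay a realistic minority of the
#' transcriptome and enhancer windows rarely span several genes),
#' 1200 CREs, 4 samples per state (A, B, REF), 30% of
#' CREs differential per mark at a 4-fold planted effect, dispersion 0.1,
#' one A-specific and one B-specific master TF plus four shared
#' epithelial TFs among 30 TFs, motif hits at background rate 2% vs 60%
#' in a program's own CREs, fanout 25 targets per program TF, a 25-gene
#' disease list bound in excess (4x) by the designated disease TF.
#'
#' @param ... named overrides of any field.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chroms = 2L, chrom_length_bp = 50000000L,
    n_genes = 1000L, n_cres = 5000L,
    n_samples_per_state = 4L,
    states = c(A = "A", B = "B", REF = "REF"),
    frac_differential_cre = 0.3,
    cre_effect_log2fc = 2.0,
    ref_cre_effect_log2fc = 6.0,
    nb_dispersion = 0.1,
    nb_mean_scale = 50,
    expr_mean_scale = 400,
    n_tfs = 30L,
    n_shared_tfs = 4L, n_A_specific_tfs = 1L, n_B_specific_tfs = 1L,
    n_ref_specific_tfs = 2L,
    expr_effect_log2fc = 2.0,
    shared_effect_log2fc = 1.8,
    motif_hit_background_rate = 0.01,
    motif_hit_target_rate = 0.8,
    tf_target_fanout = 25L,
    cres_per_target = 4L,
    n_disease_genes = 25L,
    disease_binding_effect = 4,
    peak_rate = 0.15,
    batch_effect_log2 = 0.5,
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_sim_config(cfg)
  class(cfg) <- c("sim_config", "list")
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c("frac_differential_cre", "motif_hit_background_rate",
             "motif_hit_target_rate", "peak_rate")
  for (f in rates)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$motif_hit_target_rate <= cfg$motif_hit_background_rate)
    stop("motif_hit_target_rate must exceed motif_hit_background_rate")
  for (f in c("cre_effect_log2fc", "expr_effect_log2fc", "nb_dispersion",
              "nb_mean_scale", "disease_binding_effect"))
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  for (f in c("n_chroms", "chrom_length_bp", "n_genes", "n_cres",
              "n_samples_per_state", "n_tfs", "tf_target_fanout",
              "n_disease_genes"))
    if (cfg[[f]] < 1L) stop(f, " must be positive")
  if (cfg$n_shared_tfs + cfg$n_A_specific_tfs + cfg$n_B_specific_tfs +
        cfg$n_ref_specific_tfs > cfg$n_tfs)
    stop("program TFs exceed n_tfs")
  if (cfg$n_cres > cfg$n_chroms * (cfg$chrom_length_bp / 100))
    stop("n_cres too large for the genome")
  invisible(cfg)
}

rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate the regulatory landscape
#'
#' Generates the gene annotation (with TF designations and target
#' programs), the CRE catalogue (A-active CREs placed preferentially
#' within the enhancer window of A-program gene TSSs, likewise B and
#' shared), per-mark raw count matrices for states A, B and REF, the
#' motif-hit matrix (hits concentrated in each program TF's own active
#' CREs), and the ground truth. Differential CREs are assigned
#' deterministically by index before noise: exactly
#' `round(frac_differential_cre * n_cres)` per mark, split evenly between
#' A-high and B-high.
#'
#' Mark means: a planted CRE has mean `mu 2^(+e/2)` in its favored state
#' and `mu 2^(-e/2)` in the other; the reference state sits at the low
#' mean for any planted (A-high, B-high or shared-epithelial) CRE.
#' Shared-epithelial CREs are high in both A and B (so they are
#' "nonvariable" between A and B but differential against REF).
#'
#' @param cfg a [sim_config()].
#' @return list with `genes`, `catalogue`, `counts` (mark -> raw
#'   `signal_matrix`), `motif_hits`, `states` (sample -> state),
#'   `truth` (ground-truth list).
#' @export
simulate_landscape <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$rng_seed)
  marks <- c("ATAC", "H3K4me3", "H3K27ac", "H3K27me3")

  ## --- genes, TFs, programs -------------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  gchrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  gtss <- as.integer(runif(cfg$n_genes, 1000, cfg$chrom_length_bp - 1000))
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_ids <- c(sprintf("TF%03d", seq_len(cfg$n_tfs)),
                sprintf("g%04d", seq_len(cfg$n_genes - cfg$n_tfs)))
  genes <- gene_annotation(data.table(
    gene = gene_ids, chrom = gchrom,
    start = ifelse(gstrand == "+", gtss, pmax(gtss - 1999L, 0L)),
    end = ifelse(gstrand == "+", gtss + 2000L, gtss + 1L),
    strand = gstrand))
  tf_ids <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  shared_tfs <- tf_ids[seq_len(cfg$n_shared_tfs)]
  a_tfs <- tf_ids[cfg$n_shared_tfs + seq_len(cfg$n_A_specific_tfs)]
  b_tfs <- tf_ids[cfg$n_shared_tfs + cfg$n_A_specific_tfs +
                    seq_len(cfg$n_B_specific_tfs)]
  # the reference state carries its own regulatory program (a distant cell
  # state is not an empty landscape): REF-active CREs and REF-high targets
  ref_tfs <- tf_ids[cfg$n_shared_tfs + cfg$n_A_specific_tfs +
                      cfg$n_B_specific_tfs + seq_len(cfg$n_ref_specific_tfs)]
  prog_tfs <- c(shared_tfs, a_tfs, b_tfs, ref_tfs)
  tf_class <- setNames(rep("bystander", cfg$n_tfs), tf_ids)
  tf_class[shared_tfs] <- "shared"
  tf_class[a_tfs] <- "A-specific"
  tf_class[b_tfs] <- "B-specific"
  tf_class[ref_tfs] <- "REF-specific"

  nontf <- setdiff(gene_ids, tf_ids)
  need <- length(prog_tfs) * cfg$tf_target_fanout
  if (need > length(nontf))
    stop("tf_target_fanout too large for the number of non-TF genes")
  pool <- sample(nontf, need)
  edges <- data.table(
    tf = rep(prog_tfs, each = cfg$tf_target_fanout),
    target = pool)
  edges[, label := tf_class[tf]]

  ## -- derived pool sizes for planted non-differential CRE sets ---------
  n_epi_want <- length(shared_tfs) * cfg$tf_target_fanout * cfg$cres_per_target
  n_ref_want <- length(ref_tfs) * cfg$tf_target_fanout * cfg$cres_per_target

  ## --- CRE labels (deterministic by index), then placement ------------
  n_diff <- round(cfg$frac_differential_cre * cfg$n_cres)
  n_a <- n_diff %/% 2L; n_b <- n_diff - n_a
  lab <- rep("shared", cfg$n_cres)
  if (n_diff > 0) lab[seq_len(n_diff)] <- rep(c("A-high", "B-high"), c(n_a, n_b))
  # a slice of the non-differential CREs forms the shared-epithelial set
  # (high in A and B, low in REF) feeding the shared-TF programs; its size
  # gives shared programs the same planted-CRE density per target as the
  # cell-type-specific programs
  n_nondiff <- sum(lab == "shared")
  n_epi <- min(n_epi_want, n_nondiff %/% 2L)
  epi <- rep(FALSE, cfg$n_cres)
  if (n_epi > 0) epi[n_diff + seq_len(n_epi)] <- TRUE
  # REF-program CREs: active only in the reference state
  n_refcre <- min(n_ref_want, (n_nondiff - n_epi) %/% 2L)
  refcre <- rep(FALSE, cfg$n_cres)
  if (n_refcre > 0) refcre[n_diff + n_epi + seq_len(n_refcre)] <- TRUE

  # every (program TF, target) pair receives cres_per_target CREs placed
  # within the enhancer window of the target's TSS, drawn from the pool of
  # that program's planted CREs; leftover pool CREs stay uniform (planted
  # differential signal without a targeted motif)
  assign_pool <- function(tf_set, pool_idx) {
    if (!length(tf_set) || !length(pool_idx)) return(NULL)
    slots <- edges[tf %in% tf_set]
    slots <- slots[rep(seq_len(nrow(slots)), each = cfg$cres_per_target)]
    n <- min(nrow(slots), length(pool_idx))
    slots <- slots[seq_len(n)]
    gi <- match(slots$target, genes$gene)
    offset <- as.integer(runif(n, -50000, 50000))
    data.table(idx = pool_idx[seq_len(n)], assigned_tf = slots$tf,
               chrom = genes$chrom[gi],
               summit = pmin(pmax(genes$tss[gi] + offset, 200L),
                             cfg$chrom_length_bp - 200L))
  }
  ia <- which(lab == "A-high"); ib <- which(lab == "B-high")
  ie <- which(epi); ir <- which(refcre)
  placed <- rbindlist(list(assign_pool(a_tfs, ia), assign_pool(b_tfs, ib),
                           assign_pool(shared_tfs, ie),
                           assign_pool(ref_tfs, ir)))
  # unassigned CREs: half gene-proximal (regulatory elements cluster near
  # genes), half uniform intergenic background
  near_gene <- runif(cfg$n_cres) < 0.5
  gpick <- sample.int(cfg$n_genes, cfg$n_cres, replace = TRUE)
  goffset <- as.integer(runif(cfg$n_cres, -50000, 50000))
  pos <- data.table(idx = seq_len(cfg$n_cres),
                    assigned_tf = NA_character_,
                    chrom = ifelse(near_gene, genes$chrom[gpick],
                                   sample(chroms, cfg$n_cres, replace = TRUE)),
                    summit = as.integer(ifelse(
                      near_gene,
                      pmin(pmax(genes$tss[gpick] + goffset, 200L),
                           cfg$chrom_length_bp - 200L),
                      as.integer(runif(cfg$n_cres, 200,
                                       cfg$chrom_length_bp - 200)))))
  if (nrow(placed)) pos[placed$idx, `:=`(assigned_tf = placed$assigned_tf,
                                         chrom = placed$chrom,
                                         summit = placed$summit)]
  pos[, `:=`(lab = lab, epi = epi, refcre = refcre)]
  setorder(pos, chrom, summit, idx)
  pos[, cre := sprintf("CRE%05d", .I)]
  catalogue <- pos[, .(cre, chrom, summit,
                       sources = ifelse(lab == "A-high", "A",
                                 ifelse(lab == "B-high", "B", "A,B")))]

  ## --- per-mark counts -------------------------------------------------
  nS <- cfg$n_samples_per_state
  sample_ids <- c(sprintf("A_%d", 1:nS), sprintf("B_%d", 1:nS),
                  sprintf("REF_%d", 1:nS))
  states <- setNames(rep(c("A", "B", "REF"), each = nS), sample_ids)
  e2 <- 2^(cfg$cre_effect_log2fc / 2)
  # planted CREs are closed in the lineage-distant reference state
  eref <- 2^(cfg$ref_cre_effect_log2fc / 2)
  base_mu <- cfg$nb_mean_scale * 2^rnorm(cfg$n_cres, 0, 0.25)
  state_mu <- function(lab, epi, refcre) {
    up <- base_mu * e2; dn <- base_mu / e2; closed <- base_mu / eref
    mu_a <- ifelse(refcre, closed,
            ifelse(lab == "A-high" | epi, up,
            ifelse(lab == "B-high", dn, base_mu)))
    mu_b <- ifelse(refcre, closed,
            ifelse(lab == "B-high" | epi, up,
            ifelse(lab == "A-high", dn, base_mu)))
    mu_r <- ifelse(refcre, up,
            ifelse(lab != "shared" | epi, closed, base_mu))
    cbind(A = mu_a, B = mu_b, REF = mu_r)
  }
  mus <- state_mu(pos$lab, pos$epi, pos$refcre)
  counts <- list()
  for (mk in marks) {
    mscale <- c(ATAC = 1, H3K4me3 = 1.2, H3K27ac = 1, H3K27me3 = 0.8)[[mk]]
    m <- matrix(0L, cfg$n_cres, length(sample_ids),
                dimnames = list(pos$cre, sample_ids))
    for (s in sample_ids) {
      mu_s <- mus[, states[[s]]] * mscale
      # H3K27me3 marks repression: its planted signal is anti-correlated
      # with activity (high where the element is inactive)
      if (mk == "H3K27me3") {
        hi <- base_mu * mscale * e2; lo <- base_mu * mscale / e2
        mu_act <- mus[, states[[s]]]
        mu_s <- ifelse(pos$lab == "shared" & !pos$epi & !pos$refcre,
                       base_mu * mscale,
                       ifelse(mu_act > base_mu, lo, hi))
      }
      m[, s] <- rnb(cfg$n_cres, mu_s, cfg$nb_dispersion)
    }
    counts[[mk]] <- signal_matrix(
      m, mark = mk,
      window = c(ATAC = 200L, H3K4me3 = 2000L, H3K27ac = 2000L,
                 H3K27me3 = 5000L)[[mk]],
      normalized = FALSE, states = states)
  }

  ## --- motif hits -------------------------------------------------------
  hits <- matrix(rbinom(cfg$n_cres * cfg$n_tfs, 1L,
                        cfg$motif_hit_background_rate),
                 cfg$n_cres, cfg$n_tfs,
                 dimnames = list(pos$cre, tf_ids))
  prog_rows <- which(!is.na(pos$assigned_tf))
  if (length(prog_rows)) {
    hit_draw <- rbinom(length(prog_rows), 1L, cfg$motif_hit_target_rate)
    hits[cbind(prog_rows, match(pos$assigned_tf[prog_rows], tf_ids))] <- hit_draw
  }

  truth <- list(
    all_genes = genes$gene,
    cre_labels = pos[, .(cre, label = lab, epithelial = epi,
                         ref_active = refcre, assigned_tf = assigned_tf)],
    n_differential_per_mark = n_diff,
    tf_classes = data.table(tf = tf_ids, class = unname(tf_class)),
    edges = edges,
    shared_tfs = shared_tfs, a_tfs = a_tfs, b_tfs = b_tfs,
    ref_tfs = ref_tfs)

  list(genes = genes, catalogue = catalogue, counts = counts,
       motif_hits = hits, states = states, truth = truth, cfg = cfg)
}

#' Simulate expression counts and TPM from a landscape
#'
#' Program TFs and their targets are over-expressed in the states where
#' their program is active. Cell-type-specific programs: up by
#' `expr_effect_log2fc/2` in their own state, down by the same amount in
#' the sister state AND in REF (a cell-type-specific gene is off in any
#' other state, so its sister-vs-REF contrast is null and the A-vs-B and
#' A-vs-REF log2FC both equal `expr_effect_log2fc`). Shared programs: up
#' `shared_effect_log2fc/2` in both A and B, down the same amount in REF;
#' REF-program genes mirror this in the reference state.
#' Bystander genes have equal means everywhere. A two-level
#' batch factor crossed with state adds `batch_effect_log2` on the log2
#' scale; counts are negative binomial.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_landscape()].
#' @param seed optional seed (defaults to `cfg$rng_seed + 1` so landscape
#'   and expression draws are independent streams).
#' @return list with `counts` (matrix genes x samples), `tpm`, `samples`
#'   (`data.table`: sample, state, batch).
#' @export
simulate_expression <- function(cfg, truth, seed = cfg$rng_seed + 1L) {
  set.seed(seed)
  nS <- cfg$n_samples_per_state
  sample_ids <- c(sprintf("A_%d", 1:nS), sprintf("B_%d", 1:nS),
                  sprintf("REF_%d", 1:nS))
  st <- rep(c("A", "B", "REF"), each = nS)
  batch <- rep_len(c("b1", "b2"), length(sample_ids))
  gene_ids <- truth$all_genes
  prog_of <- setNames(rep("none", length(gene_ids)), gene_ids)
  prog_of[truth$shared_tfs] <- "shared"
  prog_of[truth$a_tfs] <- "A"
  prog_of[truth$b_tfs] <- "B"
  prog_of[truth$ref_tfs] <- "REF"
  tgt_prog <- truth$edges[, .(p = label[1L]), by = target]
  prog_of[tgt_prog$target] <- c(shared = "shared", `A-specific` = "A",
                                `B-specific` = "B",
                                `REF-specific` = "REF")[tgt_prog$p]
  e_spec <- 2^(cfg$expr_effect_log2fc / 2)
  e_shared <- 2^(cfg$shared_effect_log2fc / 2)
  base_mu <- cfg$expr_mean_scale * 2^rnorm(length(gene_ids), 0, 0.5)
  mu_for <- function(state) {
    up_a <- prog_of == "A"; up_b <- prog_of == "B"
    sh <- prog_of == "shared"; rf <- prog_of == "REF"
    mu <- base_mu
    if (state == "A") {
      mu[up_a] <- mu[up_a] * e_spec; mu[up_b] <- mu[up_b] / e_spec
      mu[sh] <- mu[sh] * e_shared; mu[rf] <- mu[rf] / e_shared
    } else if (state == "B") {
      mu[up_b] <- mu[up_b] * e_spec; mu[up_a] <- mu[up_a] / e_spec
      mu[sh] <- mu[sh] * e_shared; mu[rf] <- mu[rf] / e_shared
    } else {
      # a cell-type-specific gene is off in REF just as in the sister state
      mu[up_a | up_b] <- mu[up_a | up_b] / e_spec
      mu[sh] <- mu[sh] / e_shared; mu[rf] <- mu[rf] * e_shared
    }
    mu
  }
  counts <- matrix(0L, length(gene_ids), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- mu_for(st[j]) * 2^(cfg$batch_effect_log2 * (batch[j] == "b2"))
    counts[, j] <- rnb(length(gene_ids), mu, cfg$nb_dispersion)
  }
  tpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  list(counts = counts, tpm = tpm,
       samples = data.table(sample = sample_ids, state = st, batch = batch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-TF peak sets with planted disease-gene binding excess
#'
#' Each TF receives peaks at a random subset of catalogue CREs
#' (`peak_rate`) with log-normal intensities over `n_reps` replicate
#' measurements. For the designated disease TF, candidate peaks within
#' the enhancer window of a disease-gene TSS get both a placement
#' probability and an intensity multiplied by `disease_binding_effect`
#' (effect 1 reduces exactly to the background process, so the downstream
#' tests are null-calibrated).
#'
#' @param cfg a [sim_config()].
#' @param landscape result of [simulate_landscape()].
#' @param tfs TF ids to generate peaks for (default: disease TF plus two
#'   bystanders).
#' @param disease_tf the TF with planted excess (default: the first
#'   A-specific TF).
#' @param n_reps replicate intensity columns (default 2).
#' @param window_bp window around disease TSSs receiving the excess
#'   (default 100000).
#' @param seed optional seed (defaults to `cfg$rng_seed + 2`).
#' @return list with `tf_peaks` (named list of peak tables), `disease_genes`,
#'   `disease_tf`.
#' @export
simulate_tf_peaks <- function(cfg, landscape, tfs = NULL, disease_tf = NULL,
                              n_reps = 2L, window_bp = 100000L,
                              seed = cfg$rng_seed + 2L) {
  set.seed(seed)
  truth <- landscape$truth
  catalogue <- landscape$catalogue
  genes <- landscape$genes
  if (is.null(disease_tf)) disease_tf <- truth$a_tfs[1L]
  if (is.null(tfs)) {
    bystanders <- truth$tf_classes[class == "bystander", tf]
    tfs <- c(disease_tf, head(bystanders, 2L))
  }
  disease_pool <- setdiff(genes$gene, truth$tf_classes$tf)
  disease_genes <- sort(sample(disease_pool, cfg$n_disease_genes))
  near <- rep(FALSE, nrow(catalogue))
  dg <- genes[gene %in% disease_genes]
  for (i in seq_len(nrow(dg)))
    near <- near | (catalogue$chrom == dg$chrom[i] &
                    abs(catalogue$summit - dg$tss[i]) <= window_bp)
  out <- list()
  for (tf in tfs) {
    p_place <- rep(cfg$peak_rate, nrow(catalogue))
    boost <- if (tf == disease_tf) cfg$disease_binding_effect else 1
    p_place[near] <- pmin(p_place[near] * boost, 0.95)
    take <- runif(nrow(catalogue)) < p_place
    if (!any(take)) {
      out[[tf]] <- data.table(chrom = character(), start = integer(),
                              end = integer(), summit = integer())
      next
    }
    pk <- catalogue[take, .(chrom, summit)]
    imult <- ifelse(near[take] & tf == disease_tf,
                    cfg$disease_binding_effect, 1)
    inten <- vapply(seq_len(n_reps), function(r)
      imult * exp(rnorm(nrow(pk), log(50), 0.5)), numeric(nrow(pk)))
    inten <- matrix(inten, nrow = nrow(pk))
    colnames(inten) <- sprintf("intensity.%d", seq_len(n_reps))
    pk <- cbind(pk[, .(chrom, start = summit - 100L, end = summit + 100L,
                       summit)],
                as.data.table(inten))
    pk[, intensity := rowMeans(inten)]
    out[[tf]] <- pk
  }
  list(tf_peaks = out, disease_genes = disease_genes,
       disease_tf = disease_tf)
}
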