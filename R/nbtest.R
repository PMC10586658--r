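# Bespoke negative-binomial Wald machinery shared by the CRE differential
# test and the expression DE test: median-of-ratios size factors, per-feature
# method-of-moments dispersion shrunk toward a parametric mean-dispersion
# trend a0 + a1/mu, and a Wald test of the two-state effect. This follows
# the standard count-model recipe for bulk assays; exact equality with any
# particular external implementation is not claimed.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over features with positive counts in
#' every sample contributing to the geometric-mean reference, of the ratio
#' count / geometric mean. Factors are scaled to have geometric mean 1.
#'
#' @param counts non-negative count matrix (features x samples).
#' @return named numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no feature has positive counts in all samples; using library-size factors")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt)
    exp(median(log(cnt) - loggeo[use], na.rm = TRUE)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

# Method-of-moments dispersion per feature on size-factor-normalized counts,
# pooled within condition groups, then shrunk toward the fitted trend
# a(mu) = a0 + a1/mu on the log scale. Returns the per-feature dispersion
# alpha in Var = mu + alpha * mu^2.
estimate_dispersions <- function(counts, sf, condition) {
  q <- sweep(as.matrix(counts), 2L, sf, "/")
  groups <- split(seq_len(ncol(q)), condition)
  n <- ncol(q)
  G <- length(groups)
  if (n - G < 1L) stop("need at least one residual degree of freedom per test")
  # pooled within-group variance and grand mean of normalized counts
  ssq <- 0
  for (idx in groups) {
    qi <- q[, idx, drop = FALSE]
    mg <- rowMeans(qi)
    ssq <- ssq + rowSums((qi - mg)^2)
  }
  s2 <- ssq / (n - G)
  mu <- rowMeans(q)
  # correct for the Poisson (shot-noise) component: xi = mean of 1/sf
  xi <- mean(1 / sf)
  alpha_raw <- (s2 - xi * mu) / mu^2
  alpha_raw[!is.finite(alpha_raw)] <- NA_real_
  # parametric trend alpha = a0 + a1/mu, fit on usable features
  ok <- is.finite(alpha_raw) & alpha_raw > 1e-8 & mu > 0
  if (sum(ok) >= 10L) {
    fit <- tryCatch({
      d <- data.frame(a = alpha_raw[ok], im = 1 / mu[ok])
      # two robustness passes: drop gross outliers from the first fit
      f1 <- lm(a ~ im, data = d)
      r <- abs(residuals(f1))
      keep <- r <= 4 * median(r) + 1e-12
      coef(lm(a ~ im, data = d[keep, , drop = FALSE]))
    }, error = function(e) c(0.05, 1))
    a0 <- max(fit[1L], 1e-4)
    a1 <- max(fit[2L], 0)
  } else {
    med <- median(alpha_raw[ok], na.rm = TRUE)
    a0 <- if (is.finite(med) && med > 0) med else 0.05
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  # log-scale shrinkage toward the trend; with few residual df the MoM
  # estimate is noisy, so the trend carries half the weight at n - G = 6
  w <- (n - G) / (n - G + 6)
  floor_a <- trend / 16
  alpha <- exp(w * log(pmax(alpha_raw, floor_a)) + (1 - w) * log(trend))
  alpha[!is.finite(alpha)] <- trend[!is.finite(alpha)]
  pmax(alpha, 1e-8)
}

# Vectorized Newton solve of the per-group NB mean with sample offsets sf:
# score equation sum_i (y_i - sf_i * mu) / (1 + alpha * sf_i * mu) = 0.
nb_group_mean <- function(y, sf, alpha) {
  mu <- pmax(rowSums(y) / sum(sf), 1e-8)
  for (it in 1:25) {
    g <- rep(0, length(mu)); gp <- rep(0, length(mu))
    for (i in seq_along(sf)) {
      den <- 1 + alpha * sf[i] * mu
      g <- g + (y[, i] - sf[i] * mu) / den
      gp <- gp - sf[i] * (1 + alpha * y[, i]) / den^2
    }
    step <- g / gp
    step[!is.finite(step)] <- 0
    mu_new <- pmax(mu - step, mu / 10)
    if (max(abs(mu_new - mu) / pmax(mu, 1e-8)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

# Fisher information for log(mu) in one group.
nb_loginfo <- function(mu, sf, alpha) {
  info <- rep(0, length(mu))
  for (i in seq_along(sf)) {
    m <- sf[i] * mu
    info <- info + m / (1 + alpha * m)
  }
  info
}

#' Negative-binomial Wald test of a two-state effect
#'
#' Per-feature Wald test of `state_b` vs `state_a` on raw counts:
#' median-of-ratios normalization, trend-shrunk method-of-moments
#' dispersions, group means by maximum likelihood with sample offsets, and
#' a Wald z on the log-fold-change. When `batch` is supplied each feature
#' is fit as a NB GLM with `~ condition + batch` instead (same dispersions).
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels; the reported `log2fc` is second level vs first level.
#' @param batch optional blocking factor entering the model additively.
#' @param sf optional precomputed size factors.
#' @return `data.table` with `feature`, `baseMean`, `log2fc`, `se`, `stat`,
#'   `p` (two-sided).
#' @export
nb_wald_test <- function(counts, condition, batch = NULL, sf = NULL) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels")
  tab <- table(condition)
  if (any(tab < 2L))
    stop("need >= 2 samples per state for a dispersion estimate")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(sf)) sf <- size_factors(counts)
  alpha <- estimate_dispersions(counts, sf, condition)
  lvls <- levels(condition)
  ia <- which(condition == lvls[1L]); ib <- which(condition == lvls[2L])

  if (is.null(batch)) {
    mua <- nb_group_mean(counts[, ia, drop = FALSE], sf[ia], alpha)
    mub <- nb_group_mean(counts[, ib, drop = FALSE], sf[ib], alpha)
    se <- sqrt(1 / nb_loginfo(mua, sf[ia], alpha) +
               1 / nb_loginfo(mub, sf[ib], alpha)) / log(2)
    lfc <- log2(mub / mua)
    stat <- lfc / se
  } else {
    batch <- as.factor(batch)
    mm <- model.matrix(~ condition + batch)
    if (qr(mm)$rank < ncol(mm))
      stop("condition and batch are confounded (design not full rank)")
    lfc <- se <- stat <- rep(NA_real_, nrow(counts))
    off <- log(sf)
    for (g in seq_len(nrow(counts))) {
      fit <- tryCatch(
        suppressWarnings(glm(counts[g, ] ~ condition + batch, offset = off,
                             family = MASS::negative.binomial(theta = 1 / alpha[g]))),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- summary(fit)$coefficients
      row <- paste0("condition", lvls[2L])
      if (!row %in% rownames(cf)) next
      lfc[g] <- cf[row, 1L] / log(2)
      se[g] <- cf[row, 2L] / log(2)
      stat[g] <- cf[row, 1L] / cf[row, 2L]
    }
  }
  # t reference with effective df = residual df + prior df of the
  # dispersion trend (the shrinkage weight is df_res / (df_res + 6), so
  # the trend contributes ~6 prior df, moderated-t style)
  df_res <- if (is.null(batch)) ncol(counts) - 2L
            else ncol(counts) - qr(model.matrix(~ condition + batch))$rank
  p <- 2 * stats::pt(-abs(stat), df = df_res + 6)
  p[!is.finite(p)] <- 1
  zero <- rowSums(counts) == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  data.table(feature = rownames(counts),
             baseMean = rowMeans(sweep(counts, 2L, sf, "/")),
             log2fc = lfc, se = se, stat = stat, p = p)
}
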