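#' Median-of-ratios size factors
#'
#' Library-size normalization: the reference level of each gene is its
#' geometric mean across samples, computed over genes with strictly positive
#' counts in all samples; a sample's size factor is the median across those
#' genes of its count divided by the reference.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of strictly positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop("no gene has positive counts in all samples; ",
         "lower the count filter threshold")
  m <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  sf <- apply(m, 2L, function(col) stats::median(col / ref))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size-factor estimation failed")
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion alpha from normalized counts with group means
#' removed: `alpha = max(alpha_min, (v - m) / m^2)` where `v` is the pooled
#' within-group variance and `m` the pooled mean of normalized counts.
#' Genes at or below the Poisson limit (variance <= mean) return
#' `alpha_min`.
#'
#' With few replicates the per-gene moment estimate is noisy, and genes
#' whose dispersion is underestimated by chance inflate the Wald statistic.
#' When `common_floor = TRUE` (the default) each gene's estimate is
#' additionally floored at the common dispersion, the median of the raw
#' per-gene moment values across all genes. This shares information across
#' genes without imposing a mean-dispersion trend; for data at the Poisson
#' limit the common floor collapses to `alpha_min` and the estimator is
#' unchanged.
#'
#' @param counts Integer matrix, genes x samples.
#' @param size_factors Per-sample size factors.
#' @param groups Factor or vector of group labels (one per sample).
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param common_floor Floor each gene at the across-gene median raw
#'   moment estimate (default `TRUE`).
#' @return Named numeric vector of per-gene dispersions (>= `alpha_min`).
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                alpha_min = 1e-8, common_floor = TRUE) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  groups <- as.factor(groups)
  q <- sweep(counts, 2L, size_factors, "/")
  n <- ncol(q)
  g <- nlevels(groups)
  resid <- q
  for (lev in levels(groups)) {
    j <- groups == lev
    resid[, j] <- q[, j, drop = FALSE] - rowMeans(q[, j, drop = FALSE])
  }
  v <- rowSums(resid^2) / max(1L, n - g)
  m <- rowMeans(q)
  alpha <- (v - m) / m^2
  alpha[!is.finite(alpha)] <- alpha_min
  if (common_floor && length(alpha) > 1L)
    alpha_min <- max(alpha_min, stats::median(alpha))
  alpha <- pmax(alpha, alpha_min)
  names(alpha) <- rownames(counts)
  alpha
}

# NB log-likelihood machinery for one gene, one group, fixed alpha.
# Counts k_j with means s_j * q; theta = log(q).
nb_fit_group <- function(k, s, alpha, floor_q) {
  if (all(k == 0)) {
    theta <- log(floor_q)
    floored <- TRUE
  } else {
    score <- function(theta) {
      mu <- s * exp(theta)
      sum(k) - sum((k + 1 / alpha) * alpha * mu / (1 + alpha * mu))
    }
    theta0 <- log(sum(k) / sum(s))
    theta <- stats::uniroot(score, c(theta0 - 30, theta0 + 30),
                            tol = 1e-10)$root
    floored <- FALSE
    if (exp(theta) < floor_q) { # degenerate near-zero fit
      theta <- log(floor_q)
      floored <- TRUE
    }
  }
  mu <- s * exp(theta)
  info <- sum((k + 1 / alpha) * alpha * mu / (1 + alpha * mu)^2)
  list(theta = theta, var_theta = 1 / info, floored = floored)
}

#' Per-gene negative-binomial Wald test of a two-stage contrast
#'
#' Fits stage-specific means by maximum likelihood at fixed per-gene
#' dispersion, with sample-level means `size_factor * q_stage`. The reported
#' effect is `log2fc = log2(q_XIII_XIV / q_X)` (later stage over earlier
#' stage), its standard error comes from the observed information of the
#' log-scale parameters, and the Wald statistic is referred to the standard
#' normal. A stage with all-zero counts is floored at
#' `0.5 / mean(size_factors)` and flagged.
#'
#' @param counts Integer matrix, genes x samples.
#' @param size_factors Per-sample size factors.
#' @param stage Per-sample stage labels, `"X"` or `"XIII_XIV"` (each stage
#'   needs >= 2 samples).
#' @param dispersion Per-gene dispersion (scalar recycled), each >= 1e-8.
#' @return Data frame: `gene_id`, `base_mean`, `log2fc`, `se_log2fc`,
#'   `wald_z`, `p_value`, `floored`.
#' @export
nb_wald_test <- function(counts, size_factors, stage, dispersion) {
  stage <- as.character(stage)
  if (!all(stage %in% c("X", "XIII_XIV")))
    stop("stage labels must be 'X' or 'XIII_XIV'")
  jx <- stage == "X"
  js <- stage == "XIII_XIV"
  if (sum(jx) < 2L || sum(js) < 2L)
    stop("each stage needs >= 2 samples")
  n_genes <- nrow(counts)
  dispersion <- pmax(rep_len(dispersion, n_genes), 1e-8)
  floor_q <- 0.5 / mean(size_factors)
  ln2 <- log(2)
  q <- sweep(counts, 2L, size_factors, "/")
  base_mean <- rowMeans(q)
  log2fc <- se <- numeric(n_genes)
  floored <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    k <- counts[i, ]
    if (all(k == 0))
      stop("all-zero gene reached the Wald test (gene ",
           rownames(counts)[i], "); filter counts upstream")
    fx <- nb_fit_group(k[jx], size_factors[jx], dispersion[i], floor_q)
    fs <- nb_fit_group(k[js], size_factors[js], dispersion[i], floor_q)
    log2fc[i] <- (fs$theta - fx$theta) / ln2
    se[i] <- sqrt(fx$var_theta + fs$var_theta) / ln2
    floored[i] <- fx$floored || fs$floored
  }
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se_log2fc = se, wald_z = z,
             p_value = pmin(p, 1), floored = floored,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the adjusted
#' value at rank `i` is `min over j >= i of p_(j) * m / j`, capped at 1, and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same order as the input.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Three-way direction call from FDR and fold change
#'
#' A gene is `up` iff FDR < 0.05 and FC > 2, `down` iff FDR < 0.05 and
#' FC < 0.5, and `unaltered` otherwise (FDR >= 0.05, or FC between 0.5 and
#' 2 inclusive). All inequalities are strict exactly as stated.
#'
#' @param fdr Adjusted p-values in \[0, 1\].
#' @param fc Fold changes (`2^log2fc`), each > 0.
#' @param fdr_alpha Significance cutoff (default 0.05).
#' @param fc_up Upregulation fold-change cutoff (default 2).
#' @param fc_down Downregulation cutoff (default 0.5).
#' @return Character vector over `up`, `down`, `unaltered`.
#' @export
call_direction <- function(fdr, fc, fdr_alpha = 0.05, fc_up = 2,
                           fc_down = 0.5) {
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  if (any(fc <= 0)) stop("fc must be > 0")
  ifelse(fdr < fdr_alpha & fc > fc_up, "up",
         ifelse(fdr < fdr_alpha & fc < fc_down, "down", "unaltered"))
}

#' Stage-contrast differential expression for one series
#'
#' End-to-end per-series analysis: median-of-ratios normalization,
#' method-of-moments dispersion with stage as the grouping, per-gene NB
#' Wald test of stage XIII/XIV versus stage X, BH adjustment over the genes
#' of this comparison, and the three-way direction call.
#'
#' @param counts Filtered integer matrix, genes x samples.
#' @param stage Per-sample stage labels (`"X"` / `"XIII_XIV"`).
#' @param fdr_alpha,fc_up,fc_down Direction-call thresholds.
#' @return Data frame of class `de_result`: `gene_id`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `wald_z`, `p_value`, `fdr`, `direction`.
#' @export
run_de <- function(counts, stage, fdr_alpha = 0.05, fc_up = 2,
                   fc_down = 0.5) {
  sf <- estimate_size_factors(counts)
  alpha <- estimate_dispersion(counts, sf, stage)
  res <- nb_wald_test(counts, sf, stage, alpha)
  res$fdr <- adjust_bh(res$p_value)
  res$direction <- call_direction(res$fdr, 2^res$log2fc, fdr_alpha,
                                  fc_up, fc_down)
  attr(res, "thresholds") <- c(fdr_alpha = fdr_alpha, fc_up = fc_up,
                               fc_down = fc_down)
  class(res) <- c("de_result", "data.frame")
  res
}
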