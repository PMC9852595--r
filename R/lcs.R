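#' Aggregate expression features to signature genes
#'
#' Restricts an expression matrix to features matching signature genes and
#' sums expression over all features of a gene (probes or transcripts), so
#' each gene contributes one aggregated row. Signature genes with no
#' matching feature are dropped with a message (they reduce the effective
#' signature size n).
#'
#' @param e An [expr_matrix()].
#' @param signature_genes Character vector of signature gene ids.
#' @param feature_map Optional tibble with `feature_id`, `gene_id` mapping
#'   matrix rows to genes; by default rownames of `e` are taken as gene ids.
#' @return A gene-by-sample matrix restricted to matched signature genes.
#' @export
aggregate_by_gene <- function(e, signature_genes, feature_map = NULL) {
  v <- .strip(e)
  if (is.null(feature_map)) {
    feature_map <- tibble::tibble(feature_id = rownames(v),
                                  gene_id = rownames(v))
  }
  fm <- feature_map[feature_map$gene_id %in% signature_genes &
                      feature_map$feature_id %in% rownames(v), , drop = FALSE]
  unmatched <- setdiff(signature_genes, fm$gene_id)
  if (length(unmatched)) {
    inform(paste0(length(unmatched),
                  " signature gene(s) without matching features dropped"))
  }
  if (!nrow(fm)) abort("no signature gene matches any expression feature.")
  sub <- v[fm$feature_id, , drop = FALSE]
  out <- rowsum(sub, group = fm$gene_id, reorder = TRUE)
  out
}

#' Scale gene rows to mean 0, sd 1
#'
#' Centers and standard-deviation-reduces each gene across samples (unbiased
#' n-1 denominator). Zero-variance genes cannot be scaled and are dropped
#' with a warning, reducing the signature size.
#'
#' @param g A gene-by-sample numeric matrix (>= 2 samples).
#' @return The scaled matrix.
#' @export
scale_genes <- function(g) {
  if (ncol(g) < 2) abort("need >= 2 samples to scale.")
  sds <- apply(g, 1, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (all(zero)) abort("all genes have zero variance.")
  if (any(zero)) {
    warn(paste0("dropping ", sum(zero), " zero-variance gene(s) before scaling"))
    g <- g[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  (g - rowMeans(g)) / sds
}

#' Trim positive outliers at the last permille
#'
#' Replaces values above the matrix-wide `quantile` (default the 99.9th
#' percentile) with that percentile, damping extreme positive expression
#' without discarding high values entirely. The percentile is the empirical
#' order statistic (no interpolation), which makes the operation exactly
#' idempotent. Negative values are never touched.
#'
#' @param x A scaled gene-by-sample matrix.
#' @param quantile Trimming quantile in (0, 1); default 0.999.
#' @return The trimmed matrix.
#' @export
trim_positive_outliers <- function(x, quantile = 0.999) {
  cut <- stats::quantile(x, probs = quantile, names = FALSE, type = 1)
  x[x > cut] <- cut
  x
}

#' Compute raw linear classifier scores
#'
#' `LCS(S) = (1/n) * sum_i G_i * W_i`: the mean of the signature-weighted,
#' scaled gene expressions of sample S, with n the number of signature genes
#' retained in the matrix.
#'
#' @param x A scaled (and trimmed) gene-by-sample matrix.
#' @param signature A `gene_signature` tibble (`gene_id`, `weight`).
#' @return Tibble: `sample_id`, `lcs_raw`.
#' @export
compute_lcs <- function(x, signature) {
  w <- signature$weight[match(rownames(x), signature$gene_id)]
  if (anyNA(w)) abort("matrix rows must all be signature genes.")
  tibble::tibble(sample_id = colnames(x),
                 lcs_raw = as.numeric(crossprod(x, w)) / nrow(x))
}

#' Standardize scores and call significant samples
#'
#' Cohort z-scores (`(lcs - mean) / sd`, unbiased sd) are referred to the
#' upper tail of the standard normal — high scores mean the sample carries
#' the CLL-derived RS expression imprint. `significant` flags `p < alpha`;
#' `top_quartile` flags the highest `top_fraction` of the cohort (ties
#' broken by sample order, reported).
#'
#' @param lcs Tibble from [compute_lcs()] (>= 3 samples).
#' @param alpha Significance level on the raw one-sided p (default 0.05).
#' @param top_fraction Fraction flagged as top scores (default 0.25).
#' @param adjust Optional multiplicity adjustment for the p-values
#'   (`"none"`, `"bonferroni"`, `"BH"`); default `"none"`.
#' @return A tibble of class `lcs_result`: `sample_id`, `lcs_raw`, `z`,
#'   `p`, `significant`, `top_quartile`.
#' @export
lcs_call <- function(lcs, alpha = 0.05, top_fraction = 0.25,
                     adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(lcs) < 3) abort("need >= 3 samples to standardize LCS.")
  s <- sd(lcs$lcs_raw)
  if (s == 0) abort("zero LCS variance across the cohort.")
  z <- (lcs$lcs_raw - mean(lcs$lcs_raw)) / s
  p <- pnorm(z, lower.tail = FALSE)
  if (adjust != "none") p <- p.adjust(p, method = adjust)
  n_top <- floor(top_fraction * nrow(lcs))
  rank_desc <- rank(-z, ties.method = "first")
  if (anyDuplicated(z)) inform("tied z-scores; top-quartile ties broken by sample order")
  out <- tibble::tibble(sample_id = lcs$sample_id, lcs_raw = lcs$lcs_raw,
                        z = z, p = p,
                        significant = p < alpha,
                        top_quartile = rank_desc <= n_top)
  class(out) <- c("lcs_result", class(out))
  out
}

#' Score a cohort with a gene signature
#'
#' The full linear-classifier pipeline: feature-to-gene aggregation, gene
#' scaling, positive-outlier trimming at the last permille, weighted-mean
#' scoring, cohort standardization and significance calling. Scores are
#' cohort-relative: the same sample can receive different z-scores in
#' cohorts of different composition.
#'
#' @inheritParams aggregate_by_gene
#' @inheritParams lcs_call
#' @param signature A `gene_signature` tibble; defaults to the packaged
#'   synthetic 215-gene signature ([rs_signature()]).
#' @param trim_quantile Trimming quantile (default 0.999).
#' @return An `lcs_result` tibble.
#' @examples
#' cohort <- make_gold_cohort("small", seed = 7)
#' prep <- prepare_expression(cohort$counts)
#' sig <- with(cohort$truth, extract_signature(
#'   signature_genes$gene_id[signature_genes$direction == "up"],
#'   signature_genes$gene_id[signature_genes$direction == "down"],
#'   cohort$gene_ann))
#' res <- lcs_score(prep$expr, sig)
#' head(res[order(-res$z), ])
#' @export
lcs_score <- function(e, signature = rs_signature(), feature_map = NULL,
                      alpha = 0.05, top_fraction = 0.25, trim_quantile = 0.999,
                      adjust = "none") {
  g <- aggregate_by_gene(e, signature$gene_id, feature_map)
  g <- scale_genes(g)
  g <- trim_positive_outliers(g, trim_quantile)
  lcs <- compute_lcs(g, signature)
  lcs_call(lcs, alpha = alpha, top_fraction = top_fraction, adjust = adjust)
}
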