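#' Remove weakly expressed features
#'
#' A feature is kept when it is non-zero in at least `min_samples` samples
#' and its mean count across all samples is at least `min_mean_reads`. The
#' default mean threshold is `max(20, mean(library sizes) / 5e6)`: one read
#' per five million of the average library depth, floored at the explicit
#' 20-read minimum.
#'
#' @param counts A [count_matrix()].
#' @param min_samples Minimum number of samples with a non-zero count
#'   (default 2).
#' @param min_mean_reads Minimum mean raw count; `NULL` for the default rule.
#' @return The filtered [count_matrix()].
#' @export
filter_low_expression <- function(counts, min_samples = 2,
                                  min_mean_reads = NULL) {
  v <- .strip(counts)
  if (is.null(min_mean_reads)) {
    min_mean_reads <- max(20, mean(colSums(v)) / 5e6)
  }
  keep <- rowSums(v > 0) >= min_samples & rowMeans(v) >= min_mean_reads
  if (!any(keep)) abort("all features removed by the expression filter.")
  count_matrix(v[keep, , drop = FALSE])
}

#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values (via [edgeR::calcNormFactors()]): log-ratios of
#' each sample against a reference library (the one whose upper quartile is
#' closest to the mean upper quartile) are double-trimmed (30% on M, 5% on
#' A by default), precision-weighted, and averaged; the resulting factors
#' are renormalized so their geometric mean is 1.
#'
#' @param counts A [count_matrix()] (>= 2 samples, no all-zero sample).
#' @param trim_m Fraction trimmed on the log-ratio (M) scale (default 0.30).
#' @param trim_a Fraction trimmed on the absolute-intensity (A) scale
#'   (default 0.05).
#' @return Tibble: `sample_id`, `tmm_factor`, `effective_library_size`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  v <- .strip(counts)
  if (ncol(v) < 2) abort("TMM needs >= 2 samples.")
  if (any(colSums(v) == 0)) abort("all-zero sample library.")
  f <- edgeR::calcNormFactors(v, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  tibble::tibble(
    sample_id = colnames(v),
    tmm_factor = as.numeric(f),
    effective_library_size = colSums(v) * as.numeric(f)
  )
}

#' Log2 counts-per-million
#'
#' `log2((count + prior_count) / (effective_library_size + 2 * prior_count)
#' * 1e6)`, with effective library sizes from [tmm_factors()]. The prior
#' count keeps zeros finite.
#'
#' @param counts A [count_matrix()].
#' @param factors Tibble from [tmm_factors()]; `NULL` for unit factors.
#' @param prior_count Pseudo-count added to every cell (default 0.5).
#' @return An [expr_matrix()] of log2-CPM values.
#' @export
log2_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  v <- .strip(counts)
  if (is.null(factors)) {
    eff <- colSums(v)
  } else {
    eff <- factors$effective_library_size[match(colnames(v), factors$sample_id)]
    if (anyNA(eff)) abort("normalization factors missing for some samples.")
  }
  out <- log2(sweep(v + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  expr_matrix(out)
}

#' Filter, normalize and transform a count matrix
#'
#' Convenience composition: [filter_low_expression()], [tmm_factors()],
#' [log2_cpm()].
#'
#' @inheritParams filter_low_expression
#' @inheritParams log2_cpm
#' @return List: `expr` ([expr_matrix()]), `factors` (TMM tibble),
#'   `counts` (filtered [count_matrix()]).
#' @export
prepare_expression <- function(counts, min_samples = 2, min_mean_reads = NULL,
                               prior_count = 0.5) {
  filtered <- filter_low_expression(counts, min_samples, min_mean_reads)
  factors <- tmm_factors(filtered)
  list(expr = log2_cpm(filtered, factors, prior_count),
       factors = factors, counts = filtered)
}
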