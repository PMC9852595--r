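#' Build the CpG-to-transcript association skeleton
#'
#' Associations are formed two ways and unioned: (i) shared identifiers —
#' the CpG annotation links the CpG to a gene, whose transcripts become
#' targets, carrying the array feature class (TSS200, TSS1500, FirstExon,
#' ...); (ii) genomic coordinates — a CpG within `window` bp of a transcript
#' TSS on the same chromosome is paired and labeled `TSSoverlap2kb`.
#' Duplicated pairs keep the identifier-based link (`link_method`
#' precedence). The window is inclusive and strand-agnostic for the
#' distance; the TSS itself comes strand-resolved from the gene annotation.
#'
#' @param cpgs A [cpg_annotation()] tibble.
#' @param genes A [gene_annotation()] tibble.
#' @param window Maximum CpG-TSS distance in bp (default 2000).
#' @return Tibble: `cpg_id`, `target_id` (transcript), `gene_id`,
#'   `link_method`, `feature_class`.
#' @export
build_integrome <- function(cpgs, genes, window = 2000) {
  if (!length(intersect(unique(cpgs$chrom), unique(genes$chrom)))) {
    abort(paste0("no shared chromosome names; CpG chroms: ",
                 paste(unique(cpgs$chrom), collapse = ","),
                 " vs gene chroms: ",
                 paste(unique(genes$chrom), collapse = ",")))
  }
  by_id <- dplyr::inner_join(
    cpgs[!is.na(cpgs$gene_id), c("cpg_id", "gene_id", "feature_class")],
    genes[, c("gene_id", "transcript_id")],
    by = "gene_id", relationship = "many-to-many"
  )
  by_id <- tibble::tibble(cpg_id = by_id$cpg_id,
                          target_id = by_id$transcript_id,
                          gene_id = by_id$gene_id,
                          link_method = "shared_id",
                          feature_class = by_id$feature_class)

  cpg_pos <- dplyr::distinct(cpgs[, c("cpg_id", "chrom", "pos")])
  by_coord <- purrr::map_dfr(split(genes, genes$chrom), function(g) {
    cp <- cpg_pos[cpg_pos$chrom == g$chrom[1], , drop = FALSE]
    if (!nrow(cp)) return(NULL)
    ord <- order(cp$pos)
    cp <- cp[ord, , drop = FALSE]
    lo <- findInterval(g$tss - window - 1L, cp$pos) + 1L
    hi <- findInterval(g$tss + window, cp$pos)
    keep <- which(hi >= lo)
    if (!length(keep)) return(NULL)
    idx <- unlist(lapply(keep, function(i) lo[i]:hi[i]))
    rep_n <- hi[keep] - lo[keep] + 1L
    tibble::tibble(cpg_id = cp$cpg_id[idx],
                   target_id = rep(g$transcript_id[keep], rep_n),
                   gene_id = rep(g$gene_id[keep], rep_n),
                   link_method = "coordinate_overlap",
                   feature_class = "TSSoverlap2kb")
  })
  out <- dplyr::bind_rows(by_id, by_coord)
  out <- out[!duplicated(out[, c("cpg_id", "target_id")]), , drop = FALSE]
  tibble::as_tibble(out)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

.spearman_p <- function(rho, n, x_ranks = NULL, y_ranks = NULL) {
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    return(pmin(p, 1))
  }
  # exact permutation null for small n (the t-approximation is unusable
  # at the p < 0.001 gate when n < 10)
  perms <- .permutations(n)
  null_rho <- apply(perms, 1, function(ix) cor(x_ranks, y_ranks[ix]))
  mean(abs(null_rho) >= abs(rho) - 1e-12)
}

#' Spearman correlation between one CpG and one target
#'
#' Mid-rank (average-tie) Spearman rho, with a two-sided p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` for n >= 10 and
#' an exact permutation null for 5 <= n < 10. Pairs with missing values are
#' removed first.
#'
#' @param meth Per-sample beta values for one CpG.
#' @param expr Per-sample expression for one target, in the same sample
#'   order.
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(meth, expr) {
  ok <- is.finite(meth) & is.finite(expr)
  x <- meth[ok]; y <- expr[ok]
  n <- length(x)
  if (n < 5) abort("need >= 5 paired samples.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) {
    if (n >= 10) 0 else .spearman_p(rho, n, rx, ry)
  } else {
    .spearman_p(rho, n, rx, ry)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate methylation and expression over an integrome
#'
#' Computes Spearman rho and p for every association in the skeleton,
#' vectorized over rank-standardized rows. Associations involving a
#' constant methylation or expression profile have an undefined rank
#' correlation and are dropped with a message.
#'
#' @param integrome Tibble from [build_integrome()].
#' @param b A [beta_matrix()] holding the CpGs (columns = samples).
#' @param e An [expr_matrix()] holding the targets, same sample order as
#'   `b`.
#' @return The integrome tibble with `rho`, `p` and `n` columns added.
#' @export
compute_correlations <- function(integrome, b, e) {
  bv <- .strip(b); ev <- .strip(e)
  if (!identical(colnames(bv), colnames(ev))) {
    abort("beta and expression matrices must share the same sample columns.")
  }
  n <- ncol(bv)
  if (n < 5) abort("need >= 5 paired samples.")
  keep <- integrome$cpg_id %in% rownames(bv) &
    integrome$target_id %in% rownames(ev)
  assoc <- integrome[keep, , drop = FALSE]
  cpg_idx <- unique(assoc$cpg_id)
  tgt_idx <- unique(assoc$target_id)
  rank_std <- function(m) {
    r <- t(apply(m, 1, rank))
    sds <- apply(r, 1, sd)
    const <- sds == 0
    r <- (r - rowMeans(r)) / ifelse(const, 1, sds)
    r[const, ] <- NA_real_
    r
  }
  rb <- rank_std(bv[cpg_idx, , drop = FALSE])
  re <- rank_std(ev[tgt_idx, , drop = FALSE])
  rho <- as.numeric(rowSums(rb[assoc$cpg_id, , drop = FALSE] *
                              re[assoc$target_id, , drop = FALSE])) / (n - 1)
  rho <- pmin(pmax(rho, -1), 1)
  undefined <- !is.finite(rho)
  if (any(undefined)) {
    inform(paste0("dropping ", sum(undefined),
                  " association(s) with a constant profile"))
  }
  assoc$rho <- rho
  assoc$n <- n
  if (n >= 10) {
    assoc$p <- .spearman_p(rho, n)
  } else {
    assoc$p <- vapply(seq_len(nrow(assoc)), function(i) {
      if (!is.finite(rho[i])) return(NA_real_)
      sp <- spearman_assoc(bv[assoc$cpg_id[i], ], ev[assoc$target_id[i], ])
      sp$p
    }, numeric(1))
  }
  assoc[!undefined, , drop = FALSE]
}

#' Filter associations to significant correlations
#'
#' Keeps associations with `|rho| > rho_cut` and `p < p_cut`.
#'
#' @param assocs Tibble from [compute_correlations()].
#' @param p_cut P-value cutoff (default 0.01).
#' @param rho_cut Absolute correlation cutoff (default 1/3).
#' @return The filtered tibble.
#' @export
filter_significant <- function(assocs, p_cut = 0.01, rho_cut = 1 / 3) {
  assocs[!is.na(assocs$rho) & abs(assocs$rho) > rho_cut &
           !is.na(assocs$p) & assocs$p < p_cut, , drop = FALSE]
}

#' Select candidate methylation-regulated promoter regions
#'
#' A target qualifies as a candidate region when at least `min_cpgs`
#' promoter-class CpGs (TSS200, TSS1500, FirstExon or TSSoverlap2kb) linked
#' to it correlate in the same direction with `|rho| > rho_cut` and
#' `p < p_cut`. Negative direction means higher methylation, lower
#' expression. A target may appear in both directions; the union gene list
#' deduplicates after direction-specific counting.
#'
#' @param assocs Tibble from [compute_correlations()] (with
#'   `feature_class`).
#' @param min_cpgs Minimum supporting CpGs per direction (default 3).
#' @param rho_cut Absolute correlation cutoff (default 1/3).
#' @param p_cut P-value cutoff (default 0.001).
#' @return Tibble: `target_id`, `gene_id`, `direction`, `n_cpgs`,
#'   `cpg_ids` (list), `feature_classes` (list).
#' @export
select_candidates <- function(assocs, min_cpgs = 3, rho_cut = 1 / 3,
                              p_cut = 0.001) {
  qual <- assocs[!is.na(assocs$rho) & !is.na(assocs$p) &
                   assocs$feature_class %in% .rs_promoter_classes &
                   abs(assocs$rho) > rho_cut & assocs$p < p_cut, , drop = FALSE]
  if (!nrow(qual)) {
    return(tibble::tibble(target_id = character(), gene_id = character(),
                          direction = character(), n_cpgs = integer(),
                          cpg_ids = list(), feature_classes = list()))
  }
  qual$direction <- ifelse(qual$rho < 0, "negative", "positive")
  out <- qual |>
    dplyr::group_by(.data$target_id, .data$gene_id, .data$direction) |>
    dplyr::summarise(n_cpgs = dplyr::n_distinct(.data$cpg_id),
                     cpg_ids = list(unique(.data$cpg_id)),
                     feature_classes = list(unique(.data$feature_class)),
                     .groups = "drop")
  out[out$n_cpgs >= min_cpgs, , drop = FALSE]
}

#' Unique gene lists from candidate regions
#'
#' @param candidates Tibble from [select_candidates()].
#' @return List: `negative`, `positive`, `union` (unique gene ids).
#' @export
candidate_genes <- function(candidates) {
  neg <- unique(candidates$gene_id[candidates$direction == "negative"])
  pos <- unique(candidates$gene_id[candidates$direction == "positive"])
  list(negative = neg, positive = pos, union = unique(c(neg, pos)))
}

#' Fold enrichment of a selection against a background
#'
#' `(selected / selection_size) / (background_count / background_size)` —
#' observed over expected frequency.
#'
#' @param selected Count of hits in the selection.
#' @param selection_size Size of the selection.
#' @param background_count Count of hits in the background.
#' @param background_size Size of the background.
#' @return The fold enrichment (Inf with a warning when the background
#'   frequency is zero).
#' @export
enrichment_fold <- function(selected, selection_size, background_count,
                            background_size) {
  if (selection_size <= 0 || background_size <= 0) {
    abort("sizes must be positive.")
  }
  if (background_count == 0) {
    warn("zero background frequency; enrichment undefined (Inf)")
    return(Inf)
  }
  (selected / selection_size) / (background_count / background_size)
}

#' Two-by-two enrichment test
#'
#' Two-sided p-value from Fisher's exact test (hypergeometric) or the
#' Pearson chi-square test (without continuity correction, i.e. the plain
#' `sum((O - E)^2 / E)` statistic).
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param method `"fisher"` or `"chi2"`.
#' @return The p-value.
#' @export
enrichment_test <- function(table, method = c("fisher", "chi2")) {
  method <- match.arg(method)
  if (any(table < 0) || any(table != round(table))) {
    abort("table cells must be non-negative integers.")
  }
  if (method == "fisher") {
    fisher.test(table)$p.value
  } else {
    suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
  }
}
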