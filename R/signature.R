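#' Median-center expression rows
#'
#' Subtracts each feature's median across samples, the standard preparation
#' before correlation-based clustering of expression profiles.
#'
#' @param e An [expr_matrix()].
#' @return The centered [expr_matrix()].
#' @export
median_center <- function(e) {
  v <- .strip(e)
  expr_matrix(v - apply(v, 1, median))
}

#' Uncentered Pearson correlation distance
#'
#' `d(x, y) = 1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`, in \[0, 2\].
#' Unlike the ordinary correlation, profiles are not re-centered, so the
#' distance is sensitive to a profile's offset from zero — the intended
#' behaviour on median-centered expression.
#'
#' @param x A numeric vector, or a feature-by-sample matrix (rows compared
#'   pairwise).
#' @param y A second vector when `x` is a vector; ignored otherwise.
#' @return A scalar distance, or a [stats::dist] object over rows of `x`.
#' @export
uncentered_cor_dist <- function(x, y = NULL) {
  if (is.matrix(x) || inherits(x, "rs_matrix")) {
    v <- .strip(x)
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) abort("zero feature profile; distance undefined.")
    s <- tcrossprod(v / nrm)
    s[s > 1] <- 1; s[s < -1] <- -1
    return(as.dist(1 - s))
  }
  if (sum(x^2) == 0 || sum(y^2) == 0) abort("zero vector; distance undefined.")
  1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

#' Hierarchical clustering of gene profiles
#'
#' Agglomerative clustering of expression rows under the uncentered
#' correlation distance, with complete or average linkage.
#'
#' @param e An [expr_matrix()] (>= 2 features), typically median-centered.
#' @param linkage `"complete"` or `"average"`.
#' @return An object of class [stats::hclust].
#' @export
hcluster_genes <- function(e, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(e) < 2) abort("need >= 2 features to cluster.")
  hclust(uncentered_cor_dist(e), method = linkage)
}

#' Consensus k-means clustering of gene profiles
#'
#' Runs k-means on median-centered rows over `restarts` seeded restarts,
#' accumulates the co-assignment frequency of every gene pair, and cuts the
#' average-linkage tree of the consensus (1 - co-assignment) distance into k
#' groups. Deterministic given `seed`.
#'
#' @param e An [expr_matrix()].
#' @param k Number of clusters (2 <= k <= number of features).
#' @param seed Integer seed controlling all restarts.
#' @param restarts Number of k-means restarts aggregated (default 20).
#' @return Named integer vector of cluster assignments (1..k).
#' @export
kmeans_gene_clusters <- function(e, k, seed, restarts = 20) {
  v <- .strip(median_center(e))
  n <- nrow(v)
  if (k > n) abort("k exceeds the number of features.")
  if (k == n) return(setNames(seq_len(n), rownames(v)))
  co <- matrix(0, n, n)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    cl <- kmeans(v, centers = k, nstart = 1, iter.max = 50)$cluster
    co <- co + outer(cl, cl, "==")
  }
  cons <- hclust(as.dist(1 - co / restarts), method = "average")
  setNames(cutree(cons, k = k), rownames(v))
}

#' Orient gene clusters against a group contrast
#'
#' For each cluster, the mean expression contrast between two sample groups
#' decides its direction: `up` when the cluster mean is higher in
#' `contrast[1]`, `down` otherwise.
#'
#' @param e An [expr_matrix()].
#' @param clusters Named cluster assignments over rows of `e`.
#' @param sheet A [sample_sheet()].
#' @param contrast Two group labels, `contrast[1]` being the group of
#'   interest (e.g. the CLL-derived side).
#' @param group_var Sheet column holding the labels.
#' @return Tibble: `cluster`, `direction`, `mean_contrast`, `n_genes`,
#'   `mean_intra_cor` (average pairwise uncentered correlation inside the
#'   cluster).
#' @export
cluster_directions <- function(e, clusters, sheet, contrast,
                               group_var = "group") {
  v <- .strip(e)
  g1 <- sheet$sample_id[sheet[[group_var]] == contrast[1]]
  g2 <- sheet$sample_id[sheet[[group_var]] == contrast[2]]
  if (!length(g1) || !length(g2)) abort("both contrast groups must be non-empty.")
  purrr::map_dfr(sort(unique(clusters)), function(cl) {
    rows <- names(clusters)[clusters == cl]
    sub <- v[rows, , drop = FALSE]
    contr <- mean(sub[, g1, drop = FALSE]) - mean(sub[, g2, drop = FALSE])
    intra <- if (length(rows) > 1) {
      mean(1 - as.matrix(uncentered_cor_dist(sub))[upper.tri(diag(length(rows)))])
    } else NA_real_
    tibble::tibble(cluster = cl,
                   direction = if (contr >= 0) "up" else "down",
                   mean_contrast = contr, n_genes = length(rows),
                   mean_intra_cor = intra)
  })
}

#' Reduce two oriented clusters to a +/-1 gene signature
#'
#' Members of the up-regulated cluster are weighted +1 and members of the
#' down-regulated cluster -1, after restricting to protein-coding genes
#' (portable across expression platforms that lack ncRNAs) and to genes
#' supported by the methylome-transcriptome integrome.
#'
#' @param up_genes,down_genes Character vectors of gene ids.
#' @param genes A [gene_annotation()] tibble (provides `biotype`).
#' @param integrome_genes Gene ids with significant methylation-expression
#'   integration; `NULL` skips that filter.
#' @return Tibble of class `gene_signature`: `gene_id`, `weight`.
#' @export
extract_signature <- function(up_genes, down_genes, genes,
                              integrome_genes = NULL) {
  coding <- unique(genes$gene_id[genes$biotype == "protein_coding"])
  keep <- function(ids) {
    ids <- intersect(ids, coding)
    if (!is.null(integrome_genes)) ids <- intersect(ids, integrome_genes)
    sort(ids)
  }
  up <- keep(up_genes)
  down <- keep(down_genes)
  if (!length(up) && !length(down)) abort("signature is empty after filtering.")
  out <- tibble::tibble(gene_id = c(up, down),
                        weight = c(rep(1, length(up)), rep(-1, length(down))))
  if (anyDuplicated(out$gene_id)) abort("a gene cannot be in both clusters.")
  class(out) <- c("gene_signature", class(out))
  out
}

#' Derive a gene signature from an expression cohort
#'
#' End-to-end derivation: median-center, hierarchically cluster genes under
#' the uncentered correlation distance, cut the tree into `k` flat clusters,
#' pick the pair of clusters with the largest positive and largest negative
#' mean contrast between the two sample groups, and reduce them to a
#' protein-coding, integrome-supported signature.
#'
#' @inheritParams cluster_directions
#' @inheritParams extract_signature
#' @param k Number of flat clusters cut from the tree (default 6).
#' @param linkage Linkage criterion for [hcluster_genes()].
#' @return A `gene_signature` tibble with a `clusters` attribute recording
#'   the chosen source clusters.
#' @export
derive_signature <- function(e, sheet, contrast, genes, integrome_genes = NULL,
                             k = 6, linkage = "complete", group_var = "group") {
  ec <- median_center(e)
  tree <- hcluster_genes(ec, linkage)
  clusters <- cutree(tree, k = k)
  dirs <- cluster_directions(ec, clusters, sheet, contrast, group_var)
  up_cl <- dirs$cluster[which.max(dirs$mean_contrast)]
  down_cl <- dirs$cluster[which.min(dirs$mean_contrast)]
  if (up_cl == down_cl) abort("could not find opposite-direction clusters.")
  sig <- extract_signature(names(clusters)[clusters == up_cl],
                           names(clusters)[clusters == down_cl],
                           genes, integrome_genes)
  attr(sig, "clusters") <- dirs[dirs$cluster %in% c(up_cl, down_cl), ]
  sig
}

#' Read / write a gene signature
#'
#' Two-column TSV (`gene_id`, `weight` in {+1, -1}).
#'
#' @param path File path.
#' @param signature A `gene_signature` tibble.
#' @return `read_signature()` returns the validated signature;
#'   `write_signature()` returns `path` invisibly.
#' @export
read_signature <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "weight") %in% names(tb))) {
    abort("signature file needs `gene_id` and `weight` columns.")
  }
  if (!all(tb$weight %in% c(-1, 1))) abort("signature weights must be +1 or -1.")
  if (anyDuplicated(tb$gene_id)) abort("signature gene_ids must be unique.")
  class(tb) <- c("gene_signature", class(tb))
  tb
}

#' @rdname read_signature
#' @export
write_signature <- function(signature, path) {
  readr::write_tsv(signature[, c("gene_id", "weight")], path, progress = FALSE)
  invisible(path)
}

#' Packaged synthetic 215-gene signature
#'
#' A synthetic stand-in with the structure of the published CLL-derived RS
#' expression signature: 122 genes weighted +1 (over-expressed in CLL-derived
#' RS) and 93 weighted -1 (under-expressed). The gene identifiers are
#' simulated, not the published gene list; the fixture exists so the LCS
#' machinery can be exercised with a signature of realistic size and
#' composition.
#'
#' @return A `gene_signature` tibble with 215 rows.
#' @export
rs_signature <- function() {
  read_signature(system.file("extdata", "synthetic_signature_215.tsv",
                             package = "rsclassify", mustWork = TRUE))
}
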