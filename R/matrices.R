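#' Validated feature-by-sample matrices
#'
#' Methylation and expression data move through the pipeline as plain numeric
#' matrices with features on rows and samples on columns, wrapped in thin S3
#' classes that enforce the domain invariants at construction time:
#'
#' * `beta_matrix()` — methylation fractions in \[0, 1\] (`NA` allowed for
#'   failed positions);
#' * `m_matrix()` — finite M-values (log2-odds of methylation);
#' * `count_matrix()` — non-negative integral read counts;
#' * `expr_matrix()` — finite normalized expression (log2-CPM).
#'
#' Row and column names are mandatory and must be unique: they are the CpG /
#' gene / transcript and sample identifiers used for all joins downstream.
#'
#' @param x A numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @return A matrix of class `rs_beta` / `rs_m` / `rs_counts` / `rs_expr`
#'   (all also inherit `rs_matrix`).
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.4), 2,
#'                         dimnames = list(c("cg1", "cg2"), c("s1", "s2"))))
#' beta_to_m(b)
#' @name rs_matrix
NULL

.check_dimnames <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("matrix must carry feature ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    abort(paste0("duplicate feature ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    abort(paste0("duplicate sample ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname rs_matrix
#' @export
beta_matrix <- function(x) {
  .check_dimnames(x)
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    feat <- rownames(x)[((bad[1] - 1) %% nrow(x)) + 1]
    abort(paste0("beta values outside [0,1]; first offending feature: ", feat))
  }
  structure(x, class = c("rs_beta", "rs_matrix", class(matrix())))
}

#' @rdname rs_matrix
#' @export
m_matrix <- function(x) {
  .check_dimnames(x)
  if (any(!is.finite(x) & !is.na(x))) {
    abort("M-values must be finite.")
  }
  structure(x, class = c("rs_m", "rs_matrix", class(matrix())))
}

#' @rdname rs_matrix
#' @export
count_matrix <- function(x) {
  .check_dimnames(x)
  if (anyNA(x)) abort("counts must not be missing.")
  if (any(x < 0)) {
    feat <- rownames(x)[which(apply(x < 0, 1, any))[1]]
    abort(paste0("negative count; first offending feature: ", feat))
  }
  if (any(x != round(x))) {
    feat <- rownames(x)[which(apply(x != round(x), 1, any))[1]]
    abort(paste0("non-integer count; first offending feature: ", feat))
  }
  structure(x, class = c("rs_counts", "rs_matrix", class(matrix())))
}

#' @rdname rs_matrix
#' @export
expr_matrix <- function(x) {
  .check_dimnames(x)
  if (any(!is.finite(x))) abort("expression values must be finite.")
  structure(x, class = c("rs_expr", "rs_matrix", class(matrix())))
}

#' Library sizes of a count matrix
#'
#' Per-sample column sums of raw counts, in reads.
#'
#' @param counts A [count_matrix()].
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(counts) {
  colSums(unclass(counts))
}

.strip <- function(x) {
  y <- unclass(x)
  class(y) <- class(matrix())
  y
}

#' Read / write feature-by-sample matrices
#'
#' Delimited text with a header row of sample ids and a first column of
#' feature ids. Tab is the default separator; comma is accepted. Writers
#' always emit TSV. Values round-trip exactly (shortest round-trippable
#' decimal representation).
#'
#' @param path File path.
#' @param kind One of `"beta"`, `"count"`, `"expression"`, `"m"`; selects the
#'   validation applied to the parsed values.
#' @param x An `rs_matrix`.
#' @return `read_matrix()` returns the validated matrix class matching
#'   `kind`; `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, kind = c("beta", "count", "expression", "m")) {
  kind <- match.arg(kind)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # base parser: correctly-rounded doubles, so written matrices re-load exactly
  tb <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 2) abort(paste0("parse error in ", path, ": need id column plus samples"))
  ids <- as.character(tb[[1]])
  vals <- as.matrix(tb[-1])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tb[-1], is.numeric, logical(1)))[1] + 1
    abort(paste0("parse error in ", path, ": non-numeric column ", names(tb)[bad]))
  }
  rownames(vals) <- ids
  switch(kind,
    beta = beta_matrix(vals),
    count = count_matrix(vals),
    expression = expr_matrix(vals),
    m = m_matrix(vals)
  )
}

#' @rdname read_matrix
#' @export
write_matrix <- function(x, path) {
  v <- .strip(x)
  # shortest decimal representation that round-trips the double exactly
  chr <- sprintf("%.15g", v)
  bad <- as.numeric(chr) != v
  if (any(bad)) chr[bad] <- sprintf("%.17g", v[bad])
  chr <- matrix(chr, nrow(v))
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert between methylation beta- and M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into \[eps, 1 - eps\] so
#' the transform stays finite at fully (un)methylated sites; the inverse is
#' beta = 2^M / (1 + 2^M). Statistics run on M-values (roughly homoskedastic),
#' scores and interpretation use beta-values.
#'
#' @param b A [beta_matrix()].
#' @param m An [m_matrix()].
#' @param eps Clipping bound, in (0, 0.5). Default `1e-6`.
#' @return The transformed matrix ([m_matrix()] or [beta_matrix()]).
#' @export
beta_to_m <- function(b, eps = 1e-6) {
  stopifnot(inherits(b, "rs_beta"))
  if (!(eps > 0 && eps < 0.5)) abort("`eps` must be in (0, 0.5).")
  v <- pmin(pmax(.strip(b), eps), 1 - eps)
  m_matrix(log2(v / (1 - v)))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  stopifnot(inherits(m, "rs_m"))
  v <- .strip(m)
  beta_matrix(1 / (1 + 2^(-v)))
}

#' Sample sheets
#'
#' A sample sheet is a tibble with one row per sample: `sample_id` (unique),
#' `group` in CLL / DLBCL / RS / NORMAL, `ighv_status` in U / M / unknown,
#' optional `batch`, and optional numeric covariate columns (e.g. estimated
#' cell fractions in \[0, 1\]) used as additive adjustment terms in the
#' differential models.
#'
#' @param df A data frame with at least `sample_id` and `group`.
#' @return A validated tibble of class `rs_sheet`.
#' @export
sample_sheet <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("sample sheet needs `sample_id` and `group` columns.")
  }
  if (anyDuplicated(df$sample_id)) abort("sample_ids must be unique.")
  bad <- setdiff(unique(df$group), .rs_groups)
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  if (!"ighv_status" %in% names(df)) df$ighv_status <- "unknown"
  bad <- setdiff(unique(df$ighv_status), .rs_ighv)
  if (length(bad)) {
    abort(paste0("unknown ighv_status: ", paste(bad, collapse = ", ")))
  }
  structure(df, class = c("rs_sheet", class(df)))
}

#' @rdname sample_sheet
#' @param path TSV file with named columns.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Restrict and order a matrix to the samples of a sheet
#'
#' Columns are reordered to match the sheet; matrix columns absent from the
#' sheet are dropped with a message. Samples in the sheet but not in the
#' matrix are an error.
#'
#' @param x An `rs_matrix`.
#' @param sheet A [sample_sheet()].
#' @return `x` with columns in sheet order.
#' @export
align_samples <- function(x, sheet) {
  missing <- setdiff(sheet$sample_id, colnames(x))
  if (length(missing)) {
    abort(paste0("samples absent from matrix: ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(colnames(x), sheet$sample_id)
  if (length(extra)) {
    inform(paste0("dropping ", length(extra), " matrix column(s) not in sample sheet"))
  }
  cls <- class(x)
  out <- .strip(x)[, sheet$sample_id, drop = FALSE]
  structure(out, class = cls)
}

#' Drop features with missing values
#'
#' Downstream statistics require complete rows; rows containing `NA` are
#' removed with a message reporting the count.
#'
#' @param x An `rs_matrix`.
#' @return `x` restricted to complete rows.
#' @export
drop_incomplete_features <- function(x) {
  keep <- complete.cases(.strip(x))
  if (!all(keep)) {
    inform(paste0("dropping ", sum(!keep), " feature(s) with missing values"))
  }
  cls <- class(x)
  structure(.strip(x)[keep, , drop = FALSE], class = cls)
}

#' CpG and gene annotations
#'
#' `cpg_annotation()` validates a long-format CpG table: one row per
#' CpG-to-gene link with columns `cpg_id`, `chrom`, `pos` (1-based bp),
#' `gene_id` (`NA` for intergenic probes) and `feature_class` from the closed
#' vocabulary TSS200 / TSS1500 / FirstExon / FiveUTR / Body / ThreeUTR /
#' Intergenic. `gene_annotation()` validates a gene/transcript table with
#' `gene_id`, `transcript_id`, `chrom`, `tss` (1-based bp), `strand` and
#' `biotype`.
#'
#' @param df A data frame.
#' @return A validated tibble.
#' @export
cpg_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("cpg_id", "chrom", "pos", "gene_id", "feature_class")
  if (!all(need %in% names(df))) {
    abort(paste0("cpg annotation needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(df$pos < 1)) abort("positions are 1-based; pos must be >= 1.")
  bad <- setdiff(unique(df$feature_class), .rs_feature_classes)
  if (length(bad)) {
    abort(paste0("unknown feature_class: ", paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname cpg_annotation
#' @export
gene_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("gene_id", "transcript_id", "chrom", "tss", "strand", "biotype")
  if (!all(need %in% names(df))) {
    abort(paste0("gene annotation needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(df$tss < 1)) abort("tss coordinates are 1-based; tss must be >= 1.")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (anyDuplicated(df$transcript_id)) abort("transcript_ids must be unique.")
  df
}

#' Read CpG positions from a BED file
#'
#' BED is 0-based half-open; positions are converted to the package's 1-based
#' inclusive convention at the reader boundary (`pos = start + 1`). The
#' optional 4th column is taken as the CpG id.
#'
#' @param path BED file path.
#' @return Tibble with `cpg_id`, `chrom`, `pos`.
#' @export
read_cpg_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(tb) < 3) abort(paste0("parse error in ", path, ": BED needs >= 3 columns"))
  tibble::tibble(
    cpg_id = if (ncol(tb) >= 4) as.character(tb[[4]]) else paste0("cpg", seq_len(nrow(tb))),
    chrom = as.character(tb[[1]]),
    pos = as.integer(tb[[2]]) + 1L
  )
}

#' @rdname read_cpg_bed
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos` (1-based).
#' @export
write_cpg_bed <- function(cpgs, path) {
  bed <- tibble::tibble(chrom = cpgs$chrom,
                        start = as.integer(cpgs$pos) - 1L,
                        end = as.integer(cpgs$pos),
                        name = cpgs$cpg_id)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
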