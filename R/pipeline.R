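#' Run the full multi-omics classification pipeline
#'
#' Orchestrates the stages end to end on an in-memory cohort bundle:
#'
#' 1. methylation differential testing and LPS training on the CLL/DLBCL
#'    references, scoring and labeling of the RS samples;
#' 2. count filtering, TMM normalization, log2-CPM transform;
#' 3. methylome-transcriptome integrome on the RS samples, correlation
#'    filtering, candidate promoter-region selection;
#' 4. signature derivation from the expression clustering (up/down cluster
#'    pair, protein-coding and integrome-supported genes);
#' 5. LCS scoring of the expression cohort with the derived signature.
#'
#' Every stage threshold defaults to the value used throughout the package
#' (FDR 0.01, beta-differential 0.30, posterior 0.98, alpha 0.05, top
#' fraction 0.25, window 2000 bp, >= 3 CpGs, rho 1/3, correlation p 0.001).
#' No stage mutates its inputs. The run report collects per-stage feature
#' counts (the "selection funnel").
#'
#' @param cohort A bundle from [simulate_cohort()] / [make_gold_cohort()],
#'   or an equivalently named list of real data (`beta`, `counts`, `sheet`,
#'   `cpg_ann`, `gene_ann`).
#' @param fdr,delta_beta_cut,lps_threshold LPS stage thresholds.
#' @param alpha,top_fraction LCS stage thresholds.
#' @param window,min_cpgs,rho_cut,p_cut Integration stage thresholds.
#' @param out_dir Optional directory: artifacts written as TSV/JSON.
#' @return List of class `rs_pipeline`: `lps_model`, `lps_results`,
#'   `factors`, `expr`, `integrome`, `candidates`, `candidate_genes`,
#'   `signature`, `lcs_results`, `report`.
#' @export
run_rs_pipeline <- function(cohort,
                            fdr = 0.01, delta_beta_cut = 0.30,
                            lps_threshold = 0.98,
                            alpha = 0.05, top_fraction = 0.25,
                            window = 2000, min_cpgs = 3, rho_cut = 1 / 3,
                            p_cut = 0.001, out_dir = NULL) {
  sheet <- cohort$sheet
  m <- beta_to_m(cohort$beta)

  model <- lps_train(cohort$beta, m, sheet, fdr_cut = fdr,
                     delta_cut = delta_beta_cut, threshold = lps_threshold)
  lps_results <- lps_score(cohort$beta, model, sheet)

  prep <- prepare_expression(cohort$counts)

  rs_sheet <- sheet[sheet$group == "RS", , drop = FALSE]
  rs_sheet <- rs_sheet[rs_sheet$sample_id %in% colnames(prep$expr), , drop = FALSE]
  integrome <- build_integrome(cohort$cpg_ann, cohort$gene_ann, window = window)
  feat_map <- tibble::tibble(feature_id = cohort$gene_ann$transcript_id,
                             gene_id = cohort$gene_ann$gene_id)
  expr_rs <- align_samples(prep$expr, rs_sheet)
  rownames_expr <- feat_map$feature_id[match(rownames(expr_rs), feat_map$gene_id)]
  expr_t <- .strip(expr_rs)
  rownames(expr_t) <- ifelse(is.na(rownames_expr), rownames(expr_t), rownames_expr)
  assocs <- compute_correlations(integrome, align_samples(cohort$beta, rs_sheet),
                                 expr_matrix(expr_t))
  significant <- filter_significant(assocs)
  candidates <- select_candidates(assocs, min_cpgs = min_cpgs,
                                  rho_cut = rho_cut, p_cut = p_cut)
  cand_genes <- candidate_genes(candidates)

  # label RS expression samples by their LPS call for signature derivation
  lcs_sheet <- sheet[sheet$sample_id %in% colnames(prep$expr), , drop = FALSE]
  lab <- lps_results$label[match(lcs_sheet$sample_id, lps_results$sample_id)]
  der_sheet <- lcs_sheet
  der_sheet$lps_side <- dplyr::case_when(
    der_sheet$group == "CLL" | lab == "CLL_derived" ~ "CLL_side",
    der_sheet$group == "DLBCL" | lab == "DLBCL_like" ~ "DLBCL_side",
    TRUE ~ "other"
  )
  expr_der <- align_samples(prep$expr, der_sheet)
  top_var <- order(apply(.strip(expr_der), 1, var), decreasing = TRUE)
  n_clust <- min(nrow(expr_der), 1000L)
  expr_clust <- expr_matrix(.strip(expr_der)[top_var[seq_len(n_clust)], , drop = FALSE])
  signature <- tryCatch(
    derive_signature(expr_clust, der_sheet, c("CLL_side", "DLBCL_side"),
                     cohort$gene_ann, integrome_genes = cand_genes$union,
                     group_var = "lps_side"),
    error = function(e) {
      warn(paste0("signature derivation fell back to unfiltered clusters: ",
                  conditionMessage(e)))
      derive_signature(expr_clust, der_sheet, c("CLL_side", "DLBCL_side"),
                       cohort$gene_ann, integrome_genes = NULL,
                       group_var = "lps_side")
    }
  )
  lcs_results <- lcs_score(prep$expr, signature, alpha = alpha,
                           top_fraction = top_fraction)

  report <- tibble::tibble(
    stage = c("input_cpgs", "input_genes", "scoring_cpgs",
              "rs_scored", "rs_cll_derived", "rs_dlbcl_like", "rs_intermediate",
              "genes_after_filter", "integrome_associations",
              "significant_correlations", "candidate_regions",
              "candidate_genes", "signature_genes", "lcs_significant"),
    count = c(nrow(cohort$beta), nrow(cohort$counts),
              length(model$scoring_cpgs),
              sum(lps_results$group == "RS"),
              sum(lps_results$group == "RS" & lps_results$label == "CLL_derived"),
              sum(lps_results$group == "RS" & lps_results$label == "DLBCL_like"),
              sum(lps_results$group == "RS" & lps_results$label == "intermediate"),
              nrow(prep$counts), nrow(assocs), nrow(significant),
              nrow(candidates), length(cand_genes$union), nrow(signature),
              sum(lcs_results$significant))
  )

  out <- structure(
    list(lps_model = model, lps_results = lps_results, factors = prep$factors,
         expr = prep$expr, integrome = assocs, candidates = candidates,
         candidate_genes = cand_genes, signature = signature,
         lcs_results = lcs_results, report = report),
    class = "rs_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_lps_model(model, file.path(out_dir, "lps_model.json"))
    readr::write_tsv(lps_results, file.path(out_dir, "lps_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(prep$factors, file.path(out_dir, "tmm_factors.tsv"),
                     progress = FALSE)
    readr::write_tsv(assocs, file.path(out_dir, "integrome.tsv"), progress = FALSE)
    cand_flat <- candidates
    cand_flat$cpg_ids <- vapply(cand_flat$cpg_ids, paste, "", collapse = ",")
    cand_flat$feature_classes <- vapply(cand_flat$feature_classes, paste, "",
                                        collapse = ",")
    readr::write_tsv(cand_flat, file.path(out_dir, "candidate_regions.tsv"),
                     progress = FALSE)
    write_signature(signature, file.path(out_dir, "signature.tsv"))
    readr::write_tsv(lcs_results, file.path(out_dir, "lcs_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(report, file.path(out_dir, "run_report.tsv"), progress = FALSE)
  }
  out
}

#' @export
print.rs_pipeline <- function(x, ...) {
  cat("rsclassify pipeline run\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-26s %d\n", x$report$stage[i], x$report$count[i]))
  }
  invisible(x)
}
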