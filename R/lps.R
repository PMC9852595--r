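#' Select the scoring CpGs for the methylation linear predictor score
#'
#' Three-step cascade on the reference groups:
#' (i) keep CpGs differentially methylated between CLL and DLBCL at
#' `q < fdr_cut`, retaining their moderated t-statistics as weights;
#' (ii) remove CpGs that are also differential between IGHV-unmutated and
#' IGHV-mutated CLL at `q < fdr_cut`, so the score reflects the CLL/DLBCL
#' axis rather than B-cell IGHV maturity;
#' (iii) remove CpGs whose absolute beta-differential between CLL and DLBCL
#' is `<= delta_cut`, keeping only strongly separating sites.
#'
#' @param m [m_matrix()] aligned to `sheet` (statistics run on M-values).
#' @param b Matching [beta_matrix()] (beta-differentials and scoring).
#' @param sheet A [sample_sheet()] containing CLL and DLBCL samples, with
#'   `ighv_status` filled in for the CLL group.
#' @param fdr_cut FDR threshold for both differential screens (default 0.01).
#' @param delta_cut Minimum absolute beta-differential (default 0.30, i.e.
#'   a >30% methylation difference).
#' @param covariates Optional sheet covariates for the linear models.
#' @return Tibble: `cpg_id`, `weight` (moderated t), `delta_beta`, `q`.
#' @export
select_scoring_cpgs <- function(m, b, sheet, fdr_cut = 0.01, delta_cut = 0.30,
                                covariates = character()) {
  ref <- sheet[sheet$group %in% c("CLL", "DLBCL"), , drop = FALSE]
  res <- diff_test(align_samples(m, ref), ref, c("CLL", "DLBCL"),
                   b = align_samples(b, ref), covariates = covariates)
  hits <- res[!is.na(res$q) & res$q < fdr_cut, , drop = FALSE]
  if (!nrow(hits)) {
    abort("no CpGs pass the CLL-vs-DLBCL FDR cut; consider relaxing `fdr_cut`.")
  }
  cll <- sheet[sheet$group == "CLL" & sheet$ighv_status %in% c("U", "M"), ,
               drop = FALSE]
  if (length(unique(cll$ighv_status)) == 2 &&
      min(table(cll$ighv_status)) >= 2) {
    ighv <- diff_test(align_samples(m, cll), cll, c("U", "M"),
                      covariates = covariates, group_var = "ighv_status")
    ighv_hits <- ighv$feature_id[!is.na(ighv$q) & ighv$q < fdr_cut]
    hits <- hits[!hits$feature_id %in% ighv_hits, , drop = FALSE]
  } else {
    warn("CLL group lacks both IGHV statuses; skipping the IGHV exclusion step.")
  }
  hits <- hits[abs(hits$delta_beta) > delta_cut, , drop = FALSE]
  if (!nrow(hits)) {
    abort("no CpGs survive the selection cascade; consider relaxing the cuts.")
  }
  tibble::tibble(cpg_id = hits$feature_id, weight = hits$t_mod,
                 delta_beta = hits$delta_beta, q = hits$q)
}

#' Compute linear predictor scores
#'
#' The LPS of a sample is the weighted sum of its beta-values over the
#' scoring CpGs, `LPS(S) = sum_i t_i * S_i`, where `t_i` is the moderated
#' t-statistic of CpG i from the reference contrast.
#'
#' @param b A [beta_matrix()] containing every scoring CpG.
#' @param model An `lps_model` (from [lps_train()]) or a tibble with
#'   `cpg_id` and `weight` columns.
#' @return Tibble: `sample_id`, `lps`.
#' @export
compute_lps <- function(b, model) {
  w <- if (inherits(model, "lps_model")) {
    setNames(model$weights, model$scoring_cpgs)
  } else {
    setNames(model$weight, model$cpg_id)
  }
  missing <- setdiff(names(w), rownames(b))
  if (length(missing)) {
    abort(paste0("scoring CpG(s) absent from beta matrix: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) paste0(" (+", length(missing) - 5, " more)")))
  }
  v <- .strip(b)[names(w), , drop = FALSE]
  tibble::tibble(sample_id = colnames(v), lps = as.numeric(crossprod(v, w)))
}

#' Fit the reference-group score distributions
#'
#' Sample mean and unbiased sample variance of the LPS within each reference
#' group (CLL and DLBCL); these parameterize the Gaussian densities of the
#' posterior.
#'
#' @param lps Tibble from [compute_lps()].
#' @param sheet A [sample_sheet()].
#' @return List: `mu_cll`, `var_cll`, `mu_dlbcl`, `var_dlbcl`.
#' @export
fit_group_distributions <- function(lps, sheet) {
  out <- list()
  for (g in c("CLL", "DLBCL")) {
    ids <- sheet$sample_id[sheet$group == g]
    x <- lps$lps[match(ids, lps$sample_id)]
    x <- x[!is.na(x)]
    if (length(x) < 3) abort(paste0("need >= 3 ", g, " reference samples."))
    v <- var(x)
    if (v <= 0) abort(paste0("zero LPS variance in the ", g, " reference group."))
    key <- tolower(g)
    out[[paste0("mu_", key)]] <- mean(x)
    out[[paste0("var_", key)]] <- v
  }
  out
}

#' Posterior probability of CLL origin
#'
#' Ratio of Gaussian densities under the two fitted reference distributions,
#' `p_cll = phi(x; mu_CLL, var_CLL) / (phi_CLL + phi_DLBCL)`, evaluated in
#' log space so well-separated groups do not underflow; `p_dlbcl = 1 - p_cll`
#' exactly by construction.
#'
#' @param lps_value Numeric vector of LPS values.
#' @param model An `lps_model` or a list with `mu_cll`, `var_cll`,
#'   `mu_dlbcl`, `var_dlbcl`.
#' @return Tibble: `p_cll`, `p_dlbcl`.
#' @export
lps_posterior <- function(lps_value, model) {
  lc <- dnorm(lps_value, model$mu_cll, sqrt(model$var_cll), log = TRUE)
  ld <- dnorm(lps_value, model$mu_dlbcl, sqrt(model$var_dlbcl), log = TRUE)
  p_cll <- 1 / (1 + exp(ld - lc))
  tibble::tibble(p_cll = p_cll, p_dlbcl = 1 - p_cll)
}

#' Label samples from posterior probabilities
#'
#' `CLL_derived` when `p_cll >= threshold`, `DLBCL_like` when
#' `p_dlbcl >= threshold` (both thresholds inclusive), otherwise
#' `intermediate`. With the default 0.98 the intermediate band is the score
#' region where the two reference densities overlap by more than 2% either
#' way.
#'
#' @param p_cll,p_dlbcl Posterior probabilities (must sum to 1).
#' @param threshold Posterior cutoff in (0.5, 1\]; default 0.98.
#' @return Character vector of labels.
#' @export
lps_classify <- function(p_cll, p_dlbcl, threshold = 0.98) {
  if (!(threshold > 0.5 && threshold <= 1)) abort("`threshold` must be in (0.5, 1].")
  dplyr::case_when(
    p_cll >= threshold ~ "CLL_derived",
    p_dlbcl >= threshold ~ "DLBCL_like",
    TRUE ~ "intermediate"
  )
}

#' Train an LPS model on reference groups
#'
#' Runs the CpG selection cascade on the CLL and DLBCL reference samples,
#' computes their LPS, and fits the group Gaussian parameters. The returned
#' `lps_model` can score any cohort carrying the scoring CpGs.
#'
#' @inheritParams select_scoring_cpgs
#' @param threshold Posterior cutoff stored with the model (default 0.98).
#' @return An object of class `lps_model`: scoring CpG ids, weights, group
#'   means/variances, threshold.
#' @examples
#' cohort <- make_gold_cohort("small", seed = 7)
#' model <- lps_train(cohort$beta, beta_to_m(cohort$beta), cohort$sheet)
#' res <- lps_score(cohort$beta, model, cohort$sheet)
#' table(res$label[res$group == "RS"])
#' @export
lps_train <- function(b, m, sheet, fdr_cut = 0.01, delta_cut = 0.30,
                      threshold = 0.98, covariates = character()) {
  sel <- select_scoring_cpgs(m, b, sheet, fdr_cut, delta_cut, covariates)
  ref <- sheet[sheet$group %in% c("CLL", "DLBCL"), , drop = FALSE]
  lps <- compute_lps(align_samples(b, ref), sel)
  pars <- fit_group_distributions(lps, ref)
  structure(
    c(list(scoring_cpgs = sel$cpg_id, weights = sel$weight,
           threshold = threshold, version = "1.0"),
      pars),
    class = "lps_model"
  )
}

#' Score and label samples with a trained LPS model
#'
#' @param b A [beta_matrix()] containing the model's scoring CpGs.
#' @param model An `lps_model` from [lps_train()] or [read_lps_model()].
#' @param sheet Optional [sample_sheet()]; when given, columns are aligned
#'   and `group` is carried into the result.
#' @return A tibble of class `lps_result`: `sample_id`, (`group`,) `lps`,
#'   `p_cll`, `p_dlbcl`, `label`.
#' @export
lps_score <- function(b, model, sheet = NULL) {
  if (!is.null(sheet)) b <- align_samples(b, sheet)
  out <- compute_lps(b, model)
  post <- lps_posterior(out$lps, model)
  out <- dplyr::bind_cols(out, post)
  out$label <- lps_classify(out$p_cll, out$p_dlbcl, model$threshold)
  if (!is.null(sheet)) {
    out <- dplyr::left_join(out, sheet[, c("sample_id", "group")], by = "sample_id")
    out <- out[, c("sample_id", "group", "lps", "p_cll", "p_dlbcl", "label")]
  }
  class(out) <- c("lps_result", class(out))
  out
}

#' Serialize an LPS model to JSON
#'
#' Versioned JSON document holding the scoring CpGs, weights, group Gaussian
#' parameters and threshold, so a trained model can be applied to external
#' cohorts without retraining.
#'
#' @param model An `lps_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lps_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lps_model
#' @export
read_lps_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$scoring_cpgs <- as.character(obj$scoring_cpgs)
  obj$weights <- as.numeric(obj$weights)
  structure(obj, class = "lps_model")
}

#' @export
print.lps_model <- function(x, ...) {
  cat("LPS model:", length(x$scoring_cpgs), "scoring CpGs\n")
  cat(sprintf("  CLL reference:   mu = %.3f, var = %.3f\n", x$mu_cll, x$var_cll))
  cat(sprintf("  DLBCL reference: mu = %.3f, var = %.3f\n", x$mu_dlbcl, x$var_dlbcl))
  cat(sprintf("  posterior threshold: %.2f\n", x$threshold))
  invisible(x)
}

#' Tidy an LPS model
#'
#' @param x An `lps_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per scoring CpG (`cpg_id`, `weight`);
#'   `glance()`: a one-row model summary.
#' @method tidy lps_model
#' @export
tidy.lps_model <- function(x, ...) {
  tibble::tibble(cpg_id = x$scoring_cpgs, weight = x$weights)
}

#' @rdname tidy.lps_model
#' @method glance lps_model
#' @export
glance.lps_model <- function(x, ...) {
  tibble::tibble(n_cpgs = length(x$scoring_cpgs),
                 mu_cll = x$mu_cll, var_cll = x$var_cll,
                 mu_dlbcl = x$mu_dlbcl, var_dlbcl = x$var_dlbcl,
                 threshold = x$threshold)
}
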