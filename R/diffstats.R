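#' Per-feature linear models for a two-group contrast
#'
#' Fits, for every feature (row), an ordinary least-squares model of the
#' response on group membership plus optional additive numeric covariates from
#' the sample sheet, and extracts the contrast coefficient
#' `contrast[1] - contrast[2]`. The heavy lifting is delegated to
#' limma's array-wide least squares ([limma::lmFit()]).
#'
#' @param y An [m_matrix()] (methylation) or [expr_matrix()] (expression),
#'   columns aligned to `sheet`.
#' @param sheet A [sample_sheet()]; only samples whose `group` is in
#'   `contrast` are used.
#' @param contrast Character vector of two group labels, compared as
#'   `contrast[1] - contrast[2]`.
#' @param covariates Names of numeric `sheet` columns entered as additive
#'   fixed effects.
#' @param group_var Sheet column holding the group labels (default
#'   `"group"`; use `"ighv_status"` for the U-CLL vs M-CLL comparison).
#' @return A list with `table` (tibble: `feature_id`, `effect`, `s2`,
#'   `stdev_unscaled`, `df`) and `n_samples`.
#' @export
fit_feature_models <- function(y, sheet, contrast, covariates = character(),
                               group_var = "group") {
  stopifnot(length(contrast) == 2)
  labs <- sheet[[group_var]]
  if (!all(contrast %in% labs)) {
    abort(paste0("contrast group(s) absent from sheet: ",
                 paste(setdiff(contrast, labs), collapse = ", ")))
  }
  keep <- labs %in% contrast
  sub <- sheet[keep, , drop = FALSE]
  if (min(table(sub[[group_var]])) < 2) {
    abort("need >= 2 samples per contrast group.")
  }
  ymat <- .strip(y)[, sub$sample_id, drop = FALSE]
  grp <- factor(sub[[group_var]], levels = contrast)
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- c("g1", "g2")
  for (cv in covariates) {
    if (!cv %in% names(sub)) abort(paste0("covariate not in sheet: ", cv))
    if (!is.numeric(sub[[cv]])) abort(paste0("covariate not numeric: ", cv))
    design <- cbind(design, sub[[cv]])
    colnames(design)[ncol(design)] <- cv
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[-seq_len(qr_d$rank)]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- limma::lmFit(ymat, design)
  cm <- matrix(0, ncol(design), 1, dimnames = list(colnames(design), "diff"))
  cm[c("g1", "g2"), 1] <- c(1, -1)
  cfit <- limma::contrasts.fit(fit, cm)
  list(
    table = tibble::tibble(
      feature_id = rownames(ymat),
      effect = as.numeric(cfit$coefficients[, 1]),
      s2 = as.numeric(cfit$sigma)^2,
      stdev_unscaled = as.numeric(cfit$stdev.unscaled[, 1]),
      df = as.numeric(cfit$df.residual)
    ),
    n_samples = nrow(sub)
  )
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Shrinks per-feature residual variances toward a common prior using the
#' scaled inverse-chi-square hierarchical model behind the moderated t-test
#' (moments estimation on log variances, as in [limma::squeezeVar()]):
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar or per-feature).
#' @return A list: `d0` (prior df, `Inf` when all variances coincide),
#'   `s0_2` (prior variance), `s2_post` (posterior variances).
#' @export
squeeze_variances <- function(s2, df) {
  if (length(s2) < 2) abort("need >= 2 features to estimate the variance prior.")
  sq <- limma::squeezeVar(s2, df)
  list(d0 = sq$df.prior, s0_2 = sq$var.prior, s2_post = sq$var.post)
}

#' Moderated t-statistics and two-sided p-values
#'
#' `t_mod = effect / (stdev_unscaled * sqrt(s2_post))`, referred to a Student
#' t distribution on `df + d0` total degrees of freedom. Features with a zero
#' standard error are flagged (`p = NaN`) and reported, not assigned an
#' infinite statistic.
#'
#' @param effect Contrast coefficients.
#' @param stdev_unscaled Unscaled standard errors from the linear model.
#' @param s2_post Posterior variances from [squeeze_variances()].
#' @param df_total Residual df plus prior df.
#' @return Tibble with `t_mod` and `p`.
#' @export
moderated_t <- function(effect, stdev_unscaled, s2_post, df_total) {
  se <- stdev_unscaled * sqrt(s2_post)
  t_mod <- effect / se
  bad <- !is.finite(se) | se == 0
  if (any(bad)) {
    inform(paste0(sum(bad), " feature(s) with zero standard error flagged (p = NaN)"))
    t_mod[bad] <- NaN
  }
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  tibble::tibble(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i}(m * p_(j) / j)`, capped at 1 and
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
adjust_bh <- function(p) {
  p.adjust(p, method = "BH")
}

#' Group difference of mean beta-values
#'
#' The "beta-value differential": mean beta in `contrast[1]` minus mean beta
#' in `contrast[2]`, per CpG. Used for the interpretable effect-size filter
#' (statistics themselves run on M-values).
#'
#' @inheritParams fit_feature_models
#' @param b A [beta_matrix()].
#' @return Tibble with `feature_id`, `delta_beta` (in \[-1, 1\]).
#' @export
delta_beta <- function(b, sheet, contrast, group_var = "group") {
  stopifnot(length(contrast) == 2)
  g1 <- sheet$sample_id[sheet[[group_var]] == contrast[1]]
  g2 <- sheet$sample_id[sheet[[group_var]] == contrast[2]]
  if (!length(g1) || !length(g2)) abort("both contrast groups must be non-empty.")
  v <- .strip(b)
  tibble::tibble(
    feature_id = rownames(v),
    delta_beta = unname(rowMeans(v[, g1, drop = FALSE]) -
                          rowMeans(v[, g2, drop = FALSE]))
  )
}

#' Differential testing with the moderated t
#'
#' One call from matrix to result table: per-feature linear fit, variance
#' shrinkage, moderated t, BH adjustment, and (for methylation) the group
#' beta-differential. Features with zero residual variance across all samples
#' are excluded before moderation with a message.
#'
#' @inheritParams fit_feature_models
#' @param y Response matrix (M-values or log2-CPM), columns aligned to
#'   `sheet`.
#' @param b Optional [beta_matrix()] on the same features, used to add the
#'   `delta_beta` column for methylation contrasts.
#' @return Tibble: `feature_id`, `effect`, `delta_beta` (`NA` when `b` is
#'   absent), `t_mod`, `p`, `q`, `df_total`.
#' @examples
#' cohort <- make_gold_cohort("small", seed = 7)
#' m <- beta_to_m(cohort$beta)
#' res <- diff_test(m, cohort$sheet, c("CLL", "DLBCL"), b = cohort$beta)
#' head(res)
#' @export
diff_test <- function(y, sheet, contrast, b = NULL, covariates = character(),
                      group_var = "group") {
  fit <- fit_feature_models(y, sheet, contrast, covariates, group_var)
  tab <- fit$table
  zero_var <- tab$s2 <= 0 | !is.finite(tab$s2)
  if (any(zero_var)) {
    inform(paste0("excluding ", sum(zero_var),
                  " feature(s) with zero residual variance"))
    tab <- tab[!zero_var, , drop = FALSE]
  }
  if (!nrow(tab)) abort("no features left after removing zero-variance rows.")
  sq <- squeeze_variances(tab$s2, tab$df)
  df_total <- tab$df + sq$d0
  mt <- moderated_t(tab$effect, tab$stdev_unscaled, sq$s2_post, df_total)
  out <- tibble::tibble(
    feature_id = tab$feature_id,
    effect = tab$effect,
    delta_beta = NA_real_,
    t_mod = mt$t_mod,
    p = mt$p,
    q = adjust_bh(mt$p),
    df_total = df_total
  )
  if (!is.null(b)) {
    db <- delta_beta(b, sheet[sheet[[group_var]] %in% contrast, , drop = FALSE],
                     contrast, group_var)
    out$delta_beta <- db$delta_beta[match(out$feature_id, db$feature_id)]
  }
  out
}
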