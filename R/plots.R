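#' Plot LPS scores with reference densities
#'
#' Scores of all samples along the LPS axis, colored by assigned label, with
#' the fitted Gaussian densities of the CLL and DLBCL reference groups
#' overlaid when a model is supplied.
#'
#' @param object An `lps_result` tibble from [lps_score()].
#' @param model Optional `lps_model` providing the reference densities.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lps_result
#' @export
autoplot.lps_result <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lps, y = .data$p_cll,
                                            colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "linear predictor score (LPS)",
                  y = "posterior P(CLL-derived)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    rng <- range(object$lps)
    xs <- seq(rng[1] - diff(rng) * 0.1, rng[2] + diff(rng) * 0.1, length.out = 400)
    dens <- dplyr::bind_rows(
      tibble::tibble(x = xs, d = dnorm(xs, model$mu_cll, sqrt(model$var_cll)),
                     ref = "CLL reference"),
      tibble::tibble(x = xs, d = dnorm(xs, model$mu_dlbcl, sqrt(model$var_dlbcl)),
                     ref = "DLBCL reference"))
    dens$d <- dens$d / max(dens$d)
    p <- p + ggplot2::geom_line(
      data = dens, ggplot2::aes(x = .data$x, y = .data$d, linetype = .data$ref),
      inherit.aes = FALSE, colour = "grey40")
  }
  p
}

#' Plot ranked linear classifier scores
#'
#' Cohort z-scores in decreasing order, flagging significant samples and the
#' one-sided alpha = 0.05 normal quantile.
#'
#' @param object An `lcs_result` tibble from [lcs_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcs_result
#' @export
autoplot.lcs_result <- function(object, ...) {
  df <- object[order(-object$z), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = stats::qnorm(0.95), linetype = "dashed") +
    ggplot2::labs(x = "sample rank", y = "standardized LCS",
                  colour = "p < alpha") +
    ggplot2::theme_minimal()
}

#' Histogram of integrome correlations
#'
#' Distribution of per-association Spearman correlations with the selection
#' cutoffs at +/- rho_cut.
#'
#' @param assocs Tibble from [compute_correlations()].
#' @param rho_cut Cutoff drawn as vertical lines (default 1/3).
#' @return A ggplot object.
#' @export
plot_integrome <- function(assocs, rho_cut = 1 / 3) {
  ggplot2::ggplot(assocs, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey65") +
    ggplot2::geom_vline(xintercept = c(-rho_cut, rho_cut), linetype = "dashed") +
    ggplot2::labs(x = "Spearman rho (methylation vs expression)", y = "associations") +
    ggplot2::theme_minimal()
}
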