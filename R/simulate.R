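#' Simulation configuration
#'
#' Bundles all knobs of the synthetic cohort generator. Defaults mirror the
#' study conditions the classifiers were designed for: two CLL IGHV strata
#' and a DLBCL reference group of equal total size, an RS query group split
#' into CLL-derived and DLBCL-like subpopulations, planted CLL/DLBCL
#' differential CpGs at a 0.35 beta-differential, IGHV-associated CpGs, a
#' global RS hypomethylation shift, negative-binomial expression with
#' planted signature genes, and promoter-expression coupling at Spearman
#' rho -0.6.
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param n_cll_u,n_cll_m,n_dlbcl,n_rs_cll,n_rs_dlbcl Group sizes.
#' @param n_cpgs Number of CpGs.
#' @param frac_diff Fraction of CpGs differential between CLL and DLBCL.
#' @param delta_beta_effect Target absolute group beta-differential at
#'   planted CpGs (default 0.35).
#' @param frac_ighv Fraction of CpGs differential between U-CLL and M-CLL.
#' @param ighv_delta_beta Target beta-differential at IGHV CpGs.
#' @param rs_shift Global RS hypomethylation shift on the M scale
#'   (default -0.3; negative = hypomethylated).
#' @param noise_sd Per-sample Gaussian noise sd on the M scale.
#' @param n_genes Number of genes (one transcript each).
#' @param frac_signature Fraction of genes carrying a subgroup expression
#'   effect (half up, half down in the CLL-derived direction).
#' @param expression_effect_sd Signature effect size in log2 units.
#' @param n_promoters Number of genes with methylation-coupled promoters.
#' @param cpgs_per_promoter Range of supporting CpGs per promoter.
#' @param target_rho Target Spearman correlation at coupled promoters
#'   (default -0.6).
#' @param promoter_tau Promoter latent-factor loading on CpG M-values.
#' @param promoter_cpg_noise_sd Residual CpG noise sd at coupled promoters.
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param mean_library_size Mean sequencing depth in reads (default 2e7).
#' @param covariate_leak Coefficient leaking the simulated B-cell fraction
#'   into methylation as a nuisance effect (default 0 = off).
#' @param n_chroms Number of chromosomes genes are spread over.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_cll_u = 20, n_cll_m = 20, n_dlbcl = 40,
                              n_rs_cll = 30, n_rs_dlbcl = 10,
                              n_cpgs = 20000, frac_diff = 0.05,
                              delta_beta_effect = 0.35,
                              frac_ighv = 0.03, ighv_delta_beta = 0.30,
                              rs_shift = -0.3, noise_sd = 0.5,
                              n_genes = 5000, frac_signature = 0.04,
                              expression_effect_sd = 1,
                              n_promoters = 50, cpgs_per_promoter = 3:5,
                              target_rho = -0.6, promoter_tau = 0.9,
                              promoter_cpg_noise_sd = 0.3,
                              nb_dispersion = 0.1,
                              mean_library_size = 2e7,
                              covariate_leak = 0, n_chroms = 20) {
  if (missing(seed)) abort("`seed` is mandatory.")
  cfg <- as.list(environment())
  for (f in c("frac_diff", "frac_ighv", "frac_signature")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0, 1]."))
  }
  for (n in c("n_cll_u", "n_cll_m", "n_dlbcl")) {
    if (cfg[[n]] < 3) abort(paste0("`", n, "` must be >= 3 (reference group)."))
  }
  if (abs(cfg$target_rho) >= 1) abort("`target_rho` must be in (-1, 1).")
  if (cfg$delta_beta_effect <= 0 || cfg$delta_beta_effect > 0.9) {
    abort("`delta_beta_effect` must be in (0, 0.9].")
  }
  structure(cfg, class = "sim_config")
}

.logit2 <- function(b) log2(b / (1 - b))
.expit2 <- function(m) 1 / (1 + 2^(-m))

.sim_samples <- function(cfg) {
  n <- c(cfg$n_cll_u, cfg$n_cll_m, cfg$n_dlbcl, cfg$n_rs_cll, cfg$n_rs_dlbcl)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(sum(n))),
    group = rep(c("CLL", "CLL", "DLBCL", "RS", "RS"), n),
    ighv_status = rep(c("U", "M", "M", "unknown", "unknown"), n),
    stratum = rep(c("CLL_U", "CLL_M", "DLBCL", "RS_cll", "RS_dlbcl"), n)
  )
}

#' Simulate a methylation cohort
#'
#' Generates an array-like beta matrix with the structure the classifiers
#' assume: bimodal baseline methylation, planted CLL-vs-DLBCL differential
#' CpGs hitting the configured beta-differential, IGHV-associated CpGs
#' shifting only IGHV-unmutated samples, RS samples inheriting the CLL or
#' DLBCL regime of their true subgroup plus a global hypomethylation shift,
#' and promoter CpG blocks driven by a per-promoter latent factor that the
#' expression simulator later couples to. Effects are applied on the M
#' scale (additive beta effects saturate near 0/1) and transformed back.
#'
#' @param cfg A [simulation_config()].
#' @return List: `beta` ([beta_matrix()]), `sheet` ([sample_sheet()]),
#'   `cpg_ann` ([cpg_annotation()]), `truth` (planted parameters: see
#'   Details in the package vignette).
#' @export
simulate_methylation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- .sim_samples(cfg)
  ns <- nrow(samples)
  cpg_ids <- sprintf("cg%06d", seq_len(cfg$n_cpgs))

  # gene grid shared with the expression simulator
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  gene_coords <- tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
    transcript_id = sprintf("T%05d", seq_len(cfg$n_genes)),
    chrom = paste0("chr", ((seq_len(cfg$n_genes) - 1) %% cfg$n_chroms) + 1),
    tss = 5e4 + 1e5 * ((seq_len(cfg$n_genes) - 1) %/% cfg$n_chroms),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  )

  # role assignment: promoter blocks first (coupled, non-differential),
  # then CLL/DLBCL differential, then IGHV, remainder null
  n_per_prom <- sample(cfg$cpgs_per_promoter, cfg$n_promoters, replace = TRUE)
  n_prom_cpgs <- sum(n_per_prom)
  n_diff <- round(cfg$frac_diff * cfg$n_cpgs)
  n_ighv <- round(cfg$frac_ighv * cfg$n_cpgs)
  if (n_prom_cpgs + n_diff + n_ighv > cfg$n_cpgs) {
    abort("config plants more CpGs than n_cpgs.")
  }
  idx_prom <- seq_len(n_prom_cpgs)
  idx_diff <- n_prom_cpgs + seq_len(n_diff)
  idx_ighv <- n_prom_cpgs + n_diff + seq_len(n_ighv)

  # promoter genes: the last n_promoters genes of the grid
  prom_gene_idx <- cfg$n_genes - cfg$n_promoters + seq_len(cfg$n_promoters)
  prom_of_cpg <- rep(seq_len(cfg$n_promoters), n_per_prom)

  # per-stratum mean M value for every CpG
  strata <- c("CLL_U", "CLL_M", "DLBCL", "RS_cll", "RS_dlbcl")
  mu <- matrix(0, cfg$n_cpgs, length(strata), dimnames = list(cpg_ids, strata))

  comp <- rbinom(cfg$n_cpgs, 1, 0.5)
  m0 <- rnorm(cfg$n_cpgs, ifelse(comp == 1, 3, -3), 1)
  m0[idx_prom] <- runif(n_prom_cpgs, -1.5, 1.5)  # mid-range, rankable both ways
  mu[] <- m0

  # CLL vs DLBCL differential CpGs: exact beta-differential before noise
  d <- cfg$delta_beta_effect
  lo <- runif(n_diff, 0.05, 0.95 - d)
  cll_high <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
  beta_cll <- ifelse(cll_high, lo + d, lo)
  beta_dlbcl <- ifelse(cll_high, lo, lo + d)
  mu[idx_diff, c("CLL_U", "CLL_M", "RS_cll")] <- .logit2(beta_cll)
  mu[idx_diff, c("DLBCL", "RS_dlbcl")] <- .logit2(beta_dlbcl)

  # IGHV CpGs: U-labelled samples shifted; RS subgroups follow their origin
  di <- cfg$ighv_delta_beta
  lo_i <- runif(n_ighv, 0.05, 0.95 - di)
  u_high <- sample(c(TRUE, FALSE), n_ighv, replace = TRUE)
  beta_u <- ifelse(u_high, lo_i + di, lo_i)
  beta_m <- ifelse(u_high, lo_i, lo_i + di)
  mu[idx_ighv, c("CLL_U", "RS_cll")] <- .logit2(beta_u)
  mu[idx_ighv, c("CLL_M", "DLBCL", "RS_dlbcl")] <- .logit2(beta_m)

  # expand to samples, add the RS global hypomethylation shift and noise
  M <- mu[, samples$stratum, drop = FALSE]
  colnames(M) <- samples$sample_id
  M[, samples$group == "RS"] <- M[, samples$group == "RS"] + cfg$rs_shift

  # promoter latent factors
  z <- matrix(rnorm(cfg$n_promoters * ns), cfg$n_promoters, ns,
              dimnames = list(NULL, samples$sample_id))
  M[idx_prom, ] <- M[idx_prom, ] + cfg$promoter_tau * z[prom_of_cpg, ] +
    rnorm(n_prom_cpgs * ns, 0, cfg$promoter_cpg_noise_sd)
  M[-idx_prom, ] <- M[-idx_prom, ] +
    rnorm((cfg$n_cpgs - n_prom_cpgs) * ns, 0, cfg$noise_sd)

  # simulated cell-composition covariate, optionally leaking into the data
  bfrac <- rbeta(ns, 8, 2)
  if (cfg$covariate_leak != 0) {
    leak_rows <- sample(cfg$n_cpgs, round(0.2 * cfg$n_cpgs))
    M[leak_rows, ] <- M[leak_rows, ] +
      cfg$covariate_leak * rep(bfrac - mean(bfrac), each = length(leak_rows))
  }

  beta <- beta_matrix(.expit2(M))
  sheet <- sample_sheet(dplyr::mutate(samples, bcell_fraction = bfrac))

  # annotations: promoter CpGs land in promoter classes of their gene,
  # others are placed away from any TSS
  prom_genes <- gene_coords[prom_gene_idx, ]
  ann_prom <- tibble::tibble(
    cpg_id = cpg_ids[idx_prom],
    chrom = prom_genes$chrom[prom_of_cpg],
    pos = prom_genes$tss[prom_of_cpg] + sample(-1500:1500, n_prom_cpgs, replace = TRUE),
    gene_id = prom_genes$gene_id[prom_of_cpg],
    feature_class = sample(c("TSS200", "TSS1500", "FirstExon"), n_prom_cpgs,
                           replace = TRUE, prob = c(0.4, 0.4, 0.2))
  )
  n_other <- cfg$n_cpgs - n_prom_cpgs
  other_gene <- sample(cfg$n_genes, n_other, replace = TRUE)
  in_body <- runif(n_other) < 0.3
  ann_other <- tibble::tibble(
    cpg_id = cpg_ids[-idx_prom],
    chrom = gene_coords$chrom[other_gene],
    pos = gene_coords$tss[other_gene] + sample(10000:40000, n_other, replace = TRUE),
    gene_id = ifelse(in_body, gene_coords$gene_id[other_gene], NA_character_),
    feature_class = ifelse(in_body, "Body", "Intergenic")
  )
  cpg_ann <- cpg_annotation(dplyr::bind_rows(ann_prom, ann_other))

  achieved <- if (n_diff == 0) NA_real_ else mean(abs(
    rowMeans(.strip(beta)[idx_diff, samples$group == "CLL", drop = FALSE]) -
      rowMeans(.strip(beta)[idx_diff, samples$group == "DLBCL", drop = FALSE])
  ))
  if (!is.na(achieved) && abs(achieved - d) > 0.1) {
    warn(sprintf("achieved mean |delta beta| %.3f differs from target %.3f (baseline saturation)",
                 achieved, d))
  }

  truth <- list(
    diff_cpgs = tibble::tibble(cpg_id = cpg_ids[idx_diff],
                               beta_cll = beta_cll, beta_dlbcl = beta_dlbcl,
                               delta_beta = beta_cll - beta_dlbcl),
    ighv_cpgs = tibble::tibble(cpg_id = cpg_ids[idx_ighv],
                               delta_beta = beta_u - beta_m),
    rs_labels = tibble::tibble(
      sample_id = samples$sample_id[samples$group == "RS"],
      true_subgroup = ifelse(
        samples$stratum[samples$group == "RS"] == "RS_cll",
        "CLL_derived", "DLBCL_like")),
    promoters = tibble::tibble(
      promoter_id = sprintf("P%03d", seq_len(cfg$n_promoters)),
      gene_id = prom_genes$gene_id,
      target_id = prom_genes$transcript_id,
      n_cpgs = n_per_prom,
      cpg_ids = split(cpg_ids[idx_prom], prom_of_cpg),
      target_rho = cfg$target_rho),
    z = z,
    gene_coords = gene_coords,
    achieved_delta_beta = achieved
  )
  list(beta = beta, sheet = sheet, cpg_ann = cpg_ann, truth = truth)
}

#' Simulate an expression cohort coupled to a methylation simulation
#'
#' Negative-binomial counts per gene and sample. The expected count is a
#' log-normal baseline abundance modulated by (i) a signature effect —
#' planted up/down genes shifted in CLL and CLL-derived RS samples relative
#' to the DLBCL side — and (ii) a promoter-coupling term proportional to the
#' promoter latent factor from [simulate_methylation()], with the
#' coefficient calibrated analytically so the realized methylation-expression
#' Spearman correlation approximates `target_rho`. Column sums are
#' calibrated to log-normal library sizes around `mean_library_size`.
#'
#' @param cfg The same [simulation_config()] used for methylation.
#' @param sheet Sample sheet from [simulate_methylation()].
#' @param truth Truth record from [simulate_methylation()]; returned updated
#'   with the planted signature genes.
#' @return List: `counts` ([count_matrix()]), `gene_ann`
#'   ([gene_annotation()]), `truth` (updated).
#' @export
simulate_expression <- function(cfg, sheet, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ns <- nrow(sheet)
  gene_ids <- truth$gene_coords$gene_id
  n_genes <- length(gene_ids)

  n_sig <- round(cfg$frac_signature * n_genes)
  n_up <- ceiling(n_sig / 2)
  idx_sig <- seq_len(n_sig)                      # first genes: signature
  prom_ids <- truth$promoters$gene_id            # last genes: promoters
  if (any(gene_ids[idx_sig] %in% prom_ids)) {
    abort("config overlap: signature and promoter genes collide; reduce fractions.")
  }
  direction <- rep(c("up", "down"), c(n_up, n_sig - n_up))

  log_w <- rnorm(n_genes, 0, 1.2)                # baseline abundance (ln scale)
  eff <- matrix(0, n_genes, ns)
  cll_side <- sheet$group == "CLL" |
    (sheet$group == "RS" & sheet$stratum == "RS_cll")
  eff[idx_sig, cll_side] <- log(2) * cfg$expression_effect_sd *
    ifelse(direction == "up", 1, -1)

  # promoter coupling: a = sigma_noise * r / sqrt(1 - r^2), where r is the
  # gene-side latent correlation needed so that, after attenuation by the
  # CpG-side loading and the rank transform, Spearman lands near target_rho.
  # A first pass with the analytic coefficient measures the realized
  # latent-expression correlation; the implied effective noise then refits
  # the coefficient and the counts are regenerated from the same RNG state,
  # correcting noise terms the closed form cannot see (rank transform,
  # log compression at low counts).
  mu_count <- exp(log_w + log(cfg$mean_library_size) - log(sum(exp(log_w))))
  prom_rows <- match(prom_ids, gene_ids)
  r_cpg <- cfg$promoter_tau /
    sqrt(cfg$promoter_tau^2 + cfg$promoter_cpg_noise_sd^2)
  sigma_n <- sqrt(cfg$nb_dispersion + 1 / pmax(mu_count[prom_rows], 1))
  r_tgt <- pmin(abs(cfg$target_rho) / (r_cpg * 0.96), 0.98)
  a1 <- sigma_n * r_tgt / sqrt(1 - r_tgt^2)

  lib <- rlnorm(ns, log(cfg$mean_library_size), 0.1)
  gen_counts <- function(a_mag) {
    e2 <- eff
    e2[prom_rows, ] <- e2[prom_rows, ] + sign(cfg$target_rho) * a_mag * truth$z
    abund <- exp(log_w + e2)                     # genes x samples
    mu <- sweep(abund, 2, lib / colSums(abund), "*")
    matrix(rnbinom(n_genes * ns, mu = mu, size = 1 / cfg$nb_dispersion),
           n_genes, ns, dimnames = list(gene_ids, sheet$sample_id))
  }

  set.seed(cfg$seed + 2L)
  n_pilot <- 1000L
  z_pilot <- rnorm(n_pilot)
  r1 <- vapply(seq_along(prom_rows), function(i) {
    mu_p <- mu_count[prom_rows[i]] * exp(a1[i] * z_pilot - a1[i]^2 / 2)
    y <- log2(rnbinom(n_pilot, mu = mu_p, size = 1 / cfg$nb_dispersion) + 0.5)
    abs(cor(rank(z_pilot), rank(y)))
  }, numeric(1))
  r1 <- pmin(pmax(r1, 0.05), 0.995)
  sigma_eff <- a1 * sqrt(1 - r1^2) / r1
  a2 <- sigma_eff * r_tgt / sqrt(1 - r_tgt^2)
  set.seed(cfg$seed + 3L)
  counts <- gen_counts(a2)

  biotype <- ifelse(runif(n_genes) < 0.8, "protein_coding", "lncRNA")
  biotype[c(idx_sig, prom_rows)] <- "protein_coding"
  gene_ann <- gene_annotation(dplyr::mutate(truth$gene_coords, biotype = biotype))

  truth$signature_genes <- tibble::tibble(gene_id = gene_ids[idx_sig],
                                          direction = direction)
  list(counts = count_matrix(counts), gene_ann = gene_ann, truth = truth)
}

#' Simulate a full multi-omics cohort
#'
#' Runs [simulate_methylation()] then [simulate_expression()] and bundles
#' the pieces.
#'
#' @param cfg A [simulation_config()].
#' @return List: `beta`, `counts`, `sheet`, `cpg_ann`, `gene_ann`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  meth <- simulate_methylation(cfg)
  expr <- simulate_expression(cfg, meth$sheet, meth$truth)
  list(beta = meth$beta, counts = expr$counts, sheet = meth$sheet,
       cpg_ann = meth$cpg_ann, gene_ann = expr$gene_ann,
       truth = expr$truth, config = cfg)
}

#' Named gold cohorts for testing and examples
#'
#' Deterministic preset bundles: `"small"` (2,000 CpGs, 500 genes, 60
#' samples) for fast unit tests, `"medium"` (20,000 CpGs, 5,000 genes, 200
#' samples) for end-to-end runs.
#'
#' @param preset `"small"` or `"medium"`.
#' @param seed Integer seed (default 1).
#' @return A cohort bundle as from [simulate_cohort()].
#' @export
make_gold_cohort <- function(preset = c("small", "medium"), seed = 1) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    small = simulation_config(seed = seed, n_cll_u = 10, n_cll_m = 10,
                              n_dlbcl = 20, n_rs_cll = 15, n_rs_dlbcl = 5,
                              n_cpgs = 2000, n_genes = 500,
                              n_promoters = 20, n_chroms = 5),
    medium = simulation_config(seed = seed, n_cll_u = 40, n_cll_m = 40,
                               n_dlbcl = 60, n_rs_cll = 45, n_rs_dlbcl = 15,
                               n_cpgs = 20000, n_genes = 5000,
                               n_promoters = 50)
  )
  simulate_cohort(cfg)
}

#' Write a cohort bundle to a directory
#'
#' TSV matrices and annotations, BED CpG positions, and a JSON manifest
#' with md5 checksums of every artifact.
#'
#' @param cohort A bundle from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The manifest as a list, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = write_matrix(cohort$beta, file.path(dir, "beta.tsv")),
    counts = write_matrix(cohort$counts, file.path(dir, "counts.tsv")),
    sheet = {
      readr::write_tsv(cohort$sheet, file.path(dir, "samples.tsv"), progress = FALSE)
      file.path(dir, "samples.tsv")
    },
    cpg_ann = {
      readr::write_tsv(cohort$cpg_ann, file.path(dir, "cpg_annotation.tsv"),
                       progress = FALSE)
      file.path(dir, "cpg_annotation.tsv")
    },
    cpg_bed = write_cpg_bed(
      dplyr::distinct(cohort$cpg_ann[, c("cpg_id", "chrom", "pos")]),
      file.path(dir, "cpg_positions.bed")),
    gene_ann = {
      readr::write_tsv(cohort$gene_ann, file.path(dir, "gene_annotation.tsv"),
                       progress = FALSE)
      file.path(dir, "gene_annotation.tsv")
    }
  )
  manifest <- list(
    seed = cohort$config$seed,
    n_samples = nrow(cohort$sheet),
    n_cpgs = nrow(cohort$beta),
    n_genes = nrow(cohort$counts),
    files = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate an expression cohort for classifier-score benchmarking
#'
#' Gene-level standard-normal expression for a cohort in which a fraction of
#' samples carries the signature imprint: their values are shifted by
#' `effect` standard deviations concordantly with the signature weights.
#' Used to measure how well the linear classifier score ranks planted
#' positives.
#'
#' @param signature A `gene_signature` tibble.
#' @param n_samples Cohort size.
#' @param frac_positive Fraction of samples carrying the imprint.
#' @param effect Shift size in sd units (default 1).
#' @param seed Integer seed.
#' @return List: `expr` ([expr_matrix()]), `positive` (sample ids with the
#'   imprint).
#' @export
simulate_lcs_cohort <- function(signature, n_samples = 100,
                                frac_positive = 0.08, effect = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  g <- matrix(rnorm(nrow(signature) * n_samples), nrow(signature), n_samples,
              dimnames = list(signature$gene_id, ids))
  n_pos <- max(1, round(frac_positive * n_samples))
  pos <- sample(ids, n_pos)
  g[, pos] <- g[, pos] + effect * signature$weight
  list(expr = expr_matrix(g), positive = pos)
}
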