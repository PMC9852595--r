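test_that("LPS is the weighted sum of beta-values over scoring CpGs", {
  w <- tibble::tibble(cpg_id = c("cg1", "cg2"), weight = c(2, -1))
  b <- tiny_beta(c(0.5, 0.5), cpgs = c("cg1", "cg2"), samples = "s1")
  expect_equal(compute_lps(b, w)$lps, 0.5)

  w0 <- tibble::tibble(cpg_id = c("cg1", "cg2"), weight = c(0, 0))
  expect_equal(compute_lps(b, w0)$lps, 0)

  set.seed(14)
  bb <- tiny_beta(runif(300), cpgs = paste0("cg", 1:100), samples = paste0("s", 1:3))
  ww <- tibble::tibble(cpg_id = paste0("cg", 1:100), weight = rnorm(100))
  got <- compute_lps(bb, ww)$lps
  manual <- apply(unclass(bb), 2, function(col) sum(ww$weight * col))
  expect_equal(got, unname(manual), tolerance = 1e-12)

  expect_error(compute_lps(b, tibble::tibble(cpg_id = "cgX", weight = 1)),
               "cgX")
})

test_that("LPS is linear in the beta vector", {
  set.seed(15)
  w <- tibble::tibble(cpg_id = paste0("cg", 1:20), weight = rnorm(20))
  s1 <- runif(20); s2 <- runif(20); alpha <- 0.3
  lps_of <- function(v) compute_lps(
    tiny_beta(v, cpgs = paste0("cg", 1:20), samples = "x"), w)$lps
  expect_equal(lps_of(alpha * s1 + (1 - alpha) * s2),
               alpha * lps_of(s1) + (1 - alpha) * lps_of(s2),
               tolerance = 1e-12)
})

test_that("reference distributions are the group mean and unbiased variance", {
  sheet <- sample_sheet(tibble::tibble(
    sample_id = paste0("s", 1:6), group = rep(c("CLL", "DLBCL"), each = 3)))
  lps <- tibble::tibble(sample_id = paste0("s", 1:6), lps = c(1, 2, 3, 7, 8, 9))
  fit <- fit_group_distributions(lps, sheet)
  expect_equal(fit$mu_cll, 2)
  expect_equal(fit$var_cll, 1)

  lps$lps[4:6] <- 5
  expect_error(fit_group_distributions(lps, sheet), "zero LPS variance")

  sheet2 <- sample_sheet(tibble::tibble(
    sample_id = paste0("s", 1:4), group = c("CLL", "CLL", "DLBCL", "DLBCL")))
  expect_error(
    fit_group_distributions(lps[1:4, ], sheet2), ">= 3")

  set.seed(99)
  n <- 200
  big <- sample_sheet(tibble::tibble(sample_id = paste0("s", 1:(2 * n)),
                                     group = rep(c("CLL", "DLBCL"), each = n)))
  scores <- tibble::tibble(sample_id = big$sample_id,
                           lps = c(rnorm(n, 5, 2), rnorm(n, 0, 1)))
  fit <- fit_group_distributions(scores, big)
  expect_lt(abs(fit$mu_cll - 5), 0.3)
  expect_lt(abs(fit$var_cll - 4) / 4, 0.2)
})

test_that("posteriors follow the two-Gaussian density ratio", {
  sym <- list(mu_cll = 0, var_cll = 1, mu_dlbcl = 4, var_dlbcl = 1)
  expect_equal(lps_posterior(2, sym)$p_cll, 0.5)

  sep <- list(mu_cll = 0, var_cll = 1, mu_dlbcl = 20, var_dlbcl = 1)
  expect_gt(lps_posterior(0, sep)$p_cll, 1 - 1e-12)

  # direct normal-pdf oracle
  mod <- list(mu_cll = 0, var_cll = 1, mu_dlbcl = 4, var_dlbcl = 4)
  want <- dnorm(2, 0, 1) / (dnorm(2, 0, 1) + dnorm(2, 4, 2))
  expect_equal(lps_posterior(2, mod)$p_cll, want, tolerance = 1e-12)
  expect_equal(want, 0.3086, tolerance = 1e-3)

  # complement holds exactly, even at extreme separation
  post <- lps_posterior(c(-50, 0, 2, 50), mod)
  expect_identical(post$p_cll + post$p_dlbcl, rep(1, 4))
})

test_that("labels respect the inclusive 0.98 posterior threshold", {
  expect_equal(lps_classify(0.99, 0.01), "CLL_derived")
  expect_equal(lps_classify(0.5, 0.5), "intermediate")
  expect_equal(lps_classify(0.02, 0.98), "DLBCL_like")  # boundary inclusive
  expect_equal(lps_classify(0.979, 0.021), "intermediate")
  expect_error(lps_classify(0.9, 0.1, threshold = 0.4), "threshold")
})

test_that("selection cascade keeps planted CLL/DLBCL CpGs and rejects IGHV CpGs", {
  set.seed(77)
  n1 <- 40; n2 <- 40
  sheet <- sample_sheet(tibble::tibble(
    sample_id = sprintf("S%03d", 1:(n1 + n2)),
    group = rep(c("CLL", "DLBCL"), c(n1, n2)),
    ighv_status = c(rep(c("U", "M"), each = n1 / 2), rep("M", n2))
  ))
  n_cpg <- 1000
  mu <- matrix(0, n_cpg, n1 + n2)
  planted <- 1:50          # CLL vs DLBCL, delta beta 0.4 (0.7 vs 0.3)
  ighv <- 51:80            # U vs M within CLL
  mu[planted, 1:n1] <- log2(0.7 / 0.3)
  mu[planted, (n1 + 1):(n1 + n2)] <- log2(0.3 / 0.7)
  mu[ighv, sheet$ighv_status == "U"] <- log2(0.8 / 0.2)
  mu[ighv, sheet$ighv_status == "M"] <- log2(0.4 / 0.6)
  M <- mu + rnorm(length(mu), 0, 0.4)
  dimnames(M) <- list(sprintf("cg%04d", 1:n_cpg), sheet$sample_id)
  b <- m_to_beta(m_matrix(M))
  m <- beta_to_m(b)

  sel <- select_scoring_cpgs(m, b, sheet)
  planted_ids <- sprintf("cg%04d", planted)
  ighv_ids <- sprintf("cg%04d", ighv)
  expect_true(all(planted_ids %in% sel$cpg_id))
  expect_false(any(ighv_ids %in% sel$cpg_id))

  # delta_cut = 0 disables the effect-size filter (more CpGs survive)
  sel0 <- select_scoring_cpgs(m, b, sheet, delta_cut = 0)
  expect_true(nrow(sel0) >= nrow(sel))

  # all-null data: nothing passes, informative error
  set.seed(78)
  Mn <- matrix(rnorm(200 * (n1 + n2)), 200,
               dimnames = list(sprintf("n%03d", 1:200), sheet$sample_id))
  expect_error(
    select_scoring_cpgs(m_matrix(Mn), m_to_beta(m_matrix(Mn)), sheet),
    "relaxing")
})

test_that("posteriors are invariant to a positive rescaling of the weights", {
  cohort <- make_gold_cohort("small", seed = 3)
  suppressMessages({
    model <- lps_train(cohort$beta, beta_to_m(cohort$beta), cohort$sheet)
  })
  scaled <- model
  scaled$weights <- model$weights * 3.7
  ref <- cohort$sheet[cohort$sheet$group %in% c("CLL", "DLBCL"), ]
  suppressMessages({
    lps_s <- compute_lps(align_samples(cohort$beta, sample_sheet(ref)), scaled)
  })
  pars <- fit_group_distributions(lps_s, ref)
  scaled[names(pars)] <- pars
  suppressMessages({
    p1 <- lps_score(cohort$beta, model)
    p2 <- lps_score(cohort$beta, scaled)
  })
  expect_equal(p2$p_cll, p1$p_cll, tolerance = 1e-8)
  expect_identical(p2$label, p1$label)
})

test_that("training and scoring recovers planted RS subgroups", {
  cfg <- simulation_config(seed = 424, n_cll_u = 40, n_cll_m = 40,
                           n_dlbcl = 60, n_rs_cll = 30, n_rs_dlbcl = 10,
                           n_cpgs = 4000, delta_beta_effect = 0.35,
                           n_genes = 400, n_promoters = 10)
  cohort <- suppressMessages(simulate_methylation(cfg))
  suppressMessages({
    model <- lps_train(cohort$beta, beta_to_m(cohort$beta), cohort$sheet)
    res <- lps_score(cohort$beta, model, cohort$sheet)
  })
  rs <- res[res$group == "RS", ]
  truth <- cohort$truth$rs_labels
  lab <- rs$label[match(truth$sample_id, rs$sample_id)]
  expect_gte(sum(lab == "CLL_derived" & truth$true_subgroup == "CLL_derived"), 27)
  expect_gte(sum(lab == "DLBCL_like" & truth$true_subgroup == "DLBCL_like"), 8)
  # no cross-labeling
  expect_equal(sum(lab == "DLBCL_like" & truth$true_subgroup == "CLL_derived"), 0)
  expect_equal(sum(lab == "CLL_derived" & truth$true_subgroup == "DLBCL_like"), 0)

  # a sample at the CLL centroid is CLL-derived
  ref <- cohort$sheet[cohort$sheet$group == "CLL", ]
  centroid <- rowMeans(unclass(cohort$beta)[, ref$sample_id])
  bc <- beta_matrix(matrix(centroid, ncol = 1,
                           dimnames = list(names(centroid), "centroid")))
  expect_equal(lps_score(bc, model)$label, "CLL_derived")
})

test_that("serialized models reload and score identically", {
  cohort <- make_gold_cohort("small", seed = 5)
  suppressMessages({
    model <- lps_train(cohort$beta, beta_to_m(cohort$beta), cohort$sheet)
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_lps_model(model, path)
  model2 <- read_lps_model(path)
  suppressMessages({
    r1 <- lps_score(cohort$beta, model)
    r2 <- lps_score(cohort$beta, model2)
  })
  expect_equal(r2$lps, r1$lps)
  expect_identical(r2$label, r1$label)
})

test_that("tidy and glance summarize an LPS model", {
  cohort <- make_gold_cohort("small", seed = 5)
  suppressMessages({
    model <- lps_train(cohort$beta, beta_to_m(cohort$beta), cohort$sheet)
  })
  td <- tidy(model)
  expect_named(td, c("cpg_id", "weight"))
  expect_equal(nrow(td), length(model$scoring_cpgs))
  gl <- glance(model)
  expect_equal(gl$n_cpgs, nrow(td))
  expect_equal(gl$threshold, 0.98)
})
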