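small_annotations <- function() {
  cpgs <- cpg_annotation(tibble::tibble(
    cpg_id = paste0("cg", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
    pos = c(8000, 10000 - 2000, 10000 - 2001, 10000 + 2000, 10000, 50000),
    gene_id = c("gA", NA, NA, NA, NA, "gB"),
    feature_class = c("TSS200", "Intergenic", "Intergenic", "Intergenic",
                      "Intergenic", "Body")
  ))
  genes <- gene_annotation(tibble::tibble(
    gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"),
    chrom = c("chr1", "chr1"), tss = c(10000, 52000), strand = c("+", "-"),
    biotype = "protein_coding"
  ))
  list(cpgs = cpgs, genes = genes)
}

test_that("integrome links by id and by an inclusive 2 kb TSS window", {
  ann <- small_annotations()
  integ <- build_integrome(ann$cpgs, ann$genes, window = 2000)

  # cg2 at exactly tss - 2000 pairs; cg3 at tss - 2001 does not
  expect_true(any(integ$cpg_id == "cg2" & integ$target_id == "tA"))
  expect_false(any(integ$cpg_id == "cg3"))
  expect_true(any(integ$cpg_id == "cg4" & integ$target_id == "tA"))
  # cg5 is on another chromosome: never paired
  expect_false(any(integ$cpg_id == "cg5"))
  # cg1 is both id-linked and within the window: id link takes precedence
  cg1 <- integ[integ$cpg_id == "cg1" & integ$target_id == "tA", ]
  expect_equal(nrow(cg1), 1)
  expect_equal(cg1$link_method, "shared_id")
  expect_equal(cg1$feature_class, "TSS200")
  # cg6 links to gB by id only (48 kb from its TSS)
  expect_equal(integ$link_method[integ$cpg_id == "cg6"], "shared_id")

  # brute-force all-pairs distance check
  set.seed(71)
  cp <- cpg_annotation(tibble::tibble(
    cpg_id = paste0("c", 1:20), chrom = "chr3",
    pos = sample(1000:30000, 20), gene_id = NA_character_,
    feature_class = "Intergenic"))
  gn <- gene_annotation(tibble::tibble(
    gene_id = paste0("g", 1:5), transcript_id = paste0("t", 1:5),
    chrom = "chr3", tss = sample(1000:30000, 5), strand = "+",
    biotype = "protein_coding"))
  got <- build_integrome(cp, gn, window = 2000)
  want <- 0L
  for (i in 1:20) for (j in 1:5) {
    if (abs(cp$pos[i] - gn$tss[j]) <= 2000) {
      want <- want + 1L
      expect_true(any(got$cpg_id == cp$cpg_id[i] &
                        got$target_id == gn$transcript_id[j]))
    }
  }
  expect_equal(nrow(got), want)

  bad_genes <- gn; bad_genes$chrom <- "chrZ"
  expect_error(build_integrome(cp, gene_annotation(bad_genes)), "chrZ")
})

test_that("spearman rho matches the mid-rank oracle, including ties", {
  x <- 1:8 / 10
  expect_equal(spearman_assoc(x, 2 * (1:8))$rho, 1)
  expect_equal(spearman_assoc(x, -(1:8))$rho, -1)

  set.seed(81)
  xt <- sample(c(0.1, 0.2, 0.2, 0.3, 0.5, 0.5, 0.5, 0.8, 0.9, 0.9, 0.4, 0.6))
  yt <- rnorm(12) + xt
  got <- spearman_assoc(xt, yt)
  expect_equal(got$rho, oracle_spearman(xt, yt), tolerance = 1e-12)
  # t-approximation for n >= 10
  tt <- got$rho * sqrt((12 - 2) / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(abs(tt), 10, lower.tail = FALSE), tolerance = 1e-12)

  # exact permutation p for small n: full enumeration oracle
  set.seed(82)
  xs <- runif(6); ys <- runif(6)
  got_s <- spearman_assoc(xs, ys)
  perms <- oracle_perms(6)
  null_rho <- apply(perms, 1, function(ix) oracle_spearman(xs, ys[ix]))
  p_exact <- mean(abs(null_rho) >= abs(got_s$rho) - 1e-12)
  expect_equal(got_s$p, p_exact, tolerance = 1e-12)

  expect_error(spearman_assoc(runif(3), runif(3)), ">= 5")
})

test_that("vectorized correlations agree with the per-pair operator", {
  set.seed(83)
  ns <- 12
  b <- beta_matrix(matrix(runif(5 * ns), 5,
                          dimnames = list(paste0("cg", 1:5), paste0("s", 1:ns))))
  e <- expr_matrix(matrix(rnorm(3 * ns), 3,
                          dimnames = list(paste0("t", 1:3), paste0("s", 1:ns))))
  integ <- tibble::tibble(cpg_id = rep(paste0("cg", 1:5), each = 3),
                          target_id = rep(paste0("t", 1:3), 5),
                          gene_id = rep(paste0("g", 1:3), 5),
                          link_method = "shared_id", feature_class = "TSS200")
  got <- compute_correlations(integ, b, e)
  for (i in seq_len(nrow(got))) {
    sp <- spearman_assoc(unclass(b)[got$cpg_id[i], ],
                         unclass(e)[got$target_id[i], ])
    expect_equal(got$rho[i], sp$rho, tolerance = 1e-12)
    expect_equal(got$p[i], sp$p, tolerance = 1e-12)
  }
})

test_that("significance filtering applies both the rho and p cuts", {
  assocs <- tibble::tibble(
    cpg_id = paste0("c", 1:4), target_id = paste0("t", 1:4),
    gene_id = paste0("g", 1:4), link_method = "shared_id",
    feature_class = "TSS200",
    rho = c(0.34, 0.5, -0.2, -0.6), p = c(0.005, 0.02, 0.001, 0.002))
  out <- filter_significant(assocs)
  expect_setequal(out$cpg_id, c("c1", "c4"))

  set.seed(84)
  rnd <- tibble::tibble(cpg_id = paste0("c", 1:50), target_id = "t",
                        gene_id = "g", link_method = "shared_id",
                        feature_class = "Body",
                        rho = runif(50, -1, 1), p = runif(50))
  got <- filter_significant(rnd, p_cut = 0.3, rho_cut = 0.4)
  expect_identical(got$cpg_id,
                   rnd$cpg_id[abs(rnd$rho) > 0.4 & rnd$p < 0.3])
})

test_that("candidate regions need 3 same-direction promoter CpGs", {
  base <- tibble::tibble(
    cpg_id = paste0("c", 1:3), target_id = "t1", gene_id = "g1",
    link_method = "shared_id", feature_class = "TSS200",
    rho = -0.5, p = 1e-4)
  out <- select_candidates(base)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "negative")
  expect_equal(out$n_cpgs, 3L)

  expect_equal(nrow(select_candidates(base[1:2, ])), 0)  # below min
  body <- base; body$feature_class <- "Body"
  expect_equal(nrow(select_candidates(body)), 0)         # class filter

  # nesting: stricter candidate thresholds select within the significant set
  set.seed(85)
  rnd <- tibble::tibble(
    cpg_id = paste0("c", 1:200),
    target_id = sample(paste0("t", 1:20), 200, replace = TRUE),
    gene_id = "g", link_method = "shared_id",
    feature_class = sample(c("TSS200", "Body"), 200, replace = TRUE),
    rho = runif(200, -1, 1), p = runif(200, 0, 0.02))
  cand <- select_candidates(rnd, p_cut = 0.001)
  signif <- filter_significant(rnd, p_cut = 0.01)
  for (i in seq_len(nrow(cand))) {
    expect_true(all(unlist(cand$cpg_ids[i]) %in%
                      signif$cpg_id[signif$target_id == cand$target_id[i]]))
  }

  # both directions can coexist for one target; union deduplicates
  two <- dplyr::bind_rows(base,
    dplyr::mutate(base, cpg_id = paste0("d", 1:3), rho = 0.6))
  cand2 <- select_candidates(two)
  expect_setequal(cand2$direction, c("negative", "positive"))
  expect_equal(candidate_genes(cand2)$union, "g1")
})

test_that("enrichment folds and tests match hand computation", {
  # CD5+ DLBCL among top-scoring samples: 17/22 vs 33/90 background
  expect_equal(enrichment_fold(17, 22, 33, 90), (17 / 22) / (33 / 90),
               tolerance = 1e-12)
  expect_equal(round(enrichment_fold(17, 22, 33, 90), 1), 2.1)
  expect_equal(enrichment_fold(10, 100, 20, 200), 1.0)
  set.seed(86)
  a <- sample(1:50, 4)
  expect_equal(enrichment_fold(a[1], a[1] + a[2], a[3], a[3] + a[4]),
               (a[1] / (a[1] + a[2])) / (a[3] / (a[3] + a[4])))
  expect_warning(f <- enrichment_fold(1, 10, 0, 100), "undefined")
  expect_identical(f, Inf)

  # Fisher: hypergeometric hand computation for the diagonal table
  expect_equal(enrichment_test(matrix(c(5, 0, 0, 5), 2), "fisher"),
               2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(enrichment_test(matrix(c(10, 10, 10, 10), 2), "fisher"), 1)

  # chi-square: brute-force Pearson statistic + CDF
  tb <- matrix(c(20, 10, 10, 20), 2)
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  stat <- sum((tb - expected)^2 / expected)
  expect_equal(enrichment_test(tb, "chi2"),
               pchisq(stat, df = 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(enrichment_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("planted negative promoters are recovered with few false targets", {
  cfg <- simulation_config(seed = 301, n_cpgs = 6000, n_genes = 1500,
                           n_promoters = 40)
  cohort <- suppressMessages(simulate_cohort(cfg))
  rs <- sample_sheet(cohort$sheet[cohort$sheet$group == "RS", ])
  prep <- suppressMessages(prepare_expression(cohort$counts))
  integ <- build_integrome(cohort$cpg_ann, cohort$gene_ann)
  ev <- unclass(suppressMessages(align_samples(prep$expr, rs)))
  rownames(ev) <- cohort$gene_ann$transcript_id[
    match(rownames(ev), cohort$gene_ann$gene_id)]
  assocs <- suppressMessages(compute_correlations(
    integ, suppressMessages(align_samples(cohort$beta, rs)), expr_matrix(ev)))
  cand <- select_candidates(assocs)
  neg <- cand$target_id[cand$direction == "negative"]
  planted <- cohort$truth$promoters$target_id
  expect_gte(mean(planted %in% neg), 0.7)           # single-seed bound
  false_rate <- length(setdiff(neg, planted)) / max(length(neg), 1)
  expect_lte(false_rate, 0.05)
})
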