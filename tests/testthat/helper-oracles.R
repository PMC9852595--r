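# Independent brute-force oracles used to cross-check the implementation.
# These are written from the definitions, not from the package code paths.

# ordinary least squares via the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} (m * p_(j) / j), capped at 1, in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Spearman rho on mid-ranks, from the covariance formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# step-by-step TMM: reference by upper quartile, M/A values, precision
# weights, double trim, weighted mean, geometric-mean renormalization
oracle_tmm <- function(x, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(x)
  f75 <- apply(x, 2, function(col) quantile(col, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(obs, refc, nO, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(x)), function(i)
    one(x[, i], x[, ref], lib[i], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

# O(n^3) agglomeration under a given linkage; returns the cophenetic matrix
oracle_hclust_cophenetic <- function(D, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, length(members))
  coph <- matrix(0, n, n)
  cd <- D
  diag(cd) <- Inf
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && cd[a, b] < best_d) { best_d <- cd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (i in members[[a]]) for (j in members[[b]]) {
      coph[i, j] <- coph[j, i] <- best_d
    }
    merged <- c(members[[a]], members[[b]])
    members <- c(members, list(merged))
    active <- c(active, TRUE)
    active[c(a, b)] <- FALSE
    cd <- rbind(cbind(cd, Inf), Inf)
    new <- length(members)
    for (k in which(active)) {
      if (k == new) next
      dk <- D[members[[new]], members[[k]], drop = FALSE]
      cd[new, k] <- cd[k, new] <- switch(linkage,
        complete = max(dk), average = mean(dk))
    }
  }
  coph
}

# all permutations of 1..n (test-local, independent of the package's)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- oracle_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# small labelled beta matrix fixture
tiny_beta <- function(vals, cpgs = NULL, samples = NULL) {
  m <- matrix(vals, nrow = if (is.null(cpgs)) 1 else length(cpgs))
  rownames(m) <- cpgs %||% paste0("cg", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  beta_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
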