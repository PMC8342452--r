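## Two-module latent factor design: loadings 0.8, noise sd 0.5.
two_module_tpm <- function(n_per = 60, n_samples = 29, seed = 1,
                           loading = 0.8, noise_sd = 0.5) {
  set.seed(seed)
  z1 <- rnorm(n_samples); z2 <- rnorm(n_samples)
  x <- rbind(
    t(vapply(seq_len(n_per), function(i)
      loading * z1 + rnorm(n_samples, 0, noise_sd), numeric(n_samples))),
    t(vapply(seq_len(n_per), function(i)
      loading * z2 + rnorm(n_samples, 0, noise_sd), numeric(n_samples))))
  rownames(x) <- sprintf("g%03d", seq_len(2 * n_per))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  2^(x + 5)   # back to a TPM-like positive scale; log2(tpm+1) ~ x + 5
}

test_that("network_config validates", {
  expect_error(network_config(soft_power = 40), "soft_power")
  expect_error(network_config(merge_cut_height = 0), "merge_cut_height")
  expect_equal(network_config(6)$soft_power, 6L)
})

test_that("soft power selection is the first power past the target", {
  ## heterogeneous loadings give the connectivity spread needed for a
  ## scale-free-looking fit
  set.seed(2)
  ns <- 29
  z1 <- rnorm(ns); z2 <- rnorm(ns)
  l <- runif(60, 0.3, 0.95)
  x <- rbind(t(sapply(1:60, function(i) l[i] * z1 + rnorm(ns, 0, 0.5))),
             t(sapply(1:60, function(i) l[i] * z2 + rnorm(ns, 0, 0.5))))
  rownames(x) <- sprintf("g%03d", 1:120)
  tpm <- 2^(x + 5)
  beta <- pick_soft_power(tpm)
  fits <- attr(beta, "fit")
  expect_gte(beta, 1); expect_lte(beta, 30)
  if (attr(beta, "reached_target")) {
    expect_gte(fits[beta], 0.9)
    expect_true(all(fits[seq_len(beta - 1)] < 0.9, na.rm = TRUE))
  } else {
    expect_equal(as.integer(beta), which.max(fits))
  }
  ## invariant to gene ordering
  beta2 <- pick_soft_power(tpm[sample(nrow(tpm)), ])
  expect_equal(as.integer(beta), as.integer(beta2))
  ## degenerate perfectly correlated set falls back
  flat <- matrix(rep(seq_len(20), each = 25), 25, 20, byrow = FALSE)
  rownames(flat) <- sprintf("f%d", 1:25)
  expect_error(pick_soft_power(flat[, 1:3]), "4 samples")
  perf <- outer(1:25, seq_len(20))
  rownames(perf) <- sprintf("p%d", 1:25)
  b3 <- pick_soft_power(perf)
  expect_false(attr(b3, "reached_target"))
})

test_that("constant genes are removed with a warning", {
  tpm <- two_module_tpm(n_per = 15, seed = 3)
  tpm[3, ] <- 7
  expect_warning(pick_soft_power(tpm), "constant")
})

test_that("TOM has the closed-form limits and stays in [0,1]", {
  ## zero off-diagonal adjacency: TOM off-diagonal 0
  a0 <- diag(5) * 0
  t0 <- tom_similarity(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))
  expect_true(all(diag(t0) == 1))
  ## random adjacency: symmetric, bounded
  set.seed(4)
  cc <- abs(cor(matrix(rnorm(200), 20, 10)))
  a <- cc^6; diag(a) <- 0
  tt <- tom_similarity(a)
  expect_equal(tt, t(tt))
  expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
})

test_that("planted two-module design is recovered at ARI >= 0.9", {
  tpm <- two_module_tpm(seed = 5)
  asg <- detect_modules(tpm, network_config(min_module_size = 30))
  truth <- rep(1:2, each = 60)
  keep <- asg$modules > 0
  expect_gte(mean(keep), 0.9)
  expect_gte(adjusted_rand_index(asg$modules[keep], truth[keep]), 0.9)
  ## eigengenes are unit norm
  expect_equal(unname(sqrt(rowSums(asg$eigengenes^2))),
               rep(1, nrow(asg$eigengenes)))
})

test_that("eigengene is the best single profile for its module", {
  tpm <- two_module_tpm(n_per = 40, seed = 6)
  asg <- detect_modules(tpm, network_config(min_module_size = 20))
  x <- allelome:::prepare_expr(tpm)
  for (mid in rownames(asg$eigengenes)) {
    xm <- t(scale(t(x[names(asg$modules)[asg$modules == as.integer(mid)], ])))
    ev <- as.numeric(xm %*% asg$eigengenes[mid, ])
    var_e <- sum(ev^2)
    set.seed(7)
    for (k in 1:5) {
      v <- rnorm(ncol(xm)); v <- v / sqrt(sum(v^2))
      expect_lte(sum((xm %*% v)^2), var_e + 1e-8)
    }
  }
})

test_that("fewer genes than min_module_size yields a single grey module", {
  tpm <- two_module_tpm(n_per = 10, seed = 8)
  asg <- detect_modules(tpm, network_config(min_module_size = 60))
  expect_true(all(asg$modules == 0))
})

test_that("divergence threshold follows the median-max rule", {
  ## three eigengenes with pairwise distances engineered: use 3 orthogonal
  ## unit vectors scaled -> pairwise distance sqrt(2) each; then scale
  me <- diag(3)
  rownames(me) <- 1:3
  asg <- structure(list(modules = c(gA = 1L, gB = 2L, gC = 3L, gD = 1L),
                        eigengenes = me), class = "module_assignment")
  pairs <- data.frame(locus_id = c("L1", "L2"),
                      geneA = c("gA", "gA"), geneB = c("gD", "gB"))
  calls <- classify_allele_divergence(pairs, asg)
  expect_equal(calls$class[1], "coordinated")
  expect_equal(calls$distance[1], 0)
  ## all pairwise distances sqrt(2): threshold = 0.5*sqrt(2); distance
  ## sqrt(2) > threshold -> divergent
  expect_equal(calls$threshold[2], 0.5 * sqrt(2))
  expect_equal(calls$class[2], "divergent")

  ## hand-computed example: per-module maxima {2, 3, 4} -> threshold 1.5;
  ## verify against a constructed geometry (collinear eigengenes)
  me2 <- matrix(c(0, 2, -2), 3, 1)   # distances: 1-2:2, 1-3:2, 2-3:4
  rownames(me2) <- 1:3
  d <- as.matrix(dist(me2)); diag(d) <- NA
  thr <- 0.5 * median(apply(d, 1, max, na.rm = TRUE))
  expect_equal(thr, 0.5 * median(c(2, 4, 4)))

  ## boundary: distance exactly the threshold is "similar" (strict >)
  asg3 <- structure(list(modules = c(g1 = 1L, g2 = 2L),
                         eigengenes = matrix(c(0, 1), 2, 1,
                                             dimnames = list(1:2, NULL))),
                    class = "module_assignment")
  p3 <- data.frame(locus_id = "L1", geneA = "g1", geneB = "g2")
  c3 <- classify_allele_divergence(p3, asg3)
  expect_equal(c3$distance, 1)
  expect_equal(c3$threshold, 0.5)
  expect_equal(c3$class, "divergent")
  c4 <- classify_allele_divergence(p3, asg3, threshold_fraction = 1)
  expect_equal(c4$class, "similar")   # distance == threshold

  ## unassigned allele withheld
  asg5 <- structure(list(modules = c(g1 = 1L, g2 = 0L),
                         eigengenes = me), class = "module_assignment")
  expect_equal(classify_allele_divergence(p3, asg5)$class, "withheld")
})

test_that("alleles sharing a latent factor are mostly not divergent", {
  set.seed(9)
  tpm <- two_module_tpm(seed = 9)
  n <- nrow(tpm) / 2
  pairs <- data.frame(locus_id = sprintf("L%d", 1:n),
                      geneA = rownames(tpm)[1:n],
                      geneB = rownames(tpm)[1:n])   # same gene: same factor
  ## pair gene i of module 1 with gene i+60 of ... use within-module pairs
  pairs$geneB <- rownames(tpm)[c(2:30, 1, 31:60, 91:120, 61:90)][1:n]
  asg <- detect_modules(tpm, network_config(min_module_size = 30))
  calls <- classify_allele_divergence(pairs, asg)
  frac <- mean(calls$class %in% c("coordinated", "similar"))
  expect_gte(frac, 0.95)
  ## class fractions partition
  expect_equal(sum(prop.table(table(calls$class))), 1)
})
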