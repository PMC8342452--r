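test_that("compute_tpm matches hand arithmetic and normalizes columns", {
  ## one gene: everything maps to 1e6
  expect_equal(as.numeric(compute_tpm(matrix(7, 1, 1), 500)), 1e6)
  ## two genes, equal counts, lengths 1000 and 2000
  tpm <- compute_tpm(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(as.numeric(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  ## random input: columns sum to 1e6
  set.seed(1)
  m <- matrix(rpois(60, 20), 10, 6)
  tpm2 <- compute_tpm(m, sample(500:2000, 10))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 6), tolerance = 1e-6)
  ## all-zero sample warns and stays zero
  m[, 3] <- 0
  expect_warning(tpm3 <- compute_tpm(m, rep(1000, 10)), "all-zero")
  expect_true(all(tpm3[, 3] == 0))
  expect_error(compute_tpm(m, rep(0, 10)), "> 0")
})

test_that("expressed filter uses a strict threshold", {
  tpm <- matrix(c(0.6, 0.1, 0.5, 0.2, 0, 0), 3, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), NULL))
  expect_identical(filter_expressed(tpm), "g1")   # 0.6 in, exactly 0.5 out
})

test_that("identical replicate vectors give log2fc 0 and p 1", {
  cc <- matrix(c(5, 9, 13, 7), 1, 4)
  res <- test_allelic_bias(cc, cc)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
  ## < 2 replicates: p undefined
  expect_true(is.na(test_allelic_bias(matrix(5), matrix(7))$p))
})

test_that("the NB Wald test is calibrated under the null", {
  set.seed(101)
  n <- 4000; reps <- 4
  cA <- matrix(rnbinom(n * reps, mu = 150, size = 20), n, reps)
  cB <- matrix(rnbinom(n * reps, mu = 150, size = 20), n, reps)
  res <- test_allelic_bias(cA, cB)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  ## BH keeps the planted-null family silent
  expect_lte(mean(p.adjust(res$p, "BH") < 0.05), 0.05)
})

test_that("planted fold changes are recovered", {
  set.seed(102)
  n <- 400; reps <- 4; fc <- 10
  cA <- matrix(rnbinom(n * reps, mu = 150 * sqrt(fc), size = 20), n, reps)
  cB <- matrix(rnbinom(n * reps, mu = 150 / sqrt(fc), size = 20), n, reps)
  res <- test_allelic_bias(cA, cB)
  expect_lt(abs(median(res$log2fc) - log2(fc)), 0.3)
})

test_that("swapping alleles negates log2fc and keeps p", {
  set.seed(103)
  cA <- matrix(rnbinom(40, mu = 100, size = 20), 10, 4)
  cB <- matrix(rnbinom(40, mu = 300, size = 20), 10, 4)
  r1 <- test_allelic_bias(cA, cB)
  r2 <- test_allelic_bias(cB, cA)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("classify_bias implements the four-level scheme", {
  expect_equal(classify_bias(0, 0.8), "none")
  expect_equal(classify_bias(log2(3), 0.01), "larger")
  expect_equal(classify_bias(log2(10), 0.001), "largest")
  expect_equal(classify_bias(log2(1.4), 0.01), "smaller")
  ## boundaries: FC = 2 -> smaller, FC = 8 -> largest
  expect_equal(classify_bias(1, 0.01), "smaller")
  expect_equal(classify_bias(3, 0.01), "largest")
  ## sign does not matter
  expect_equal(classify_bias(-log2(10), 0.001), "largest")
  ## adjusted p at exactly 0.05 is not significant
  expect_equal(classify_bias(3, 0.05), "none")
})

test_that("category recovery has >= 90% diagonal mass at band midpoints", {
  set.seed(104)
  n <- 4000; reps <- 4; disp <- 0.05
  mix <- c(none = 0.70, smaller = 0.10, larger = 0.12, largest = 0.08)
  fcs <- c(none = 1, smaller = 1.5, larger = 4, largest = 12)
  planted <- sample(names(mix), n, replace = TRUE, prob = mix)
  mus <- exp(rnorm(n, log(150), 1))
  fc <- fcs[planted]
  cA <- matrix(rnbinom(n * reps, mu = rep(mus * sqrt(fc), reps),
                       size = 1 / disp), n, reps)
  cB <- matrix(rnbinom(n * reps, mu = rep(mus / sqrt(fc), reps),
                       size = 1 / disp), n, reps)
  res <- test_allelic_bias(cA, cB)
  called <- classify_bias(res$log2fc, p.adjust(res$p, "BH"))
  expect_gte(mean(called == planted), 0.90)
})

make_calls <- function(loci, tissues, log2fc, p_adj) {
  df <- expand.grid(locus_id = loci, tissue = tissues,
                    stringsAsFactors = FALSE)
  df$log2fc <- log2fc
  df$p <- p_adj
  df$p_adj <- p_adj
  df$category <- classify_bias(df$log2fc, df$p_adj)
  df
}

test_that("dynamic/stable ranking takes exactly the top and bottom 10%", {
  set.seed(105)
  loci <- sprintf("L%03d", 1:100)
  calls <- make_calls(loci, c("t1", "t2"),
                      log2fc = c(seq(0, 9.9, 0.1), rep(0, 100)),
                      p_adj = 0.001)
  prof <- rank_dynamic_stable(calls)
  expect_equal(sum(prof$label == "dynamic"), 10)
  expect_equal(sum(prof$label == "stable"), 10)
  ## a never-significant locus has range 0 and lands in the stable pool
  expect_true(all(prof$fc_range >= 0))
  ## permuting row order leaves labels unchanged
  prof2 <- rank_dynamic_stable(calls[sample(nrow(calls)), ])
  expect_identical(prof[order(prof$locus_id), ],
                   prof2[order(prof2$locus_id), ], ignore_attr = TRUE)
  ## fewer than 10 loci: labels withheld
  expect_message(small <- rank_dynamic_stable(
    make_calls(sprintf("L%d", 1:5), "t1", 1, 0.001)), "withheld")
  expect_true(all(small$label == "neither"))
})

test_that("non-significant calls are masked to FC 0 in profiles", {
  calls <- make_calls("L1", c("t1", "t2"), log2fc = c(4, 4),
                      p_adj = c(0.001, 0.5))
  prof <- suppressMessages(rank_dynamic_stable(calls))
  expect_equal(prof$fc_range, 4)   # masked tissue contributes 0
})

test_that("transition summary distinguishes neighboring from jumping", {
  calls <- rbind(
    make_calls("L1", c("t1", "t2"), log2fc = c(log2(1.5), log2(4)),
               p_adj = 0.01),                         # smaller -> larger
    make_calls("L2", c("t1", "t2"), log2fc = c(log2(1.5), log2(20)),
               p_adj = 0.01),                         # smaller -> largest
    make_calls("L3", c("t1", "t2"), log2fc = log2(4), p_adj = 0.01),
    make_calls("L4", c("t1", "t2"), log2fc = c(log2(4), 0),
               p_adj = c(0.01, 0.9)))                 # larger, none
  ts <- transition_summary(calls)
  types <- setNames(ts$per_locus$transition_type, ts$per_locus$locus_id)
  expect_equal(unname(types[c("L1", "L2", "L3", "L4")]),
               c("neighboring", "jumping", "none", "none"))
  expect_equal(as.numeric(ts$counts), c(2, 1, 1))
})

test_that("per-tissue calls on the small world recover planted bias", {
  w <- small_world()
  truth <- w$truth
  calls <- ase_bias_calls(w$counts$counts, w$counts$sample_sheet,
                          truth$pairs[, c("locus_id", "geneA", "geneB")])
  ## categories partition tested loci; proportions sum to 1 per tissue
  prop <- prop.table(table(calls$tissue, calls$category), margin = 1)
  expect_equal(unname(rowSums(prop)), rep(1, nrow(prop)))
  ## sign-aware agreement: strongly biased planted loci are mostly called
  merged <- merge(calls,
                  data.frame(locus_id = truth$pairs$locus_id,
                             tissue = rep(colnames(truth$category_tissue),
                                          each = nrow(truth$pairs)),
                             planted = as.vector(truth$category_tissue)))
  big <- merged[merged$planted == "largest", ]
  expect_gte(mean(big$category == "largest"), 0.8)
  none <- merged[merged$planted == "none", ]
  expect_gte(mean(none$category == "none"), 0.9)
})
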