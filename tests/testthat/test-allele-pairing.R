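make_matches <- function(rankA, rankB, score = 1, chrom = c("c1A", "c1B"),
                         ids = seq_along(rankA)) {
  data.frame(geneA = sprintf("a%02d", ids), geneB = sprintf("b%02d", ids),
             score = rep(score, length.out = length(rankA)),
             chromA = rep(chrom[1], length(rankA)),
             chromB = rep(chrom[2], length(rankA)),
             rankA = rankA, rankB = rankB, stringsAsFactors = FALSE)
}

test_that("identical gene sets match themselves with similarity 1", {
  set.seed(1)
  cds <- setNames(vapply(1:8, function(i) allelome:::random_cds(60),
                         character(1)), sprintf("g%dA", 1:8))
  cdsB <- setNames(cds, sub("A$", "B", names(cds)))
  m <- build_match_table(cds, cdsB, top_k = 1)
  expect_equal(nrow(m), 8)
  expect_equal(sub("A$", "", m$geneA), sub("B$", "", m$geneB))
  expect_true(all(m$score == 1))
})

test_that("disjoint random sequences yield no or near-zero matches", {
  set.seed(2)
  cds <- setNames(vapply(1:6, function(i) allelome:::random_cds(60),
                         character(1)), sprintf("x%d", 1:6))
  cdsB <- setNames(vapply(1:6, function(i) allelome:::random_cds(60),
                          character(1)), sprintf("y%d", 1:6))
  m <- build_match_table(cds, cdsB, top_k = 1, min_similarity = 0)
  expect_true(nrow(m) == 0 || all(m$score < 0.05))
})

test_that("mutated counterparts rank first for nearly all genes", {
  set.seed(3)
  n <- 60
  cds <- setNames(vapply(seq_len(n), function(i) allelome:::random_cds(150),
                         character(1)), sprintf("g%03dA", seq_len(n)))
  cdsB <- setNames(vapply(cds, function(x) {
    chars <- strsplit(x, "")[[1]]
    k <- round(0.05 * length(chars))
    pos <- sample(seq(4, length(chars)), k)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(chars, collapse = "")
  }, character(1)), sub("A$", "B", names(cds)))
  m <- build_match_table(cds, cdsB, top_k = 1, min_similarity = 0)
  hit <- sub("A$", "", m$geneA[match(names(cds), m$geneA)]) ==
    sub("B$", "", m$geneB[match(names(cds), m$geneA)])
  expect_gte(mean(hit, na.rm = TRUE), 0.99)
})

test_that("untranslatable sequences are skipped with a warning", {
  cds <- c(ok = allelome:::random_cds(30), bad = "ATGCC")
  expect_warning(m <- build_match_table(cds, c(z = allelome:::random_cds(30))),
                 "not translatable")
})

test_that("chaining finds planted forward and reverse runs", {
  expect_identical(chain_collinear_blocks(
    make_matches(integer(0), integer(0))[0, ]), list())

  m <- make_matches(0:4, 10:14)
  bl <- chain_collinear_blocks(m, min_block_size = 5)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$orientation, "forward")
  expect_equal(nrow(bl[[1]]$anchors), 5)

  m2 <- make_matches(0:4, 14:10)
  bl2 <- chain_collinear_blocks(m2, min_block_size = 5)
  expect_length(bl2, 1)
  expect_equal(bl2[[1]]$orientation, "reverse")

  ## gaps above max_gap break a chain
  m3 <- make_matches(c(0:4, 40:44), c(0:4, 40:44))
  bl3 <- chain_collinear_blocks(m3, min_block_size = 5, max_gap = 25)
  expect_length(bl3, 2)
})

test_that("chaining equals the brute-force maximal-chain oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    m <- make_matches(sample(0:20, n), sample(0:20, n),
                      score = round(runif(n), 3))
    bl <- chain_collinear_blocks(m, min_block_size = 1, max_gap = 25)
    best_dp <- if (length(bl)) max(vapply(bl, `[[`, numeric(1), "score")) else 0
    expect_equal(best_dp, oracle_best_chain(m, max_gap = 25), tolerance = 1e-9)
  }
})

test_that("chaining output is invariant to input row order", {
  set.seed(9)
  m <- make_matches(sample(0:30, 12), sample(0:30, 12), score = runif(12))
  b1 <- blocks_to_df(chain_collinear_blocks(m, min_block_size = 2))
  b2 <- blocks_to_df(chain_collinear_blocks(m[sample(12), ],
                                            min_block_size = 2))
  rownames(b1) <- rownames(b2) <- NULL
  expect_identical(b1, b2)
})

test_that("WGD-block filtering keeps the low-Ks block", {
  mk_block <- function(id, rankA, rankB, ks, score = length(rankA)) {
    anchors <- data.frame(geneA = sprintf("%s_a%d", id, seq_along(rankA)),
                          geneB = sprintf("%s_b%d", id, seq_along(rankA)),
                          rankA = rankA, rankB = rankB,
                          score = 1, stringsAsFactors = FALSE)
    structure(list(block_id = id, chromA = "c1A", chromB = "c1B",
                   orientation = "forward", score = score, anchors = anchors),
              class = "collinear_block")
  }
  ksmap <- function(blocks, ks_values) {
    df <- blocks_to_df(blocks)
    ks <- unlist(lapply(seq_along(blocks), function(i)
      rep(ks_values[i], nrow(blocks[[i]]$anchors))))
    data.frame(geneA = df$geneA, geneB = df$geneB, ks = ks)
  }
  b1 <- mk_block("B1", 0:4, 0:4, 0)
  b2 <- mk_block("B2", 0:4, 10:14, 0)   # same A ranks: overlapping claim
  kept <- filter_wgd_blocks(list(b1, b2), ksmap(list(b1, b2), c(0.02, 0.31)))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$block_id, "B1")
  expect_equal(kept[[1]]$median_ks, 0.02)

  ## no overlap, all low Ks: unchanged
  b3 <- mk_block("B3", 20:24, 20:24, 0)
  kept2 <- filter_wgd_blocks(list(b1, b3), ksmap(list(b1, b3), c(0.02, 0.05)))
  expect_length(kept2, 2)

  ## a lone block above the ceiling is dropped
  kept3 <- filter_wgd_blocks(list(b1), ksmap(list(b1), 0.3))
  expect_length(kept3, 0)
})

test_that("pair extraction dedupes genes and counts correctly", {
  mk <- function(id, genesA, genesB, score) {
    anchors <- data.frame(geneA = genesA, geneB = genesB,
                          rankA = seq_along(genesA) - 1L,
                          rankB = seq_along(genesA) - 1L,
                          score = score / length(genesA),
                          stringsAsFactors = FALSE)
    structure(list(block_id = id, chromA = "c1A", chromB = "c1B",
                   orientation = "forward", score = score, anchors = anchors),
              class = "collinear_block")
  }
  b1 <- mk("B1", sprintf("a%d", 1:5), sprintf("b%d", 1:5), 10)
  b2 <- mk("B2", sprintf("a%d", 6:10), sprintf("b%d", 6:10), 8)
  pairs <- extract_allele_pairs(list(b1, b2))
  expect_equal(nrow(pairs), 10)
  expect_equal(anyDuplicated(pairs$geneA), 0)
  expect_equal(pairs$locus_id, sprintf("L%05d", 1:10))

  ## shared gene goes to the higher-scoring block only
  b3 <- mk("B3", c("a1", "a11", "a12", "a13", "a14"),
           c("bx1", "bx2", "bx3", "bx4", "bx5"), 5)
  pairs2 <- extract_allele_pairs(list(b1, b3))
  expect_equal(sum(pairs2$geneA == "a1"), 1)
  expect_equal(pairs2$block_id[pairs2$geneA == "a1"], "B1")
})

test_that("planted pairs are recovered from the small world", {
  w <- small_world()
  ann <- w$annotation
  isA <- ann$haplotype == "A"
  m <- attach_ranks(build_match_table(w$cds[ann$gene_id[isA]],
                                      w$cds[ann$gene_id[!isA]]), ann)
  bl <- chain_collinear_blocks(m)
  ak <- kaks_pairs(w$cds, unique(blocks_to_df(bl)[, c("geneA", "geneB")]))
  kept <- filter_wgd_blocks(bl, ak)
  pairs <- extract_allele_pairs(kept)
  truthkey <- paste(w$truth$pairs$geneA, w$truth$pairs$geneB)
  callkey <- paste(pairs$geneA, pairs$geneB)
  expect_gte(mean(truthkey %in% callkey), 0.95)
  expect_gte(mean(callkey %in% truthkey), 0.99)
  ## no decoy paralog ends up in the pair list
  expect_false(any(w$truth$decoys$gene_id %in%
                   c(pairs$geneA, pairs$geneB)))
  ## pair count bound and uniqueness
  expect_lte(nrow(pairs), min(sum(isA), sum(!isA)))
  expect_equal(anyDuplicated(c(pairs$geneA, pairs$geneB)), 0)
})
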