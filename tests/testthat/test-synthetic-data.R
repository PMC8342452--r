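test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(tissues = "only_one"), "2 tissues")
  expect_error(sim_config(bias_category_mix = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(sim_config(ltr_mix = c(0.5, 0.6, -0.1)), "\\[0, 1\\]")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_equal(sum(sim_config()$replicates_per_tissue), 29L)
})

test_that("annotation generator plants pairs, noise and decoys correctly", {
  w <- small_world()
  ann <- w$annotation
  truth <- w$truth
  n_paired <- round(60 * 0.9)
  expect_equal(nrow(truth$pairs), 2 * n_paired)
  expect_equal(length(truth$unpaired), 2 * 2 * (60 - n_paired))
  ## pairs reference annotated genes on homologous chromosomes
  expect_true(all(c(truth$pairs$geneA, truth$pairs$geneB) %in% ann$gene_id))
  ia <- match(truth$pairs$geneA, ann$gene_id)
  ib <- match(truth$pairs$geneB, ann$gene_id)
  expect_true(all(ann$chrom_pair[ia] == ann$chrom_pair[ib]))
  expect_true(all(ann$haplotype[ia] == "A" & ann$haplotype[ib] == "B"))
  ## coordinates non-overlapping per chromosome
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  ## ranks dense from 0
  for (ch in unique(ann$chrom))
    expect_equal(sort(ann$rank[ann$chrom == ch]),
                 seq_len(sum(ann$chrom == ch)) - 1L)
})

test_that("fraction_unpaired = 0 puts every core gene in a pair", {
  cfg <- sim_config(seed = 5, n_chromosome_pairs = 1,
                    genes_per_chromosome = 30, fraction_unpaired = 0,
                    wgd_blocks_per_chromosome = 0, cds_codons = 50)
  gen <- generate_diploid_annotation(cfg)
  expect_setequal(c(gen$truth$pairs$geneA, gen$truth$pairs$geneB),
                  gen$annotation$gene_id)
})

test_that("undersized configurations are rejected with a sizing message", {
  expect_error(generate_diploid_annotation(
    sim_config(seed = 1, genes_per_chromosome = 4)), "genes_per_chromosome")
})

test_that("same seed gives byte-identical artifacts", {
  cfg <- sim_config(seed = 99, n_chromosome_pairs = 1,
                    genes_per_chromosome = 20, cds_codons = 50,
                    n_ltr = 50, n_ks = 500)
  run <- function() {
    gen <- generate_diploid_annotation(cfg)
    cdsres <- simulate_cds_pairs(gen$truth, cfg)
    cnt <- simulate_counts(cdsres$truth, cfg)
    reg <- plant_regulatory_context(cdsres$truth, cfg)
    kl <- simulate_ks_and_ltr(cfg)
    list(gen$annotation, cdsres$cds, cnt$counts, reg$promoters, reg$te,
         kl$ks, kl$ltr, kl$kmer_hist)
  }
  expect_identical(run(), run())
})

test_that("counts follow the planted fold changes and NB moments", {
  w <- small_world()
  truth <- w$truth
  cfg <- w$cfg
  cnt <- w$counts
  ## generating means: category none => equal allele means in every tissue;
  ## planted FC reproduced exactly by construction
  mu <- cnt$mu
  none <- truth$pairs$locus_id[truth$pairs$category == "none"]
  i <- match(none, truth$pairs$locus_id)
  s1 <- cnt$sample_sheet$sample_id[1]
  expect_equal(mu[truth$pairs$geneA[i], s1], mu[truth$pairs$geneB[i], s1],
               ignore_attr = TRUE)
  ## a biased pair has allele mean ratio equal to planted FC
  bi <- which(truth$pairs$category == "largest")[1]
  t1 <- cnt$sample_sheet$tissue[match(s1, cnt$sample_sheet$sample_id)]
  ratio <- (mu[truth$pairs$geneA[bi], s1] / mu[truth$pairs$geneB[bi], s1])
  expect_equal(unname(ratio^truth$pairs$direction[bi]),
               unname(truth$fc_tissue[bi, t1]))

  ## Monte-Carlo NB moment check: 10000 draws at one gene's mean
  set.seed(1)
  mu0 <- 80; alpha <- cfg$nb_dispersion
  x <- rnbinom(10000, mu = mu0, size = 1 / alpha)
  se_mean <- sqrt((mu0 + alpha * mu0^2) / 10000)
  expect_lt(abs(mean(x) - mu0), 3 * se_mean)
  v0 <- mu0 + alpha * mu0^2
  se_var <- sqrt(2 * v0^2 / 10000) * 1.5   # inflate for NB kurtosis
  expect_lt(abs(var(x) - v0), 3 * se_var)
})

test_that("CDS pairs keep frame, avoid stops and hit Ka/Ks targets", {
  w <- small_world()
  cds <- w$cds
  expect_true(all(nchar(cds) %% 3 == 0))
  ## no internal stops anywhere
  ct <- Biostrings::GENETIC_CODE
  internal_stop <- vapply(cds[1:20], function(x) {
    cods <- substring(x, seq(1, nchar(x) - 3, 3), seq(3, nchar(x) - 3, 3))
    any(ct[cods] == "*")
  }, logical(1))
  expect_false(any(internal_stop))

  ## planted (0, 0) gives identical sequences
  cfg0 <- sim_config(seed = 2, n_chromosome_pairs = 1,
                     genes_per_chromosome = 10, fraction_unpaired = 0,
                     wgd_blocks_per_chromosome = 0, cds_codons = 60,
                     kaks_grid = list(none = c(0, 0), smaller = c(0, 0),
                                      larger = c(0, 0), largest = c(0, 0)))
  gen0 <- generate_diploid_annotation(cfg0)
  cds0 <- simulate_cds_pairs(gen0$truth, cfg0)$cds
  expect_identical(unname(cds0[gen0$truth$pairs$geneA]),
                   unname(cds0[gen0$truth$pairs$geneB]))

  ## planted Ka=0, Ks=0.3 at 3000 codons: estimated Ka below 0.02
  set.seed(7)
  anc <- allelome:::random_cds(3000)
  pairx <- allelome:::mutate_lineages(anc, 0, 0.3)
  est <- kaks(pairx[1], pairx[2])
  expect_lt(est$ka, 0.02)
  expect_lt(abs(est$ks - 0.3), 0.045)

  ## Ks beyond the JC-correctable range is rejected
  expect_error(allelome:::check_ks_range(10, 100), "Jukes-Cantor")
})

test_that("regulatory planting records counts, offsets and TE distances", {
  w <- small_world()
  cfg <- w$cfg
  reg <- plant_regulatory_context(w$truth, cfg)
  truth <- reg$truth
  expect_equal(length(reg$promoters), nrow(w$annotation))
  expect_true(all(nchar(reg$promoters) == cfg$promoter_length))
  ## planted insertions are present verbatim at their recorded offsets
  cons <- setNames(vapply(reg$motifs, pwm_consensus, character(1)),
                   vapply(reg$motifs, function(m) m$motif_id, character(1)))
  g <- names(truth$motif_offsets)[[1]]
  off <- truth$motif_offsets[[g]]
  if (nrow(off)) {
    for (i in seq_len(nrow(off))) {
      mseq <- cons[[off$motif_id[i]]]
      expect_identical(substr(reg$promoters[[g]], off$offset[i] + 1,
                              off$offset[i] + nchar(mseq)), mseq)
    }
  }
  ## every planted TE sits at its planted distance from the gene end
  ann <- w$annotation
  smp <- head(names(truth$te_distance), 25)
  for (g in smp) {
    ge <- ann[ann$gene_id == g, ]
    sub <- reg$te[reg$te$chrom == ge$chrom, ]
    nd <- nearest_te_distance(ge$start - 1L, ge$end, sub)
    expect_lte(nd$distance, truth$te_distance[[g]])
  }
  ## motif longer than promoter rejected
  long_m <- pwm("LONG", matrix(0.25, 4, cfg$promoter_length + 1))
  expect_error(plant_regulatory_context(w$truth, cfg, motifs = list(long_m)),
               "longer than promoter")
})

test_that("Ks/LTR/k-mer simulator matches its stated construction", {
  cfg <- sim_config(seed = 21, n_ltr = 400, n_ks = 1000)
  kl <- simulate_ks_and_ltr(cfg)
  expect_true(all(kl$ks$value >= 0 & kl$ks$value <= 5))
  expect_equal(nrow(kl$ltr), 400)
  ## class-consistent evidence
  expect_true(all(kl$ltr$gagpol_complete[kl$ltr$true_class == "intact"]))
  expect_true(all(is.na(kl$ltr$flank_coverage[kl$ltr$true_class == "intact"])))
  expect_true(all(kl$ltr$flank_coverage[kl$ltr$true_class == "truncated"] >= 0.5))
  ## histogram mass identity: exact by construction
  h <- kl$kmer_hist
  mass <- sum(as.numeric(h$depth[h$depth > 2]) * h$count[h$depth > 2])
  expect_identical(mass, cfg$genome_size_bp * cfg$kmer_depth)
  ## ltr_mix (1,0,0) classifies everything intact
  cfg2 <- sim_config(seed = 3, n_ltr = 100,
                     ltr_mix = c(intact = 1, solo = 0, truncated = 0))
  kl2 <- simulate_ks_and_ltr(cfg2)
  expect_true(all(classify_ltr(kl2$ltr) == "intact"))
})
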