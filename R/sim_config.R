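#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generator. Defaults state
#' the world the downstream analyses assume: a diploid with 11 homologous
#' chromosome pairs, expression over 7 tissues in 29 samples total (4
#' replicates per tissue plus one extra in the first tissue),
#' negative-binomial counts, four-level allelic-bias categories, 2-kb
#' promoters, and an LTR mutation rate of 1.3e-8 substitutions/site/year.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_chromosome_pairs number of homologous chromosome pairs.
#' @param genes_per_chromosome genes per haplotype chromosome.
#' @param fraction_unpaired proportion of genes per chromosome without a
#'   counterpart on the other haplotype (noise genes).
#' @param tissues character vector of tissue labels (>= 2).
#' @param replicates_per_tissue integer replicates per tissue; may be a single
#'   number or one per tissue. Default `c(5, 4, 4, 4, 4, 4, 4)` gives 29
#'   samples over 7 tissues.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param bias_category_mix proportions of the four bias categories
#'   (none, smaller, larger, largest); must sum to 1.
#' @param promoter_length promoter length in bp upstream of the gene start.
#' @param te_distance_grid candidate TE-to-gene distances in bp.
#' @param kaks_grid list of c(ka, ks) targets, one per bias category in the
#'   order none/smaller/larger/largest (recycled if shorter).
#' @param ks_mixture list of c(mean, sd, weight) normal components for the
#'   paralog Ks distribution; weights must sum to 1.
#' @param ltr_mix proportions of intact/solo/truncated LTR records (sums to 1).
#' @param mutation_rate substitutions per site per year used to convert LTR
#'   divergence to insertion age.
#' @param cds_codons codon length of simulated coding sequences.
#' @param n_ltr number of simulated LTR-RT records.
#' @param n_ltr_families number of LTR families seeding the cluster structure.
#' @param n_ks number of simulated paralog Ks values.
#' @param genome_size_bp genome size implied by the synthetic k-mer histogram.
#' @param kmer_depth homozygous-peak sequencing depth of the k-mer histogram.
#' @param block_size gene count per planted collinear block.
#' @param wgd_blocks_per_chromosome planted paralogous (WGD-like) decoy blocks
#'   per chromosome pair; these must be removed by the Ks-ceiling filter.
#' @param base_log_mean,base_log_sd log-normal parameters of per-gene baseline
#'   expression means (counts scale).
#' @param transition_rate per-tissue probability that a biased locus steps to a
#'   neighbouring category in one tissue.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosome_pairs = 11L,
                       genes_per_chromosome = 200L,
                       fraction_unpaired = 0.10,
                       tissues = c("leaf", "bud", "rhizome", "rhizome_heart",
                                   "rhizome_skin", "tip_lateral", "tip_upward"),
                       replicates_per_tissue = c(5L, 4L, 4L, 4L, 4L, 4L, 4L),
                       nb_dispersion = 0.05,
                       bias_category_mix = c(none = 0.70, smaller = 0.10,
                                             larger = 0.12, largest = 0.08),
                       promoter_length = 2000L,
                       te_distance_grid = c(0L, 200L, 500L, 1000L, 2000L,
                                            5000L, 10000L),
                       kaks_grid = list(none = c(0.004, 0.020),
                                        smaller = c(0.006, 0.025),
                                        larger = c(0.010, 0.030),
                                        largest = c(0.020, 0.040)),
                       ks_mixture = list(c(mean = 0.3, sd = 0.06, weight = 0.5),
                                         c(mean = 0.7, sd = 0.10, weight = 0.5)),
                       ltr_mix = c(intact = 0.25, solo = 0.50, truncated = 0.25),
                       mutation_rate = 1.3e-8,
                       cds_codons = 300L,
                       n_ltr = 2000L,
                       n_ltr_families = 20L,
                       n_ks = 4000L,
                       genome_size_bp = 1e8,
                       kmer_depth = 30L,
                       block_size = 50L,
                       wgd_blocks_per_chromosome = 1L,
                       base_log_mean = log(150),
                       base_log_sd = 1.0,
                       transition_rate = 0.05) {
  if (length(replicates_per_tissue) == 1L)
    replicates_per_tissue <- rep(replicates_per_tissue, length(tissues))
  cfg <- list(seed = as.integer(seed),
              n_chromosome_pairs = as.integer(n_chromosome_pairs),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              fraction_unpaired = fraction_unpaired,
              tissues = tissues,
              replicates_per_tissue = as.integer(replicates_per_tissue),
              nb_dispersion = nb_dispersion,
              bias_category_mix = bias_category_mix,
              promoter_length = as.integer(promoter_length),
              te_distance_grid = as.integer(te_distance_grid),
              kaks_grid = kaks_grid,
              ks_mixture = ks_mixture,
              ltr_mix = ltr_mix,
              mutation_rate = mutation_rate,
              cds_codons = as.integer(cds_codons),
              n_ltr = as.integer(n_ltr),
              n_ltr_families = as.integer(n_ltr_families),
              n_ks = as.integer(n_ks),
              genome_size_bp = genome_size_bp,
              kmer_depth = as.integer(kmer_depth),
              block_size = as.integer(block_size),
              wgd_blocks_per_chromosome = as.integer(wgd_blocks_per_chromosome),
              base_log_mean = base_log_mean,
              base_log_sd = base_log_sd,
              transition_rate = transition_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (length(cfg$tissues) < 2L)
    stop("at least 2 tissues are required")
  if (length(cfg$replicates_per_tissue) != length(cfg$tissues))
    stop("replicates_per_tissue must have one entry per tissue")
  props <- c(cfg$fraction_unpaired, cfg$bias_category_mix, cfg$ltr_mix)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (abs(sum(cfg$bias_category_mix) - 1) > 1e-9)
    stop("bias_category_mix must sum to 1")
  if (abs(sum(cfg$ltr_mix) - 1) > 1e-9)
    stop("ltr_mix must sum to 1")
  w <- sum(vapply(cfg$ks_mixture, function(x) x[["weight"]], numeric(1)))
  if (abs(w - 1) > 1e-9)
    stop("ks_mixture weights must sum to 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$mutation_rate <= 0) stop("mutation_rate must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  chromosomes: %d pairs x %d genes (%.0f%% unpaired)\n",
              x$n_chromosome_pairs, x$genes_per_chromosome,
              100 * x$fraction_unpaired))
  cat(sprintf("  expression: %d tissues, %d samples, NB dispersion %.3g\n",
              length(x$tissues), sum(x$replicates_per_tissue),
              x$nb_dispersion))
  cat(sprintf("  bias mix: %s\n",
              paste(sprintf("%s=%.2f", names(x$bias_category_mix),
                            x$bias_category_mix), collapse = " ")))
  invisible(x)
}
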