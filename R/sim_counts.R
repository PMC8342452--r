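#' Simulate a negative-binomial count matrix with planted allelic bias
#'
#' Generates integer counts for every annotated gene over the configured
#' tissue/replicate design. For an allele pair planted in category c in
#' tissue t with fold change FC, the two allele means are m * sqrt(FC) and
#' m / sqrt(FC) (direction decides which allele is up), where m is the
#' locus baseline mean; unpaired and decoy genes keep their own baseline
#' mean in every tissue. Counts are drawn independently per gene and sample
#' from NB(mu, dispersion = `nb_dispersion`), with per-sample library-size
#' factors (log-normal, sd 0.2) multiplying all means.
#'
#' @param truth a `truth_table`.
#' @param config the matching [sim_config()].
#' @return list with `counts` (integer matrix genes x samples),
#'   `sample_sheet` (data.frame sample_id, tissue), `lengths` (named bp
#'   vector) and `mu` (the generating mean matrix, for diagnostics).
#' @export
simulate_counts <- function(truth, config) {
  set.seed(child_seed(config$seed, "counts"))
  tissues <- config$tissues
  reps <- config$replicates_per_tissue
  sample_sheet <- data.frame(
    sample_id = unlist(lapply(seq_along(tissues), function(i)
      sprintf("%s_r%d", tissues[i], seq_len(reps[i])))),
    tissue = rep(tissues, reps), stringsAsFactors = FALSE)

  genes <- names(truth$base_mean)
  n_g <- length(genes); n_s <- nrow(sample_sheet)

  ## per-gene per-tissue means: baseline x latent tissue program, with the
  ## planted fold change split symmetrically between the two alleles
  prog <- truth$program_profile[truth$gene_program[genes], , drop = FALSE]
  mu_t <- matrix(truth$base_mean, n_g, length(tissues),
                 dimnames = list(genes, tissues)) * prog
  pr <- truth$pairs
  base_locus <- truth$base_mean[pr$geneA]
  prog_locus <- truth$program_profile[truth$gene_program[pr$geneA], ,
                                      drop = FALSE]
  for (t in seq_along(tissues)) {
    fc <- truth$fc_tissue[, t]
    up <- sqrt(fc)^pr$direction
    mu_t[pr$geneA, t] <- base_locus * prog_locus[, t] * up
    mu_t[pr$geneB, t] <- base_locus * prog_locus[, t] / up
  }

  size_factor <- exp(rnorm(n_s, 0, 0.2))
  mu <- mu_t[, sample_sheet$tissue, drop = FALSE] *
    rep(size_factor, each = n_g)
  colnames(mu) <- sample_sheet$sample_id

  counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / config$nb_dispersion),
                   n_g, n_s, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  list(counts = counts, sample_sheet = sample_sheet,
       lengths = truth$gene_length[genes], mu = mu)
}
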