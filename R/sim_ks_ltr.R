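#' Simulate Ks samples, LTR-RT records and a k-mer histogram
#'
#' Three dating-related inputs with planted truth:
#' \itemize{
#' \item Ks values drawn from the configured normal mixture, truncated to
#'   [0, 5] by resampling (component means are the planted peaks);
#' \item LTR-RT records in the configured intact/solo/truncated proportions,
#'   carrying class-consistent evidence fields (complete Gag-Pol for intact;
#'   a passing library hit for solo and truncated; partial flanking Gag-Pol
#'   coverage only for truncated) plus 5'/3' LTR sequences for intact
#'   elements whose divergence encodes a planted insertion age drawn
#'   uniformly over the past 5 million years;
#' \item a diploid-style k-mer histogram with a heterozygous peak at half
#'   depth and a homozygous peak at `kmer_depth`, whose k-mer mass at depths
#'   >= 3 equals `genome_size_bp * kmer_depth` exactly.
#' }
#'
#' @param config a [sim_config()].
#' @return list with `ks` (data.frame value/source/excluded), `ltr`
#'   (record table with evidence fields and planted class/age), `kmer_hist`
#'   (data.frame depth/count), and `planted` (peaks, class table, ages).
#' @export
simulate_ks_and_ltr <- function(config) {
  set.seed(child_seed(config$seed, "ks_ltr"))

  ## --- Ks mixture ---
  comp <- sample(seq_along(config$ks_mixture), config$n_ks, replace = TRUE,
                 prob = vapply(config$ks_mixture, `[[`, numeric(1), "weight"))
  ks_val <- vapply(comp, function(ci) {
    m <- config$ks_mixture[[ci]]
    repeat {
      x <- rnorm(1, m[["mean"]], m[["sd"]])
      if (x >= 0 && x <= 5) return(x)
    }
  }, numeric(1))
  ks <- data.frame(value = ks_val, source = "paralog",
                   excluded = ks_val > 5, stringsAsFactors = FALSE)

  ## --- LTR records ---
  n <- config$n_ltr
  classes <- sample(names(config$ltr_mix), n, replace = TRUE,
                    prob = config$ltr_mix)
  fam_len <- 300L
  fam_seq <- vapply(seq_len(config$n_ltr_families), function(i)
    random_dna(fam_len), character(1))
  fam <- sample.int(config$n_ltr_families, n, replace = TRUE)
  age <- runif(n, 0, 5e6)
  d <- 2 * config$mutation_rate * age        # planted 5'-3' divergence
  p_raw <- 0.75 * (1 - exp(-4 * d / 3))

  ltr5 <- vapply(seq_len(n), function(i)
    mutate_dna(fam_seq[fam[i]], runif(1, 0.02, 0.18)), character(1))
  ltr3 <- rep(NA_character_, n)
  intact <- classes == "intact"
  ltr3[intact] <- vapply(which(intact), function(i)
    mutate_dna(ltr5[i], p_raw[i]), character(1))
  age[!intact] <- NA_real_

  lib_pass <- classes %in% c("solo", "truncated")
  ltr <- data.frame(
    record_id = sprintf("LTR%05d", seq_len(n)),
    chromosome = sprintf("chr%02dA", sample.int(config$n_chromosome_pairs, n,
                                                replace = TRUE)),
    start = sample.int(1e7, n), family = fam,
    gagpol_complete = intact,
    lib_evalue = ifelse(lib_pass, 10^runif(n, -40, -12), NA_real_),
    lib_overlap = ifelse(lib_pass, runif(n, 0.92, 1.0), NA_real_),
    lib_identity = ifelse(lib_pass, runif(n, 0.92, 1.0), NA_real_),
    flank_coverage = ifelse(classes == "truncated", runif(n, 0.55, 0.95),
                            ifelse(classes == "solo", runif(n, 0, 0.2),
                                   NA_real_)),
    flank_identity = ifelse(classes == "truncated", runif(n, 0.32, 0.60),
                            ifelse(classes == "solo", runif(n, 0.0, 0.15),
                                   NA_real_)),
    flank_evalue = ifelse(classes == "truncated", 10^runif(n, -30, -9),
                          ifelse(classes == "solo", 10^runif(n, -4, 0),
                                 NA_real_)),
    ltr5_seq = ltr5, ltr3_seq = ltr3,
    true_class = classes, true_age = age,
    stringsAsFactors = FALSE)
  ltr$end <- ltr$start + ifelse(intact, 8000L, fam_len)

  kmer_hist <- synthetic_kmer_histogram(config$genome_size_bp,
                                        config$kmer_depth)

  planted <- list(
    ks_peaks = sort(vapply(config$ks_mixture, `[[`, numeric(1), "mean")),
    ltr_class = setNames(classes, ltr$record_id),
    ltr_age = setNames(age, ltr$record_id))
  list(ks = ks, ltr = ltr, kmer_hist = kmer_hist, planted = planted)
}

## point mutations at proportion p of sites (distinct positions)
mutate_dna <- function(seqn, p) {
  chars <- strsplit(seqn, "")[[1]]
  k <- round(p * length(chars))
  if (k > 0) {
    pos <- sample.int(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

## Diploid k-mer histogram whose mass at depths >= 3 is exactly size * depth.
synthetic_kmer_histogram <- function(genome_size, depth) {
  depths <- 1:(3 * depth)
  shape <- 0.4 * stats::dnorm(depths, depth / 2, depth / 12) +
    0.6 * stats::dnorm(depths, depth, depth / 9)
  shape[1:2] <- 0
  counts <- round(shape * genome_size * depth / sum(depths * shape))
  counts[1:2] <- round(genome_size * 0.05)   # error tail, excluded downstream
  target <- genome_size * depth
  resid <- target - sum(depths[-(1:2)] * counts[-(1:2)])
  counts[depth] <- counts[depth] + resid %/% depth
  rem <- resid %% depth
  if (rem > 0) {
    if (rem < 3) { counts[depth] <- counts[depth] - 1L; rem <- rem + depth }
    counts[rem] <- counts[rem] + 1L
  }
  data.frame(depth = depths, count = counts)
}
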