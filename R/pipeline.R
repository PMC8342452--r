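## End-to-end orchestration on synthetic or user-supplied inputs.

#' Pipeline thresholds
#'
#' All tunables in one place; defaults are the analysis' stated values
#' (0.5 TPM expressed rule, fold-change cut-offs 2 and 8 on adjusted
#' p < 0.05, top/bottom 10% dynamic/stable, PWM p < 1e-5 with pseudocount
#' 1e-8, scale-free fit 0.9, minimum module size 60, merge cut 0.15,
#' divergence at 50% of the median maximum eigengene distance, Ks > 5
#' exclusion, LTR mutation rate 1.3e-8, library hit E < 1e-10 /
#' overlap > 0.9 / identity > 0.9, flank coverage >= 0.5 / identity >= 0.3
#' at E < 1e-8, and a Ks = 0.7 / 63.57 MYA rate anchor).
#'
#' @param ... overrides of the defaults (checked by name).
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function(...) {
  th <- list(tpm_expressed = 0.5, fc_small = 2, fc_large = 8, alpha = 0.05,
             top_fraction = 0.10, pwm_p = 1e-5, pwm_pseudocount = 1e-8,
             scale_free_target = 0.9, min_module_size = 60L,
             merge_cut_height = 0.15, divergence_fraction = 0.5,
             ks_exclude = 5.0, wgd_ks_ceiling = 0.15,
             min_block_size = 5L, max_gap = 25L, match_top_k = 3L,
             mu = 1.3e-8, anchor_ks = 0.7, anchor_mya = 63.57,
             ltr = ltr_thresholds())
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  th
}

#' Run the allele-aware pipeline end to end on synthetic data
#'
#' Generates every input from `config`, persists the artifacts under
#' `outdir`, and runs the enabled stages in dependency order: allele
#' pairing (match table, collinear chaining, WGD-block filtering), TPM and
#' expressed-gene filtering, per-tissue allelic bias calls with
#' dynamic/stable ranking and transition summary, Ka/Ks per pair, promoter
#' TFBS scanning and shared/specific accounting, nearest-TE distances,
#' coexpression modules with the eigengene divergence rule, Ks-peak/WGD
#' and LTR dating plus k-mer genome size, LTR lifecycle statistics, and
#' category contrasts. Identical config and seed give an identical report.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @param stages character vector of stages to run (default all):
#'   subset of pairing, ase, kaks, tfbs, te, coexpr, dating, ltr,
#'   contrasts. The simulate stage always runs.
#' @param thresholds a [pipeline_thresholds()] list.
#' @param cluster_ltr logical; run LTR family clustering (quadratic in the
#'   number of records; default only when <= 300 records).
#' @return a `run_report` list; also written as `report.json` in `outdir`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("allelome_"),
                         stages = c("pairing", "ase", "kaks", "tfbs", "te",
                                    "coexpr", "dating", "ltr", "contrasts"),
                         thresholds = pipeline_thresholds(),
                         cluster_ltr = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("allelome")),
                 seed = config$seed, stages = stages,
                 thresholds = thresholds[setdiff(names(thresholds), "ltr")])

  ## ---- simulate ----
  gen <- generate_diploid_annotation(config)
  cdsres <- simulate_cds_pairs(gen$truth, config)
  truth <- cdsres$truth
  cnt <- simulate_counts(truth, config)
  reg <- plant_regulatory_context(truth, config)
  truth <- reg$truth
  ksltr <- simulate_ks_and_ltr(config)

  write_annotation_gff3(gen$annotation, file.path(outdir, "annotation.gff3"))
  write_fasta(cdsres$cds, file.path(outdir, "cds.fasta"))
  write_fasta(reg$promoters, file.path(outdir, "promoters.fasta"))
  write_te_bed(reg$te, file.path(outdir, "te.bed"))
  write_counts(cnt$counts, cnt$sample_sheet, file.path(outdir, "counts.tsv"),
               file.path(outdir, "samples.tsv"))
  write_meme(reg$motifs, file.path(outdir, "motifs.meme"))
  write_table_tsv(ksltr$ks, file.path(outdir, "ks_values.tsv"))
  write_table_tsv(ksltr$ltr, file.path(outdir, "ltr_records.tsv"))
  write_kmer_histogram(ksltr$kmer_hist, file.path(outdir, "kmer_hist.tsv"))
  report$simulate <- list(n_genes = nrow(gen$annotation),
                          n_planted_pairs = nrow(truth$pairs),
                          n_samples = nrow(cnt$sample_sheet))

  ## read everything back through the package's own readers so later
  ## stages consume the persisted artifacts, not in-memory objects
  annotation <- read_annotation_gff3(file.path(outdir, "annotation.gff3"))
  cds <- read_fasta(file.path(outdir, "cds.fasta"))
  promoters <- read_fasta(file.path(outdir, "promoters.fasta"))
  te <- read_te_bed(file.path(outdir, "te.bed"))
  cc <- read_counts(file.path(outdir, "counts.tsv"),
                    file.path(outdir, "samples.tsv"))
  motifs <- read_meme(file.path(outdir, "motifs.meme"),
                      pseudocount = thresholds$pwm_pseudocount)

  pairs <- NULL; kaks_tab <- NULL; calls <- NULL

  ## ---- allele pairing ----
  if ("pairing" %in% stages) {
    isA <- annotation$haplotype == "A"
    matches <- build_match_table(cds[annotation$gene_id[isA]],
                                 cds[annotation$gene_id[!isA]],
                                 top_k = thresholds$match_top_k)
    matches <- attach_ranks(matches, annotation)
    blocks <- chain_collinear_blocks(matches, thresholds$min_block_size,
                                     thresholds$max_gap)
    anchors <- blocks_to_df(blocks)
    anchor_ks <- kaks_pairs(cds, unique(anchors[, c("geneA", "geneB")]))
    kept <- filter_wgd_blocks(blocks, anchor_ks,
                              ks_ceiling = thresholds$wgd_ks_ceiling)
    pairs <- extract_allele_pairs(kept)
    write_table_tsv(matches, file.path(outdir, "matches.tsv"))
    write_table_tsv(blocks_to_df(kept), file.path(outdir, "blocks.tsv"))
    write_table_tsv(pairs, file.path(outdir, "pairs.tsv"))
    report$pairing <- list(n_matches = nrow(matches),
                           n_blocks = length(blocks),
                           n_blocks_kept = length(kept),
                           n_pairs = nrow(pairs))
    ## reuse anchor Ka/Ks for the final pairs
    key <- paste(anchor_ks$geneA, anchor_ks$geneB)
    kaks_tab <- anchor_ks[match(paste(pairs$geneA, pairs$geneB), key), ]
    kaks_tab$locus_id <- pairs$locus_id
  }

  ## ---- expression ----
  tpm <- compute_tpm(cc$counts, setNames(annotation$end - annotation$start + 1L,
                                         annotation$gene_id))
  expressed <- filter_expressed(tpm, thresholds$tpm_expressed)
  report$expression <- list(n_expressed = length(expressed),
                            n_genes = nrow(tpm))

  if ("ase" %in% stages && !is.null(pairs) && nrow(pairs)) {
    calls <- ase_bias_calls(cc$counts, cc$sample_sheet, pairs,
                            alpha = thresholds$alpha)
    profiles <- rank_dynamic_stable(calls, thresholds$top_fraction)
    trans <- transition_summary(calls)
    write_table_tsv(calls, file.path(outdir, "bias_calls.tsv"))
    write_table_tsv(profiles, file.path(outdir, "profiles.tsv"))
    prop <- prop.table(table(calls$tissue, calls$category), margin = 1)
    report$ase <- list(
      category_proportions = as.data.frame.matrix(prop),
      n_dynamic = sum(profiles$label == "dynamic"),
      n_stable = sum(profiles$label == "stable"),
      transitions = as.list(trans$counts))
  }

  if ("kaks" %in% stages && !is.null(kaks_tab)) {
    write_table_tsv(kaks_tab, file.path(outdir, "kaks.tsv"))
    ok <- !kaks_tab$excluded & !is.na(kaks_tab$ks)
    report$kaks <- list(n = nrow(kaks_tab), n_excluded = sum(kaks_tab$excluded),
                        median_ka = median(kaks_tab$ka[ok], na.rm = TRUE),
                        median_ks = median(kaks_tab$ks[ok], na.rm = TRUE))
  }

  tfbs_cmp <- NULL
  if ("tfbs" %in% stages && !is.null(pairs) && nrow(pairs)) {
    pair_genes <- unique(c(pairs$geneA, pairs$geneB))
    hits <- scan_promoters(promoters[pair_genes], motifs,
                           p_threshold = thresholds$pwm_p)
    write_table_tsv(hits, file.path(outdir, "tfbs_hits.tsv"))
    hsplit <- split(hits, hits$gene_id)
    empty <- hits[0, ]
    tfbs_cmp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      cbind(locus_id = pairs$locus_id[i],
            compare_tfbs(hsplit[[pairs$geneA[i]]] %||% empty,
                         hsplit[[pairs$geneB[i]]] %||% empty))))
    write_table_tsv(tfbs_cmp, file.path(outdir, "tfbs_comparison.tsv"))
    report$tfbs <- list(n_hits = nrow(hits),
                        mean_shared = mean(tfbs_cmp$shared),
                        mean_specific = mean(tfbs_cmp$specific_A +
                                             tfbs_cmp$specific_B))
  }

  te_dist <- NULL
  if ("te" %in% stages && !is.null(pairs) && nrow(pairs)) {
    pair_genes <- unique(c(pairs$geneA, pairs$geneB))
    gsub <- annotation[annotation$gene_id %in% pair_genes, ]
    te_dist <- nearest_te_distances(gsub, te)
    write_table_tsv(te_dist, file.path(outdir, "te_distance.tsv"))
    report$te <- list(n = nrow(te_dist),
                      median_distance = median(te_dist$nearest_te_distance,
                                               na.rm = TRUE))
  }

  divergence <- NULL
  if ("coexpr" %in% stages && !is.null(pairs) && nrow(pairs)) {
    pair_genes <- unique(c(pairs$geneA, pairs$geneB))
    use <- intersect(pair_genes, expressed)
    ncfg <- network_config(scale_free_target = thresholds$scale_free_target,
                           min_module_size = thresholds$min_module_size,
                           merge_cut_height = thresholds$merge_cut_height)
    assignment <- detect_modules(tpm[use, , drop = FALSE], ncfg)
    divergence <- classify_allele_divergence(
      pairs, assignment, threshold_fraction = thresholds$divergence_fraction)
    write_table_tsv(divergence, file.path(outdir, "divergence.tsv"))
    write_table_tsv(data.frame(gene_id = names(assignment$modules),
                               module = unname(assignment$modules)),
                    file.path(outdir, "modules.tsv"))
    report$coexpr <- list(
      soft_power = assignment$soft_power,
      n_modules = nrow(assignment$eigengenes),
      class_fractions = as.list(prop.table(table(divergence$class))))
  }

  if ("dating" %in% stages) {
    ksv <- read_table_tsv(file.path(outdir, "ks_values.tsv"))
    peaks <- detect_ks_peaks(ksv$value[!ksv$excluded])
    cal <- calibrate_rate(thresholds$anchor_ks, thresholds$anchor_mya * 1e6)
    dated <- do.call(rbind, lapply(seq_along(peaks), function(i)
      date_event(peaks[i], cal, label = sprintf("ks_peak_%d", i))))
    ltr_tab <- read_table_tsv(file.path(outdir, "ltr_records.tsv"))
    cls <- classify_ltr(ltr_tab, thresholds$ltr)
    ages <- ltr_ages(ltr_tab, cls, mu = thresholds$mu)
    gs <- kmer_genome_size(read_kmer_histogram(file.path(outdir,
                                                         "kmer_hist.tsv")))
    write_table_tsv(dated, file.path(outdir, "dating.tsv"))
    report$dating <- list(ks_peaks = as.numeric(peaks),
                          rate = cal$r, events = dated,
                          median_ltr_age_my = median(ages, na.rm = TRUE) / 1e6,
                          genome_size = gs$genome_size,
                          kmer_peak_depth = gs$peak_depth)
  }

  if ("ltr" %in% stages) {
    ltr_tab <- read_table_tsv(file.path(outdir, "ltr_records.tsv"))
    cls <- classify_ltr(ltr_tab, thresholds$ltr)
    if (is.null(cluster_ltr)) cluster_ltr <- nrow(ltr_tab) <= 300L
    clusters <- NULL
    if (cluster_ltr) {
      l5 <- setNames(ltr_tab$ltr5_seq, ltr_tab$record_id)
      clusters <- cluster_ltrs(l5, classes = setNames(cls, ltr_tab$record_id))
      clusters <- clusters[ltr_tab$record_id]
    }
    stats <- lifecycle_ratios(cls, clusters)
    write_table_tsv(data.frame(record_id = ltr_tab$record_id, class = cls,
                               cluster = if (is.null(clusters)) NA
                                         else unname(clusters)),
                    file.path(outdir, "ltr_classes.tsv"))
    report$ltr <- list(counts = as.list(stats$counts),
                       SI = unname(stats$ratios["SI"]),
                       TI = unname(stats$ratios["TI"]),
                       fraction_clusters_SI_gt3 = stats$fraction_clusters_SI_gt3)
  }

  if ("contrasts" %in% stages && !is.null(calls)) {
    report$contrasts <- contrast_by_category(
      calls = calls, tpm = tpm, pairs = pairs, kaks_tab = kaks_tab,
      tfbs_cmp = tfbs_cmp, te_dist = te_dist)
  }

  class(report) <- "run_report"
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, na = "null", force = TRUE),
             file.path(outdir, "report.json"))
  report$outdir <- outdir
  report
}

#' Category contrasts of expression, regulatory and divergence metrics
#'
#' Assigns each locus its most severe significant bias category across
#' tissues and compares metric distributions between categories with the
#' two-sided tie-corrected Mann-Whitney-Wilcoxon test ([mww_test()]).
#' Categories with fewer than 3 members are skipped.
#'
#' @param calls per-tissue bias calls ([ase_bias_calls()]).
#' @param tpm TPM matrix.
#' @param pairs allele-pair table.
#' @param kaks_tab Ka/Ks table with locus_id (optional).
#' @param tfbs_cmp TFBS comparison table with locus_id (optional).
#' @param te_dist nearest-TE distance table (optional).
#' @return list with `locus_category` and per-metric pairwise test tables.
#' @export
contrast_by_category <- function(calls, tpm, pairs, kaks_tab = NULL,
                                 tfbs_cmp = NULL, te_dist = NULL) {
  sev <- c(none = 0L, smaller = 1L, larger = 2L, largest = 3L)
  locus_cat <- vapply(split(calls$category, calls$locus_id),
                      function(cc) names(sev)[max(sev[cc]) + 1L], character(1))
  pairs$category <- locus_cat[pairs$locus_id]

  metrics <- list()
  metrics$tpm <- data.frame(
    locus_id = pairs$locus_id,
    value = (rowMeans(tpm[pairs$geneA, , drop = FALSE]) +
             rowMeans(tpm[pairs$geneB, , drop = FALSE])) / 2)
  if (!is.null(tfbs_cmp)) {
    metrics$shared_tfbs <- data.frame(locus_id = tfbs_cmp$locus_id,
                                      value = tfbs_cmp$shared)
    metrics$specific_tfbs <- data.frame(
      locus_id = tfbs_cmp$locus_id,
      value = tfbs_cmp$specific_A + tfbs_cmp$specific_B)
  }
  if (!is.null(te_dist)) {
    byg <- setNames(te_dist$nearest_te_distance, te_dist$gene_id)
    metrics$te_distance <- data.frame(
      locus_id = pairs$locus_id,
      value = pmin(byg[pairs$geneA], byg[pairs$geneB]))
  }
  if (!is.null(kaks_tab)) {
    ok <- !kaks_tab$excluded
    metrics$ka <- data.frame(locus_id = kaks_tab$locus_id[ok],
                             value = kaks_tab$ka[ok])
    metrics$ks <- data.frame(locus_id = kaks_tab$locus_id[ok],
                             value = kaks_tab$ks[ok])
    metrics$kaks_ratio <- data.frame(locus_id = kaks_tab$locus_id[ok],
                                     value = kaks_tab$ratio[ok])
  }

  tests <- lapply(metrics, function(m) {
    m$category <- locus_cat[as.character(m$locus_id)]
    m <- m[!is.na(m$value) & !is.na(m$category), ]
    groups <- split(m$value, m$category)
    groups <- groups[lengths(groups) >= 3L]
    if (length(groups) < 2L) return(NULL)
    cmb <- utils::combn(names(groups), 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      tst <- mww_test(groups[[a]], groups[[b]])
      data.frame(group1 = a, group2 = b, n1 = length(groups[[a]]),
                 n2 = length(groups[[b]]),
                 median1 = median(groups[[a]]), median2 = median(groups[[b]]),
                 p = tst$p.value, stringsAsFactors = FALSE)
    }))
  })
  list(locus_category = locus_cat,
       category_counts = as.list(table(locus_cat)),
       tests = tests[!vapply(tests, is.null, logical(1))])
}

#' @export
print.run_report <- function(x, ...) {
  cat("allelome run report\n")
  cat(sprintf("  seed %d; stages: %s\n", x$seed,
              paste(x$stages, collapse = ", ")))
  if (!is.null(x$pairing))
    cat(sprintf("  pairing: %d pairs from %d blocks\n", x$pairing$n_pairs,
                x$pairing$n_blocks_kept))
  if (!is.null(x$ase))
    cat(sprintf("  ase: %d dynamic / %d stable loci\n", x$ase$n_dynamic,
                x$ase$n_stable))
  if (!is.null(x$dating))
    cat(sprintf("  dating: Ks peaks at %s\n",
                paste(sprintf("%.2f", x$dating$ks_peaks), collapse = ", ")))
  if (!is.null(x$ltr))
    cat(sprintf("  LTR: S:I = %.2f\n", x$ltr$SI))
  invisible(x)
}
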