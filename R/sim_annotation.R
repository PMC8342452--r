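#' Generate a diploid gene annotation with planted allele pairs
#'
#' Emulates a haplotype-resolved diploid assembly: `n_chromosome_pairs`
#' homologous chromosome pairs (suffixes A/B), each carrying collinear blocks
#' of allele pairs with conserved gene order (a fraction of blocks is
#' orientation-reversed on B), plus a fraction of unpaired noise genes per
#' haplotype and, optionally, paralogous decoy blocks on haplotype B that
#' mimic collinear blocks arising from an ancient whole-genome duplication
#' (these carry high planted Ks and must be removed by the Ks-ceiling
#' filter).
#'
#' All genes are single-exon, on the + strand, with a promoter of
#' `promoter_length` bp immediately upstream. The generated genome sequence
#' is random background; gene content enters downstream analyses through the
#' CDS, promoter and count artifacts.
#'
#' @param config a [sim_config()] object.
#' @return list with `annotation` (data.frame: gene_id, chrom, start, end,
#'   strand, haplotype, chrom_pair, rank, role), `genome` (named
#'   `DNAStringSet`), and `truth` (a `truth_table`; see Details).
#' @details The truth table records the planted world: allele pairs with
#'   their block and orientation, per-locus bias category and direction,
#'   per-tissue category and fold-change matrices, per-gene baseline means,
#'   planted (Ka, Ks) targets per pair, decoy paralog links and unpaired
#'   gene ids. Later generator stages append planted motif counts, TE
#'   distances, Ks peaks and LTR classes.
#' @export
generate_diploid_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "annotation"))

  n_chr <- config$n_chromosome_pairs
  n_genes <- config$genes_per_chromosome
  n_unpaired <- round(config$fraction_unpaired * n_genes)
  n_paired <- n_genes - n_unpaired
  if (n_paired < 5L)
    stop("genes_per_chromosome too small: fewer than 5 paired genes per ",
         "chromosome cannot host one minimum-size collinear block; ",
         "increase genes_per_chromosome or lower fraction_unpaired")

  gene_len <- config$cds_codons * 3L
  slot <- config$promoter_length + gene_len + 500L

  ann <- list(); pairs <- list(); decoys <- list()
  locus_counter <- 0L

  for (ci in seq_len(n_chr)) {
    pair_ids <- sprintf("Zo%02dG%04d", ci, seq_len(n_paired))
    geneA <- paste0(pair_ids, "A")
    geneB <- paste0(pair_ids, "B")

    ## block structure over the paired genes; every third block reversed on B
    n_blocks <- max(1L, ceiling(n_paired / config$block_size))
    block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(n_paired)]
    block_rev <- (seq_len(n_blocks) %% 3L) == 0L & n_blocks > 1L

    ## order on A: blocks in order; order on B: reversed blocks flipped
    ordA <- seq_len(n_paired)
    ordB <- unlist(lapply(seq_len(n_blocks), function(b) {
      idx <- which(block_of == b)
      if (block_rev[b]) rev(idx) else idx
    }), use.names = FALSE)

    noiseA <- sprintf("Zo%02dN%04dA", ci, seq_len(max(n_unpaired, 0L)))
    noiseB <- sprintf("Zo%02dN%04dB", ci, seq_len(max(n_unpaired, 0L)))
    if (n_unpaired == 0L) { noiseA <- character(0); noiseB <- character(0) }

    seqA <- interleave_noise(geneA[ordA], noiseA)
    seqB <- interleave_noise(geneB[ordB], noiseB)

    ## paralogous decoy block(s) on B, copied from a run of A-paired genes
    dec <- NULL
    if (config$wgd_blocks_per_chromosome > 0L && n_paired >= 10L) {
      for (wi in seq_len(config$wgd_blocks_per_chromosome)) {
        w <- min(8L, n_paired %/% 2L)
        start_idx <- ((wi - 1L) * w) %% (n_paired - w) + 1L
        src <- geneA[start_idx:(start_idx + w - 1L)]
        dec_ids <- sprintf("Zo%02dW%02d%02dB", ci, wi, seq_len(w))
        seqB <- c(seqB, dec_ids)
        dec <- rbind(dec, data.frame(gene_id = dec_ids, source_gene = src,
                                     stringsAsFactors = FALSE))
      }
    }
    if (!is.null(dec)) decoys[[ci]] <- dec

    chromA <- sprintf("chr%02dA", ci)
    chromB <- sprintf("chr%02dB", ci)
    ann[[length(ann) + 1L]] <- chrom_annotation(seqA, chromA, "A", ci, slot,
                                                gene_len, config$promoter_length)
    ann[[length(ann) + 1L]] <- chrom_annotation(seqB, chromB, "B", ci, slot,
                                                gene_len, config$promoter_length)

    loci <- locus_counter + seq_len(n_paired)
    locus_counter <- locus_counter + n_paired
    pairs[[ci]] <- data.frame(
      locus_id = sprintf("L%05d", loci),
      geneA = geneA, geneB = geneB,
      chrom_pair = ci, block = block_of,
      orientation = ifelse(block_rev[block_of], "reverse", "forward"),
      stringsAsFactors = FALSE)
  }

  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(gene_id = character(0), source_gene = character(0))

  truth <- plant_expression_truth(pairs, annotation, decoys, config)

  genome <- Biostrings::DNAStringSet(vapply(
    split(annotation, annotation$chrom),
    function(df) random_dna(max(df$end) + 500L), character(1)))

  list(annotation = annotation, genome = genome, truth = truth)
}

interleave_noise <- function(core, noise) {
  if (!length(noise)) return(core)
  out <- character(length(core) + length(noise))
  pos <- sort(sample(length(out), length(noise)))
  out[pos] <- noise
  out[-pos] <- core
  out
}

chrom_annotation <- function(gene_order, chrom, hap, ci, slot, gene_len,
                             promoter_length) {
  r <- seq_along(gene_order) - 1L
  start <- r * slot + promoter_length + 1L
  role <- ifelse(grepl("W\\d+", gene_order), "wgd_decoy",
                 ifelse(grepl("N\\d+", gene_order), "noise", "paired"))
  data.frame(gene_id = gene_order, chrom = chrom, start = start,
             end = start + gene_len - 1L, strand = "+", haplotype = hap,
             chrom_pair = ci, rank = r, role = role, stringsAsFactors = FALSE)
}

## Assign bias categories, per-tissue dynamics, baseline means and Ka/Ks
## targets to the planted pairs.
plant_expression_truth <- function(pairs, annotation, decoys, config) {
  n <- nrow(pairs)
  cats <- c("none", "smaller", "larger", "largest")
  base_cat <- sample(cats, n, replace = TRUE, prob = config$bias_category_mix)
  direction <- sample(c(1, -1), n, replace = TRUE)

  tissues <- config$tissues
  nt <- length(tissues)
  cat_idx <- matrix(match(base_cat, cats), n, nt)
  ## per-tissue category wander for biased loci: mostly stay, sometimes step
  ## to a neighbouring bias level, rarely jump two levels
  jump_rate <- config$transition_rate / 10
  for (t in seq_len(nt)) {
    biased <- cat_idx[, t] > 1L
    u <- runif(n)
    step <- ifelse(u < jump_rate, 2L, ifelse(u < jump_rate + config$transition_rate, 1L, 0L))
    step[!biased] <- 0L
    dirn <- sample(c(-1L, 1L), n, replace = TRUE)
    prop <- cat_idx[, t] + step * dirn
    prop <- pmin(pmax(prop, 2L), 4L)   # biased loci stay within bias levels
    cat_idx[biased, t] <- prop[biased]
  }
  category_tissue <- matrix(cats[cat_idx], n, nt,
                            dimnames = list(pairs$locus_id, tissues))

  ## fold changes per category band; one draw per locus per band
  fc_band <- cbind(none = rep(1, n),
                   smaller = runif(n, 1.3, 2.0),
                   larger = runif(n, 2.5, 7.0),
                   largest = runif(n, 8.0, 16.0))
  fc_tissue <- matrix(fc_band[cbind(rep(seq_len(n), nt), as.vector(cat_idx))],
                      n, nt, dimnames = dimnames(category_tissue))

  base_mean <- rlnorm(nrow(annotation), config$base_log_mean, config$base_log_sd)
  names(base_mean) <- annotation$gene_id

  ## latent expression programs: multiplicative tissue profiles shared by
  ## both alleles of a locus, giving the count matrix a real coexpression
  ## structure (tissue-patterned modules) on top of the allelic bias
  n_programs <- 5L
  program_profile <- matrix(exp(rnorm(n_programs * nt, 0, 0.8)),
                            n_programs, nt,
                            dimnames = list(NULL, tissues))
  locus_program <- sample.int(n_programs, n, replace = TRUE)
  gene_program <- setNames(sample.int(n_programs, nrow(annotation),
                                      replace = TRUE), annotation$gene_id)
  gene_program[pairs$geneA] <- locus_program
  gene_program[pairs$geneB] <- locus_program

  grid <- config$kaks_grid
  if (is.null(names(grid))) names(grid) <- cats[seq_along(grid)]
  kk <- t(vapply(base_cat, function(cc)
    grid[[cc]] %||% grid[[1L]], numeric(2)))
  planted_kaks <- data.frame(locus_id = pairs$locus_id,
                             ka = kk[, 1], ks = kk[, 2],
                             stringsAsFactors = FALSE)

  unpaired <- annotation$gene_id[annotation$role == "noise"]

  truth <- list(pairs = cbind(pairs, category = base_cat,
                              direction = direction),
                category_tissue = category_tissue,
                fc_tissue = fc_tissue,
                base_mean = base_mean,
                program_profile = program_profile,
                gene_program = gene_program,
                planted_kaks = planted_kaks,
                decoys = decoys,
                decoy_kaks = c(ka = 0.10, ks = 0.35),
                unpaired = unpaired,
                gene_length = setNames(annotation$end - annotation$start + 1L,
                                       annotation$gene_id),
                gene_coords = data.frame(chrom = annotation$chrom,
                                         start = annotation$start,
                                         end = annotation$end,
                                         row.names = annotation$gene_id,
                                         stringsAsFactors = FALSE),
                tissues = tissues)
  class(truth) <- "truth_table"
  truth
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Planted truth: %d allele pairs, %d unpaired genes, %d decoys\n",
              nrow(x$pairs), length(x$unpaired), nrow(x$decoys)))
  print(table(x$pairs$category))
  invisible(x)
}
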