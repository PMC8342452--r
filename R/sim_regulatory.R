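#' Generate a synthetic motif set
#'
#' Random high-information PWMs (dominant base probability 0.85-0.95 per
#' column), suitable for planting exact-consensus occurrences that a scanner
#' at p < 1e-5 must recover.
#'
#' @param n_motifs number of motifs.
#' @param length_range integer range of motif lengths.
#' @param seed integer seed.
#' @return list of [pwm()] objects.
#' @export
generate_motif_set <- function(n_motifs = 10L, length_range = c(8L, 12L),
                               seed = 1L) {
  set.seed(child_seed(seed, "motifs"))
  lapply(seq_len(n_motifs), function(i) {
    L <- sample(length_range[1]:length_range[2], 1L)
    cons <- sample(BASES, L, replace = TRUE)
    mat <- sapply(seq_len(L), function(j) {
      p <- runif(1, 0.85, 0.95)
      rest <- runif(3); rest <- (1 - p) * rest / sum(rest)
      v <- numeric(4); names(v) <- BASES
      v[cons[j]] <- p
      v[setdiff(BASES, cons[j])] <- rest
      v
    })
    rownames(mat) <- BASES
    pwm(sprintf("M%03d", i), mat)
  })
}

#' Plant motif occurrences in promoters and TEs near genes
#'
#' Builds a 2-kb (configurable) promoter for every annotated gene from
#' i.i.d. background sequence, inserts exact-consensus motif occurrences at
#' recorded, non-overlapping offsets, and places one TE interval at a
#' planted distance downstream of each allele-pair gene. Shared motif
#' content is higher and specific content lower for weakly biased loci, and
#' TEs sit nearer to strongly biased loci, reproducing the directional
#' regulatory contrasts the downstream comparisons test for.
#'
#' @param truth a `truth_table`.
#' @param config the matching [sim_config()].
#' @param motifs optional motif set (list of [pwm()]); generated from the
#'   config seed when `NULL`.
#' @return list with `promoters` (named character vector), `te` (BED-style
#'   data.frame: chrom, start, end, te_id; 0-based half-open), `motifs`,
#'   and the updated `truth` (planted motif counts and TE distances).
#' @export
plant_regulatory_context <- function(truth, config, motifs = NULL) {
  set.seed(child_seed(config$seed, "regulatory"))
  if (is.null(motifs)) motifs <- generate_motif_set(seed = config$seed)
  plen <- config$promoter_length
  if (any(vapply(motifs, function(m) ncol(m$mat), integer(1)) > plen))
    stop("motif longer than promoter")
  motif_ids <- vapply(motifs, function(m) m$motif_id, character(1))
  consensus <- vapply(motifs, pwm_consensus, character(1))
  names(consensus) <- motif_ids

  genes <- names(truth$gene_length)
  promoters <- vapply(seq_along(genes), function(i) random_dna(plen),
                      character(1))
  names(promoters) <- genes

  ## planted motif content by bias category
  shared_mean <- c(none = 5, smaller = 4, larger = 3, largest = 2)
  spec_mean   <- c(none = 0.3, smaller = 0.7, larger = 1.5, largest = 3)
  counts <- list(); offsets <- list()
  pr <- truth$pairs
  for (i in seq_len(nrow(pr))) {
    cc <- pr$category[i]
    shared <- draw_motif_counts(shared_mean[[cc]], motif_ids)
    specA <- draw_motif_counts(spec_mean[[cc]], motif_ids)
    specB <- draw_motif_counts(spec_mean[[cc]], motif_ids)
    for (gene_side in list(c(pr$geneA[i], "A"), c(pr$geneB[i], "B"))) {
      g <- gene_side[1]
      tot <- shared + (if (gene_side[2] == "A") specA else specB)
      ins <- insert_motifs(promoters[[g]], tot, consensus)
      promoters[[g]] <- ins$seq
      counts[[g]] <- tot[tot > 0]
      offsets[[g]] <- ins$offsets
    }
  }

  ## TE placement: distance drawn from the grid with category-dependent bias
  grid <- sort(config$te_distance_grid)
  gw <- seq_along(grid)
  wts <- list(none = gw^1.5, smaller = gw^0.5, larger = gw^-0.5,
              largest = gw^-1.5)
  ann_end <- truth$gene_length   # gene end offset = start + len; use coords
  te <- list(); te_planted <- numeric(0)
  pair_genes <- c(pr$geneA, pr$geneB)
  pair_cat <- c(pr$category, pr$category)
  gene_tab <- truth$gene_coords
  for (j in seq_along(pair_genes)) {
    g <- pair_genes[j]
    d <- sample(grid, 1L, prob = wts[[pair_cat[j]]])
    te_planted[[g]] <- d
    crd <- gene_tab[g, ]
    te[[j]] <- data.frame(chrom = crd$chrom, start = crd$end + d,
                          end = crd$end + d + 500L,
                          te_id = sprintf("TE%05d", j),
                          stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, te)

  truth$motif_counts <- counts
  truth$motif_offsets <- offsets
  truth$te_distance <- te_planted
  truth$motifs <- motifs
  list(promoters = promoters, te = te, motifs = motifs, truth = truth)
}

draw_motif_counts <- function(mean_total, motif_ids) {
  total <- stats::rpois(1, mean_total)
  v <- setNames(integer(length(motif_ids)), motif_ids)
  if (total > 0) {
    pick <- table(sample(motif_ids, total, replace = TRUE))
    v[names(pick)] <- as.integer(pick)
  }
  v
}

## Insert `counts[m]` copies of each motif consensus at random
## non-overlapping offsets; returns updated sequence and a data.frame of
## recorded insertions (0-based offsets).
insert_motifs <- function(seqn, counts, consensus) {
  plen <- nchar(seqn)
  placed <- data.frame(motif_id = character(0), offset = integer(0))
  occupied <- logical(plen)
  for (m in names(counts)) {
    k <- counts[[m]]
    if (k == 0) next
    cons <- consensus[[m]]
    L <- nchar(cons)
    for (r in seq_len(k)) {
      for (att in 1:200) {
        off <- sample.int(plen - L + 1L, 1L) - 1L
        span <- (off + 1L):(off + L)
        if (!any(occupied[span])) {
          substr(seqn, off + 1L, off + L) <- cons
          occupied[span] <- TRUE
          placed <- rbind(placed, data.frame(motif_id = m, offset = off,
                                             stringsAsFactors = FALSE))
          break
        }
      }
    }
  }
  list(seq = seqn, offsets = placed)
}
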