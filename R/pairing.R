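## Allele pairing: homology matching, collinear-block chaining, WGD-block
## filtering, pair extraction.

#' Build a homology match table from translated k-mer similarity
#'
#' Scores candidate gene matches between the two haplotypes by Jaccard
#' similarity of amino-acid k-mer sets of the translated CDS (k = 5 by
#' default), keeping the `top_k` best candidates per gene from either side.
#' A light-weight, deterministic stand-in for protein alignment that keeps
#' the pipeline self-contained; a precomputed match table can be supplied
#' instead wherever one is accepted.
#'
#' @param cds_A,cds_B named character vectors (or `DNAStringSet`s) of CDS,
#'   one per gene of haplotype A / B.
#' @param top_k candidates kept per gene.
#' @param k amino-acid k-mer length.
#' @param min_similarity candidates below this Jaccard similarity are
#'   dropped (random-sequence collisions score well below 0.1).
#' @return data.frame (geneA, geneB, score) sorted by (score desc, geneA,
#'   geneB); attribute `n_skipped` counts untranslatable inputs.
#' @export
build_match_table <- function(cds_A, cds_B, top_k = 3L, k = 5L,
                              min_similarity = 0.1) {
  setA <- protein_kmer_sets(setNames(as.character(cds_A), names(cds_A)), k)
  setB <- protein_kmer_sets(setNames(as.character(cds_B), names(cds_B)), k)
  n_skipped <- attr(setA, "n_skipped") + attr(setB, "n_skipped")
  if (n_skipped > 0)
    warning(n_skipped, " sequence(s) not translatable; skipped")
  if (!length(setA) || !length(setB))
    return(structure(data.frame(geneA = character(0), geneB = character(0),
                                score = numeric(0)), n_skipped = n_skipped))

  ## inverted index of B k-mers -> integer gene indices
  nB <- length(setB)
  idx <- split(rep(seq_len(nB), lengths(setB)),
               unlist(setB, use.names = FALSE))
  sizeB <- lengths(setB)
  namesB <- names(setB)

  rows <- lapply(names(setA), function(ga) {
    ka <- setA[[ga]]
    hits <- unlist(idx[ka], use.names = FALSE)
    if (is.null(hits) || !length(hits)) return(NULL)
    shared <- tabulate(hits, nbins = nB)
    cand <- which(shared > 0)
    jac <- shared[cand] / (length(ka) + sizeB[cand] - shared[cand])
    pass <- jac >= min_similarity
    cand <- cand[pass]; jac <- jac[pass]
    if (!length(cand)) return(NULL)
    ord <- order(-jac, namesB[cand])
    keep <- ord[seq_len(min(top_k, length(ord)))]
    data.frame(geneA = ga, geneB = namesB[cand[keep]], score = jac[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(geneA = character(0), geneB = character(0),
                      score = numeric(0))
  ## symmetrize: keep rows that are top_k for their geneA or their geneB
  if (nrow(out)) {
    out <- out[order(-out$score, out$geneA, out$geneB), ]
    keepB <- unlist(lapply(split(seq_len(nrow(out)), out$geneB), function(ix)
      ix[seq_len(min(top_k, length(ix)))]), use.names = FALSE)
    keepA <- unlist(lapply(split(seq_len(nrow(out)), out$geneA), function(ix)
      ix[seq_len(min(top_k, length(ix)))]), use.names = FALSE)
    out <- out[sort(unique(c(keepA, keepB))), ]
    out <- out[order(-out$score, out$geneA, out$geneB), ]
    rownames(out) <- NULL
  }
  structure(out, n_skipped = n_skipped)
}

protein_kmer_sets <- function(cds, k) {
  ok <- nchar(cds) %% 3L == 0L
  prots <- character(length(cds))
  if (any(ok))
    prots[ok] <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[ok]), if.fuzzy.codon = "X")))
  ok <- ok & nchar(prots) >= k
  sets <- lapply(which(ok), function(i) {
    p <- prots[i]
    unique(substring(p, 1:(nchar(p) - k + 1L), k:nchar(p)))
  })
  names(sets) <- names(cds)[ok]
  attr(sets, "n_skipped") <- sum(!ok)
  sets
}

#' Attach chromosome and gene-order ranks to a match table
#'
#' @param matches data.frame (geneA, geneB, score).
#' @param annotation annotation data.frame with gene_id, chrom, rank.
#' @return the match table with chromA, chromB, rankA, rankB columns.
#' @export
attach_ranks <- function(matches, annotation) {
  ia <- match(matches$geneA, annotation$gene_id)
  ib <- match(matches$geneB, annotation$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("match table contains unannotated genes")
  matches$chromA <- annotation$chrom[ia]
  matches$chromB <- annotation$chrom[ib]
  matches$rankA <- annotation$rank[ia]
  matches$rankB <- annotation$rank[ib]
  matches
}

#' Chain matches into collinear blocks
#'
#' Dynamic-programming chaining over gene-rank space, run per chromosome
#' pair and in both orientations. Anchors in a block are strictly increasing
#' in rankA and strictly monotone in rankB (increasing for forward blocks,
#' decreasing for reverse), with rank gaps of at most `max_gap` on both
#' sides between consecutive anchors. Chains are extracted greedily by
#' score; chains shorter than `min_block_size` are discarded. Defaults
#' mirror common collinearity-scanner settings (5 anchors, gap 25).
#'
#' @param matches match table with rank columns (see [attach_ranks()]).
#' @param min_block_size minimum anchors per block.
#' @param max_gap maximum rank gap between consecutive anchors.
#' @return list of `collinear_block` objects (fields: block_id, chromA,
#'   chromB, orientation, score, anchors data.frame).
#' @export
chain_collinear_blocks <- function(matches, min_block_size = 5L,
                                   max_gap = 25L) {
  if (!nrow(matches)) return(list())
  need <- c("geneA", "geneB", "score", "chromA", "chromB", "rankA", "rankB")
  stopifnot(all(need %in% names(matches)))
  blocks <- list()
  for (key in sort(unique(paste(matches$chromA, matches$chromB)))) {
    sub <- matches[paste(matches$chromA, matches$chromB) == key, , drop = FALSE]
    for (orient in c("forward", "reverse")) {
      m <- sub
      m$rb <- if (orient == "forward") m$rankB else -m$rankB
      chains <- extract_chains(m, min_block_size, max_gap)
      for (ch in chains) {
        anchors <- ch[order(ch$rankA), c("geneA", "geneB", "rankA", "rankB",
                                         "score")]
        rownames(anchors) <- NULL
        blocks[[length(blocks) + 1L]] <- structure(
          list(block_id = NA_character_, chromA = sub$chromA[1],
               chromB = sub$chromB[1], orientation = orient,
               score = sum(anchors$score), anchors = anchors),
          class = "collinear_block")
      }
    }
  }
  ## resolve cross-orientation match reuse: greedy by score; a lower-scoring
  ## block loses its already-claimed anchors and survives only if it still
  ## meets min_block_size
  if (length(blocks) > 1L) {
    ord <- order(-vapply(blocks, `[[`, numeric(1), "score"),
                 vapply(blocks, function(b) b$anchors$geneA[1], character(1)))
    used <- character(0); kept <- list()
    for (b in blocks[ord]) {
      keyset <- paste(b$anchors$geneA, b$anchors$geneB)
      fresh <- !(keyset %in% used)
      if (sum(fresh) >= min_block_size) {
        b$anchors <- b$anchors[fresh, , drop = FALSE]
        b$score <- sum(b$anchors$score)
        used <- c(used, keyset[fresh])
        kept[[length(kept) + 1L]] <- b
      }
    }
    blocks <- kept
  }
  ## deterministic ids ordered by location
  if (length(blocks)) {
    ord <- order(vapply(blocks, `[[`, character(1), "chromA"),
                 vapply(blocks, function(b) min(b$anchors$rankA), numeric(1)),
                 vapply(blocks, `[[`, character(1), "chromB"))
    blocks <- blocks[ord]
    for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("B%04d", i)
  }
  blocks
}

## Repeated weighted-chain extraction on one chromosome pair/orientation.
extract_chains <- function(m, min_block_size, max_gap) {
  m <- m[order(m$rankA, m$rb, m$geneB), , drop = FALSE]
  chains <- list()
  repeat {
    n <- nrow(m)
    if (n < min_block_size) break
    dp <- m$score; prev <- rep(NA_integer_, n); len <- rep(1L, n)
    for (i in seq_len(n)) {
      cand <- which(m$rankA < m$rankA[i] & m$rb < m$rb[i] &
                    m$rankA[i] - m$rankA <= max_gap &
                    m$rb[i] - m$rb <= max_gap)
      if (length(cand)) {
        j <- cand[which.max(dp[cand])]
        dp[i] <- dp[i] + dp[j]; prev[i] <- j; len[i] <- len[j] + 1L
      }
    }
    best <- which.max(dp)
    if (len[best] < min_block_size) break
    path <- integer(0); cur <- best
    while (!is.na(cur)) { path <- c(cur, path); cur <- prev[cur] }
    chains[[length(chains) + 1L]] <- m[path, , drop = FALSE]
    m <- m[-path, , drop = FALSE]
  }
  chains
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("Collinear block %s: %s ~ %s (%s), %d anchors, score %.3f\n",
              x$block_id %||% "?", x$chromA, x$chromB, x$orientation,
              nrow(x$anchors), x$score))
  invisible(x)
}

#' Collapse a block list into an anchors data.frame
#' @param blocks list of `collinear_block`.
#' @return data.frame with one row per anchor.
#' @export
blocks_to_df <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block_id = character(0), chromA = character(0),
                      chromB = character(0), orientation = character(0),
                      geneA = character(0), geneB = character(0),
                      rankA = integer(0), rankB = integer(0),
                      score = numeric(0)))
  do.call(rbind, lapply(blocks, function(b)
    cbind(data.frame(block_id = b$block_id, chromA = b$chromA,
                     chromB = b$chromB, orientation = b$orientation,
                     stringsAsFactors = FALSE), b$anchors)))
}

#' Remove collinear blocks that likely arise from whole-genome duplication
#'
#' Allelic blocks between haplotypes of one individual show near-zero
#' synonymous divergence, whereas blocks pairing paralogous regions retain
#' the WGD-age Ks. Two rules operationalize the removal: (i) a block whose
#' median anchor Ks exceeds `ks_ceiling` is dropped; (ii) where two blocks
#' claim overlapping rank ranges on a shared chromosome, only the block with
#' the lower median Ks is kept as allelic.
#'
#' @param blocks list of `collinear_block`.
#' @param ks_per_pair data.frame (geneA, geneB, ks) or named vector keyed
#'   `"geneA|geneB"`.
#' @param ks_ceiling maximum allelic median Ks (default 0.15, well below a
#'   WGD peak near 0.3).
#' @return filtered block list, each block annotated with `median_ks`.
#' @export
filter_wgd_blocks <- function(blocks, ks_per_pair, ks_ceiling = 0.15) {
  if (!length(blocks)) return(blocks)
  ksmap <- if (is.data.frame(ks_per_pair))
    setNames(ks_per_pair$ks, paste(ks_per_pair$geneA, ks_per_pair$geneB,
                                   sep = "|"))
  else ks_per_pair
  for (i in seq_along(blocks)) {
    kk <- ksmap[paste(blocks[[i]]$anchors$geneA, blocks[[i]]$anchors$geneB,
                      sep = "|")]
    blocks[[i]]$median_ks <- median(kk, na.rm = TRUE)
  }
  keep <- vapply(blocks, function(b)
    !is.na(b$median_ks) && b$median_ks <= ks_ceiling, logical(1))
  blocks <- blocks[keep]
  if (length(blocks) > 1L) {
    drop <- rep(FALSE, length(blocks))
    ranks <- function(b, side)
      if (side == "A") b$anchors$rankA else b$anchors$rankB
    for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
      if (i >= j || drop[i] || drop[j]) next
      for (side in c("A", "B")) {
        ch_i <- if (side == "A") blocks[[i]]$chromA else blocks[[i]]$chromB
        ch_j <- if (side == "A") blocks[[j]]$chromA else blocks[[j]]$chromB
        if (ch_i != ch_j) next
        ri <- ranks(blocks[[i]], side); rj <- ranks(blocks[[j]], side)
        shared <- length(intersect(ri, rj))
        ## blocks claim the same region when most of the smaller block's
        ## anchor positions are also claimed by the other block
        if (shared > 0.5 * min(length(ri), length(rj))) {
          if (blocks[[i]]$median_ks <= blocks[[j]]$median_ks)
            drop[j] <- TRUE else drop[i] <- TRUE
        }
      }
    }
    blocks <- blocks[!drop]
  }
  blocks
}

#' Extract allele pairs from filtered collinear blocks
#'
#' One pair per anchor; a gene claimed by several blocks is assigned to the
#' highest-scoring block (ties broken by block id). Locus ids are sequential
#' in (chromA, rankA) order.
#'
#' @param blocks list of `collinear_block` (after filtering).
#' @return data.frame (locus_id, geneA, geneB, block_id).
#' @export
extract_allele_pairs <- function(blocks) {
  df <- blocks_to_df(blocks)
  if (!nrow(df))
    return(data.frame(locus_id = character(0), geneA = character(0),
                      geneB = character(0), block_id = character(0)))
  bscore <- setNames(vapply(blocks, `[[`, numeric(1), "score"),
                     vapply(blocks, `[[`, character(1), "block_id"))
  df <- df[order(-bscore[df$block_id], df$block_id, df$rankA), ]
  df <- df[!duplicated(df$geneA) & !duplicated(df$geneB), ]
  df <- df[order(df$chromA, df$rankA, df$geneB), ]
  data.frame(locus_id = sprintf("L%05d", seq_len(nrow(df))),
             geneA = df$geneA, geneB = df$geneB, block_id = df$block_id,
             stringsAsFactors = FALSE)
}
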