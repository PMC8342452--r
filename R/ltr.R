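## LTR-RT lifecycle: classification, family clustering, removal-rate stats.

#' Classification thresholds for LTR-RT records
#'
#' Defaults follow the quoted screening rules: a library hit requires
#' E-value < 1e-10, overlap > 90% and identity > 90%; flanking Gag-Pol
#' evidence (within 15 kb) requires coverage >= 50% and identity >= 30% at
#' E-value < 1e-8.
#'
#' @param lib_evalue,lib_overlap,lib_identity library-hit thresholds.
#' @param flank_coverage,flank_identity,flank_evalue flanking Gag-Pol
#'   thresholds.
#' @return named list of thresholds.
#' @export
ltr_thresholds <- function(lib_evalue = 1e-10, lib_overlap = 0.90,
                           lib_identity = 0.90, flank_coverage = 0.50,
                           flank_identity = 0.30, flank_evalue = 1e-8) {
  list(lib_evalue = lib_evalue, lib_overlap = lib_overlap,
       lib_identity = lib_identity, flank_coverage = flank_coverage,
       flank_identity = flank_identity, flank_evalue = flank_evalue)
}

#' Classify LTR-RT records as intact, solo or truncated
#'
#' A record with a complete Gag-Pol is `intact`. Otherwise it must show a
#' passing similarity hit to the intact library (strictly better than the
#' E-value/overlap/identity thresholds) to be considered at all; among
#' passing records, those with qualifying flanking Gag-Pol evidence on at
#' least one side are `truncated`, those without any flanking Gag-Pol are
#' `solo`. Records failing the library screen, or with missing evidence,
#' are `unclassified`.
#'
#' @param records data.frame with columns gagpol_complete, lib_evalue,
#'   lib_overlap, lib_identity, flank_coverage, flank_identity,
#'   flank_evalue.
#' @param thresholds a [ltr_thresholds()] list.
#' @return character vector of classes.
#' @export
classify_ltr <- function(records, thresholds = ltr_thresholds()) {
  th <- thresholds
  n <- nrow(records)
  out <- rep("unclassified", n)
  intact <- !is.na(records$gagpol_complete) & records$gagpol_complete
  out[intact] <- "intact"

  lib_pass <- !is.na(records$lib_evalue) & !is.na(records$lib_overlap) &
    !is.na(records$lib_identity) &
    records$lib_evalue < th$lib_evalue &
    records$lib_overlap > th$lib_overlap &
    records$lib_identity > th$lib_identity

  flank_pass <- !is.na(records$flank_coverage) &
    !is.na(records$flank_identity) & !is.na(records$flank_evalue) &
    records$flank_coverage >= th$flank_coverage &
    records$flank_identity >= th$flank_identity &
    records$flank_evalue < th$flank_evalue

  out[!intact & lib_pass & flank_pass] <- "truncated"
  out[!intact & lib_pass & !flank_pass] <- "solo"
  out
}

#' Cluster LTR sequences into families
#'
#' Two LTRs belong to the same cluster when each covers at least
#' `min_coverage` (default 70%) of the other's length and their aligned
#' identity is at least `min_identity` (default 60%); clusters are the
#' single-linkage connected components of this pass/fail graph. Solo and
#' truncated records are then attached to the cluster of their most
#' similar intact 5'-LTR. Pairwise similarity uses a local alignment
#' (match +1 / mismatch -1, affine gaps), or a precomputed pair table.
#'
#' @param ltr5 named character vector of 5'-LTR sequences.
#' @param classes optional class per record (same names); when supplied,
#'   only intact records seed the graph and others are attached.
#' @param min_coverage,min_identity cluster admission thresholds.
#' @param pair_table optional precomputed data.frame (id1, id2, coverage1,
#'   coverage2, identity) replacing the built-in alignment.
#' @return named integer cluster ids.
#' @export
cluster_ltrs <- function(ltr5, classes = NULL, min_coverage = 0.70,
                         min_identity = 0.60, pair_table = NULL) {
  ids <- names(ltr5)
  stopifnot(!is.null(ids))
  seed_ids <- if (is.null(classes)) ids else ids[classes[ids] == "intact"]
  other_ids <- setdiff(ids, seed_ids)

  sim_vs <- function(query_id, target_ids) {
    if (!is.null(pair_table)) {
      return(t(vapply(target_ids, function(j) {
        row <- pair_table[(pair_table$id1 == query_id & pair_table$id2 == j) |
                          (pair_table$id1 == j & pair_table$id2 == query_id), ]
        if (!nrow(row)) c(0, 0, 0)
        else c(row$coverage1[1], row$coverage2[1], row$identity[1])
      }, numeric(3))))
    }
    ltr_similarity_batch(ltr5[[query_id]], ltr5[target_ids])
  }

  ## single-linkage components over passing pairs (union-find)
  parent <- seq_along(seed_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(seed_ids) > 1L) {
    for (i in seq_len(length(seed_ids) - 1L)) {
      s <- sim_vs(seed_ids[i], seed_ids[(i + 1L):length(seed_ids)])
      pass <- pmin(s[, 1], s[, 2]) >= min_coverage & s[, 3] >= min_identity
      for (j in which(pass) + i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(seed_ids), find, integer(1))
  comp <- match(roots, sort(unique(roots)))
  clusters <- setNames(comp, seed_ids)

  ## attach non-intact records to the most similar intact 5'-LTR's cluster
  for (oid in other_ids) {
    if (!length(seed_ids)) { clusters[oid] <- NA_integer_; next }
    sims <- sim_vs(oid, seed_ids)[, 3]
    clusters[oid] <- comp[which.max(sims)]
  }
  clusters[ids]
}

## coverage of each sequence and identity from local alignments of one
## query against many targets (vectorized over targets)
ltr_similarity_batch <- function(query, targets) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(rep(query, length(targets))),
    Biostrings::DNAStringSet(unname(targets)), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  w <- Biostrings::width(Biostrings::pattern(aln))
  ident <- ifelse(w > 0, Biostrings::nmatch(aln) / w, 0)
  cbind(w / nchar(query), w / nchar(targets), ident)
}

## one-pair convenience wrapper
ltr_pair_similarity <- function(s1, s2) {
  as.numeric(ltr_similarity_batch(s1, s2))
}

#' Lifecycle ratios of LTR-RT classes
#'
#' Genome-wide and per-cluster counts of intact (I), solo (S) and
#' truncated (T) elements with the removal-rate ratios S:I, T:I and
#' (S+T):I, and the fraction of clusters with S:I > 3 (clusters without
#' intact members are excluded from that fraction's denominator and their
#' ratios reported as missing).
#'
#' @param classes character vector of classes per record.
#' @param clusters optional cluster id per record.
#' @return list of class `ltr_stats`: counts, ratios, per_cluster,
#'   fraction_clusters_SI_gt3.
#' @export
lifecycle_ratios <- function(classes, clusters = NULL) {
  cnt <- function(cl) c(I = sum(cl == "intact"), S = sum(cl == "solo"),
                        T = sum(cl == "truncated"),
                        unclassified = sum(cl == "unclassified"))
  tot <- cnt(classes)
  ratios <- c(SI = unname(if (tot["I"] > 0) tot["S"] / tot["I"] else NA),
              TI = unname(if (tot["I"] > 0) tot["T"] / tot["I"] else NA),
              STI = unname(if (tot["I"] > 0)
                (tot["S"] + tot["T"]) / tot["I"] else NA))
  per_cluster <- NULL; frac <- NA_real_
  if (!is.null(clusters)) {
    per_cluster <- do.call(rbind, lapply(
      sort(unique(clusters[!is.na(clusters)])), function(cid) {
        cc <- cnt(classes[!is.na(clusters) & clusters == cid])
        data.frame(cluster = cid, I = cc["I"], S = cc["S"], T = cc["T"],
                   SI = if (cc["I"] > 0) cc["S"] / cc["I"] else NA_real_,
                   TI = if (cc["I"] > 0) cc["T"] / cc["I"] else NA_real_,
                   row.names = NULL)
      }))
    with_I <- per_cluster[!is.na(per_cluster$SI), , drop = FALSE]
    if (nrow(with_I)) frac <- mean(with_I$SI > 3)
  }
  structure(list(counts = tot, ratios = ratios, per_cluster = per_cluster,
                 fraction_clusters_SI_gt3 = frac), class = "ltr_stats")
}

#' @export
print.ltr_stats <- function(x, ...) {
  cat(sprintf("LTR lifecycle: I=%d S=%d T=%d (unclassified %d)\n",
              x$counts["I"], x$counts["S"], x$counts["T"],
              x$counts["unclassified"]))
  cat(sprintf("  S:I = %.2f, T:I = %.2f, (S+T):I = %.2f\n",
              x$ratios["SI"], x$ratios["TI"], x$ratios["STI"]))
  if (!is.na(x$fraction_clusters_SI_gt3))
    cat(sprintf("  clusters with S:I > 3: %.1f%%\n",
                100 * x$fraction_clusters_SI_gt3))
  invisible(x)
}

#' Insertion ages for intact LTR records
#'
#' JC69-corrected divergence between the 5' and 3' LTR of each intact
#' record converted to years at rate `mu`.
#'
#' @param records LTR record table with ltr5_seq/ltr3_seq columns.
#' @param classes classes per record.
#' @param mu substitution rate per site per year.
#' @return numeric vector of ages (NA for non-intact records).
#' @export
ltr_ages <- function(records, classes, mu = 1.3e-8) {
  vapply(seq_len(nrow(records)), function(i) {
    if (classes[i] != "intact" || is.na(records$ltr3_seq[i])) return(NA_real_)
    d <- pairwise_jc_distance(records$ltr5_seq[i], records$ltr3_seq[i])
    ltr_insertion_time(d, mu)
  }, numeric(1))
}
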