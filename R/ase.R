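## Allelic expression bias: TPM, expressed filter, per-tissue NB Wald test,
## four-level category classification, dynamic/stable ranking, transitions.

#' Transcripts-per-million normalization
#'
#' TPM_g = (c_g / l_g) / sum_j (c_j / l_j) * 1e6 per sample; every column of
#' the result sums to 1e6 (all-zero samples stay all-zero, with a warning).
#'
#' @param counts integer matrix genes x samples.
#' @param lengths gene lengths in bp (recycled by name when named).
#' @return numeric TPM matrix with the dimensions of `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0) || anyNA(lengths)) stop("gene lengths must be > 0")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s); TPM left at zero")
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene is expressed when its TPM strictly exceeds `threshold` in at least
#' one sample (default 0.5 TPM).
#'
#' @param tpm TPM matrix.
#' @param threshold expression threshold.
#' @return character vector of expressed gene ids (or logical vector when
#'   `tpm` has no rownames).
#' @export
filter_expressed <- function(tpm, threshold = 0.5) {
  keep <- apply(tpm, 1, max) > threshold
  if (is.null(rownames(tpm))) keep else rownames(tpm)[keep]
}

#' Median-of-ratios library size factors
#'
#' @param counts integer matrix genes x samples.
#' @return numeric vector of per-sample size factors (geometric-mean
#'   reference, median ratio), normalized to geometric mean 1.
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(cc)
    exp(median(log(cc) - logg[use], na.rm = TRUE)))
  sf / exp(mean(log(sf)))
}

#' Per-tissue allelic differential-expression test
#'
#' Negative-binomial Wald test of allele A against allele B within one
#' tissue. Counts are divided by library size factors; a pseudo-mean of 0.5
#' is added to both allele means; the common dispersion is estimated by
#' pooled method of moments across all loci in the tissue (floored at
#' 1e-8); the log fold change variance follows from the delta method,
#' var(log mu_hat) ~ (1/mu + alpha) / n, and the two-sided Wald p-value
#' uses the normal reference (the pooled dispersion is shared across
#' thousands of loci and treated as known).
#'
#' @param countsA,countsB integer matrices (loci x replicates) of the two
#'   alleles' counts in one tissue, rows aligned by locus.
#' @param sfA,sfB size factors for the replicate columns (default 1).
#' @return data.frame (log2fc, p, baseMeanA, baseMeanB, dispersion) with one
#'   row per locus; loci with fewer than 2 replicates on either side get NA
#'   p-values.
#' @export
test_allelic_bias <- function(countsA, countsB, sfA = NULL, sfB = NULL) {
  countsA <- rbind(countsA); countsB <- rbind(countsB)
  stopifnot(nrow(countsA) == nrow(countsB))
  nA <- ncol(countsA); nB <- ncol(countsB)
  if (is.null(sfA)) sfA <- rep(1, nA)
  if (is.null(sfB)) sfB <- rep(1, nB)
  qA <- sweep(countsA, 2, sfA, "/")
  qB <- sweep(countsB, 2, sfB, "/")

  mA <- rowMeans(qA); mB <- rowMeans(qB)
  vA <- apply(qA, 1, var); vB <- apply(qB, 1, var)
  ## pooled method-of-moments dispersion over all loci and both alleles:
  ## E[s^2 - m] = alpha mu^2, with E[m^2] corrected by s^2/n
  num <- sum(vA - mA, vB - mB, na.rm = TRUE)
  den <- sum(mA^2 - vA / nA, mB^2 - vB / nB, na.rm = TRUE)
  alpha <- max(ifelse(den > 0, num / den, 0), 1e-8)

  muA <- mA + 0.5; muB <- mB + 0.5
  log2fc <- log2(muA / muB)
  se_ln <- sqrt((1 / muA + alpha) / nA + (1 / muB + alpha) / nB)
  zstat <- log(muA / muB) / se_ln
  p <- 2 * pnorm(-abs(zstat))
  p[zstat == 0] <- 1
  if (nA < 2L || nB < 2L) p[] <- NA_real_
  data.frame(log2fc = log2fc, p = p, baseMeanA = muA, baseMeanB = muB,
             dispersion = alpha)
}

#' Four-level allelic bias category
#'
#' `none` when the BH-adjusted p-value is >= 0.05; otherwise the absolute
#' fold change FC = 2^|log2fc| decides: `smaller` for FC <= 2, `larger` for
#' 2 < FC < 8, `largest` for FC >= 8.
#'
#' @param log2fc signed log2 fold change.
#' @param p_adj BH-adjusted p-value (adjusted within tissue).
#' @param alpha significance level.
#' @return character vector of categories.
#' @export
classify_bias <- function(log2fc, p_adj, alpha = 0.05) {
  fc <- 2^abs(log2fc)
  out <- ifelse(is.na(p_adj) | p_adj >= alpha, "none",
                ifelse(fc <= 2, "smaller",
                       ifelse(fc < 8, "larger", "largest")))
  out
}

#' Run the allelic bias test across all tissues
#'
#' @param counts integer count matrix genes x samples.
#' @param sample_sheet data.frame (sample_id, tissue).
#' @param pairs allele-pair data.frame (locus_id, geneA, geneB).
#' @param alpha significance level applied to BH-adjusted p-values.
#' @return data.frame of per-locus, per-tissue calls (locus_id, tissue,
#'   log2fc, p, p_adj, category).
#' @export
ase_bias_calls <- function(counts, sample_sheet, pairs, alpha = 0.05) {
  sf <- size_factors(counts)
  out <- list()
  for (t in unique(sample_sheet$tissue)) {
    cols <- sample_sheet$sample_id[sample_sheet$tissue == t]
    res <- test_allelic_bias(counts[pairs$geneA, cols, drop = FALSE],
                             counts[pairs$geneB, cols, drop = FALSE],
                             sf[cols], sf[cols])
    p_adj <- p.adjust(res$p, method = "BH")
    out[[t]] <- data.frame(locus_id = pairs$locus_id, tissue = t,
                           log2fc = res$log2fc, p = res$p, p_adj = p_adj,
                           category = classify_bias(res$log2fc, p_adj, alpha),
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Spatiotemporal profiles and dynamic/stable ranking
#'
#' Builds the per-locus significance-masked signed log2 fold-change vector
#' (0 where the call is not significant), computes its range (max - min)
#' across tissues, and labels the top 10% of loci by range `dynamic` and
#' the bottom 10% `stable` (ties broken by locus id).
#'
#' @param calls output of [ase_bias_calls()].
#' @param top_fraction fraction labelled at each extreme.
#' @return data.frame (locus_id, per-tissue fc columns, fc_range, label).
#' @export
rank_dynamic_stable <- function(calls, top_fraction = 0.10) {
  eff <- ifelse(!is.na(calls$p_adj) & calls$p_adj < 0.05, calls$log2fc, 0)
  mat <- tapply(eff, list(calls$locus_id, calls$tissue), mean)
  mat[is.na(mat)] <- 0
  fc_range <- apply(mat, 1, max) - apply(mat, 1, min)
  n <- length(fc_range)
  label <- rep("neither", n)
  if (n < 10L) {
    message("fewer than 10 loci; dynamic/stable labels withheld")
  } else {
    k <- floor(top_fraction * n)
    ord <- order(-fc_range, rownames(mat))
    label[ord[seq_len(k)]] <- "dynamic"
    ord_low <- order(fc_range, rownames(mat))
    label[ord_low[seq_len(k)]] <- "stable"
  }
  out <- data.frame(locus_id = rownames(mat), mat, fc_range = fc_range,
                    label = label, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Category transition summary across tissues
#'
#' Orders the bias levels smaller < larger < largest (ignoring `none`) and,
#' for each locus, classifies its tissue-to-tissue changes: `neighboring`
#' if any change is one step, `jumping` if any change is two steps, `none`
#' otherwise.
#'
#' @param calls output of [ase_bias_calls()].
#' @return list with `per_locus` (locus_id, transition_type) and `counts`.
#' @export
transition_summary <- function(calls) {
  lev <- c(smaller = 1L, larger = 2L, largest = 3L)
  per_locus <- vapply(split(calls$category, calls$locus_id), function(cc) {
    x <- lev[cc[cc %in% names(lev)]]
    if (length(x) < 2L) return("none")
    steps <- abs(diff(x))
    if (any(steps == 2L)) "jumping"
    else if (any(steps == 1L)) "neighboring"
    else "none"
  }, character(1))
  list(per_locus = data.frame(locus_id = names(per_locus),
                              transition_type = unname(per_locus),
                              stringsAsFactors = FALSE),
       counts = table(factor(per_locus,
                             levels = c("none", "neighboring", "jumping"))))
}
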