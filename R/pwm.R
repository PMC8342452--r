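## Promoter regulatory context: PWM scanning with exact p-values,
## shared/specific TFBS accounting, nearest-TE distances.

PWM_BIN_BITS <- 1e-3   # score discretization for the exact p-value DP

#' Position weight matrix
#'
#' @param motif_id motif identifier.
#' @param mat 4 x L matrix of per-position base frequencies; rows A, C, G,
#'   T; columns must sum to 1 (within 1e-9).
#' @param background background base probabilities (default uniform).
#' @param pseudocount added to frequencies before the log-odds (default
#'   1e-8, matching common scanner settings).
#' @return object of class `pwm`.
#' @export
pwm <- function(motif_id, mat, background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                pseudocount = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(mat) <- BASES
  if (ncol(mat) < 1L) stop("PWM must have length >= 1")
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (!is.null(names(background))) background <- background[BASES]
  structure(list(motif_id = motif_id, mat = mat,
                 background = setNames(as.numeric(background), BASES),
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: length %d, consensus %s, IC %.1f bits\n", x$motif_id,
              ncol(x$mat), pwm_consensus(x), pwm_info_content(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return character string of per-column argmax bases.
#' @export
pwm_consensus <- function(x) paste(BASES[apply(x$mat, 2, which.max)],
                                   collapse = "")

#' Information content of a PWM in bits
#' @param x a `pwm`.
#' @return total IC relative to the background.
#' @export
pwm_info_content <- function(x) {
  f <- x$mat
  sum(f * log2(pmax(f, 1e-300) / x$background[rownames(f)]))
}

## Integer-binned log-odds column scores (rows A,C,G,T). Zero frequencies
## with a zero pseudocount are floored at -100 bits (impossible bases).
pwm_score_bins <- function(x) {
  s <- log2((x$mat + x$pseudocount) / x$background[rownames(x$mat)])
  s[!is.finite(s)] <- -100
  round(s / PWM_BIN_BITS)
}

#' Exact score distribution of a PWM under the background model
#'
#' Dynamic-programming convolution of the per-column binned score
#' distributions under the i.i.d. background; scores are discretized to
#' 1e-3-bit bins (the same binning used when scanning, so scanner p-values
#' are exact for the binned score).
#'
#' @param x a `pwm`.
#' @return list with `bins` (integer bin values), `prob`, and `tail`
#'   (P(score >= bin)).
#' @export
pwm_score_distribution <- function(x) {
  sb <- pwm_score_bins(x)
  bg <- x$background
  lo <- sum(apply(sb, 2, min)); hi <- sum(apply(sb, 2, max))
  prob <- numeric(hi - lo + 1L)
  prob[1L] <- 1
  for (j in seq_len(ncol(sb))) {
    width <- length(prob)
    newp <- numeric(width)
    cmin <- min(sb[, j])
    for (b in seq_len(4L)) {
      shift <- sb[b, j] - cmin
      if (shift == 0L) newp <- newp + prob * bg[b]
      else {
        idx <- seq_len(width - shift)
        newp[idx + shift] <- newp[idx + shift] + prob[idx] * bg[b]
      }
    }
    prob <- newp
  }
  bins <- lo + seq_along(prob) - 1L
  tail <- rev(cumsum(rev(prob)))
  list(bins = bins, prob = prob, tail = tail)
}

## p-value of binned score s under the distribution d (P(S >= s)).
pwm_tail_p <- function(d, s) {
  i <- s - d$bins[1] + 1L
  i <- pmin(pmax(i, 1L), length(d$tail) + 1L)
  out <- rep(0, length(s))
  inb <- i <= length(d$tail)
  out[inb] <- d$tail[i[inb]]
  out
}

#' Scan a promoter with a PWM
#'
#' Log-odds scoring of every window on both strands with exact tail
#' p-values under the background (dynamic-programming score distribution on
#' 1e-3-bit bins). Windows containing non-ACGT characters are skipped.
#' Hits with p < `p_threshold` (strict) are reported. Offsets are 0-based
#' positions of the leftmost base of the hit on the forward strand.
#'
#' @param promoter promoter sequence (character).
#' @param x a `pwm`.
#' @param p_threshold reporting threshold (default 1e-5).
#' @param dist optional precomputed [pwm_score_distribution()].
#' @return data.frame (motif_id, offset, strand, score, p).
#' @export
scan_pwm <- function(promoter, x, p_threshold = 1e-5, dist = NULL) {
  L <- ncol(x$mat)
  n <- nchar(promoter)
  empty <- data.frame(motif_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0))
  if (L > n) return(empty)
  if (is.null(dist)) dist <- pwm_score_distribution(x)
  sb <- pwm_score_bins(x)

  scan_strand <- function(seqn) {
    code <- match(strsplit(seqn, "")[[1]], BASES)   # NA for N etc.
    np <- length(code) - L + 1L
    if (np < 1L) return(NULL)
    sc <- rep(0L, np)
    bad <- rep(FALSE, np)
    for (j in seq_len(L)) {
      cj <- code[j:(j + np - 1L)]
      bad <- bad | is.na(cj)
      sc <- sc + ifelse(is.na(cj), 0L, sb[cbind(cj, j)])
    }
    p <- pwm_tail_p(dist, sc)
    keep <- !bad & p < p_threshold
    if (!any(keep)) return(NULL)
    data.frame(pos = which(keep) - 1L, score = sc[keep] * PWM_BIN_BITS,
               p = p[keep])
  }

  fw <- scan_strand(promoter)
  rv <- scan_strand(revcomp(promoter))
  out <- list()
  if (!is.null(fw))
    out$f <- data.frame(motif_id = x$motif_id, offset = fw$pos, strand = "+",
                        score = fw$score, p = fw$p, stringsAsFactors = FALSE)
  if (!is.null(rv))
    out$r <- data.frame(motif_id = x$motif_id, offset = n - L - rv$pos,
                        strand = "-", score = rv$score, p = rv$p,
                        stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Scan many promoters with a motif set
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs list of [pwm()] objects.
#' @param p_threshold reporting threshold.
#' @return data.frame (gene_id, motif_id, offset, strand, score, p).
#' @export
scan_promoters <- function(promoters, motifs, p_threshold = 1e-5) {
  dists <- lapply(motifs, pwm_score_distribution)
  rows <- list()
  for (g in names(promoters)) {
    for (mi in seq_along(motifs)) {
      h <- scan_pwm(promoters[[g]], motifs[[mi]], p_threshold,
                    dist = dists[[mi]])
      if (nrow(h)) rows[[length(rows) + 1L]] <- cbind(gene_id = g, h)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared and specific TFBS counts between two allele promoters
#'
#' Per motif with a hits in promoter A and b in promoter B: shared
#' accumulates min(a, b), specific_A accumulates max(a - b, 0), specific_B
#' max(b - a, 0). Type-level counts (motifs present in both vs one
#' promoter) are reported alongside the instance-level accounting.
#'
#' @param hitsA,hitsB hit tables (from [scan_pwm()]/[scan_promoters()]) for
#'   the two promoters.
#' @return one-row data.frame: shared, specific_A, specific_B,
#'   shared_types, specific_types_A, specific_types_B.
#' @export
compare_tfbs <- function(hitsA, hitsB) {
  ca <- table(hitsA$motif_id); cb <- table(hitsB$motif_id)
  motifs <- union(names(ca), names(cb))
  a <- ifelse(motifs %in% names(ca), as.numeric(ca[motifs]), 0)
  b <- ifelse(motifs %in% names(cb), as.numeric(cb[motifs]), 0)
  data.frame(shared = sum(pmin(a, b)),
             specific_A = sum(pmax(a - b, 0)),
             specific_B = sum(pmax(b - a, 0)),
             shared_types = sum(a > 0 & b > 0),
             specific_types_A = sum(a > 0 & b == 0),
             specific_types_B = sum(b > 0 & a == 0))
}

#' Distance to the nearest transposable element
#'
#' Intervals are 0-based half-open. Distance is 0 when the gene overlaps
#' any TE, otherwise the smallest gap between interval ends.
#'
#' @param gene_start,gene_end gene interval (0-based half-open).
#' @param te data.frame with columns start, end, te_id (same chromosome).
#' @return list with `distance` (NA when `te` is empty) and `te_id`.
#' @export
nearest_te_distance <- function(gene_start, gene_end, te) {
  if (!nrow(te)) return(list(distance = NA_real_, te_id = NA_character_))
  gap <- pmax(te$start - gene_end, gene_start - te$end, 0)
  i <- which.min(gap)
  list(distance = gap[i], te_id = te$te_id[i])
}

#' Nearest-TE distances for an annotation table
#'
#' @param genes data.frame (gene_id, chrom, start, end), 1-based inclusive
#'   coordinates as in the annotation.
#' @param te BED-style data.frame (chrom, start, end, te_id), 0-based
#'   half-open.
#' @return data.frame (gene_id, nearest_te_distance, te_id).
#' @export
nearest_te_distances <- function(genes, te) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    sub <- te[te$chrom == genes$chrom[i], , drop = FALSE]
    nearest_te_distance(genes$start[i] - 1L, genes$end[i], sub)
  })
  data.frame(gene_id = genes$gene_id,
             nearest_te_distance = vapply(res, `[[`, numeric(1), "distance"),
             te_id = vapply(res, `[[`, character(1), "te_id"),
             stringsAsFactors = FALSE)
}
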