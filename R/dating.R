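## Molecular dating: Ks-peak detection, rate calibration, event dating,
## LTR insertion ages, k-mer genome size.

#' Detect peaks in a Ks distribution
#'
#' Gaussian kernel density (Silverman's rule by default) over [0, 5];
#' peaks are interior local maxima with density at least `prominence`
#' (default 5%) of the global maximum, returned in ascending Ks order.
#'
#' @param ks numeric Ks values (values > 5 and non-finite values are
#'   dropped before fitting).
#' @param bandwidth kernel bandwidth, or `"auto"` for Silverman's rule.
#' @param prominence minimum density relative to the global maximum.
#' @param min_n minimum number of usable values.
#' @return numeric vector of peak locations with attribute `bandwidth`.
#' @export
detect_ks_peaks <- function(ks, bandwidth = "auto", prominence = 0.05,
                            min_n = 50L) {
  ks <- ks[is.finite(ks) & ks >= 0 & ks <= 5]
  if (length(ks) < min_n)
    stop("need at least ", min_n, " usable Ks values (got ", length(ks), ")")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(ks) else bandwidth
  d <- density(ks, bw = bw, from = 0, to = 5, n = 2048)
  y <- d$y
  local_max <- which(diff(sign(diff(y))) == -2) + 1L
  keep <- local_max[y[local_max] >= prominence * max(y)]
  structure(sort(d$x[keep]), bandwidth = bw)
}

#' Calibrate the synonymous substitution rate from an anchor
#'
#' r = Ks / (2 t) for a known divergence (e.g. a dated speciation event
#' with its ortholog Ks peak).
#'
#' @param ks_anchor anchor Ks.
#' @param t_anchor anchor age in years.
#' @return list of class `rate_calibration` (r, ks_anchor, t_anchor).
#' @export
calibrate_rate <- function(ks_anchor, t_anchor) {
  if (ks_anchor <= 0 || t_anchor <= 0)
    stop("ks_anchor and t_anchor must be positive")
  structure(list(r = ks_anchor / (2 * t_anchor), ks_anchor = ks_anchor,
                 t_anchor = t_anchor), class = "rate_calibration")
}

#' Date an event from its Ks peak
#'
#' age = Ks / (2 r) with the calibrated rate r.
#'
#' @param ks_peak peak Ks of the event.
#' @param cal a [calibrate_rate()] result.
#' @param label event label.
#' @return data.frame (event, ks_peak, age_years, age_mya).
#' @export
date_event <- function(ks_peak, cal, label = "event") {
  stopifnot(ks_peak >= 0, inherits(cal, "rate_calibration"))
  age <- ks_peak / (2 * cal$r)
  data.frame(event = label, ks_peak = ks_peak, age_years = age,
             age_mya = age / 1e6, stringsAsFactors = FALSE)
}

#' LTR insertion time from LTR-pair divergence
#'
#' T = d / (2 mu), with d the JC69-corrected distance between the 5' and
#' 3' LTR of one element and mu the substitution rate per site per year
#' (default 1.3e-8).
#'
#' @param d corrected divergence (substitutions/site); `NA` propagates.
#' @param mu mutation rate.
#' @return insertion age in years.
#' @export
ltr_insertion_time <- function(d, mu = 1.3e-8) {
  stopifnot(mu > 0)
  ifelse(is.na(d) | d < 0, NA_real_, d / (2 * mu))
}

#' JC69-corrected divergence between two aligned sequences
#'
#' Proportion of mismatching sites corrected with [jc_correct()];
#' saturation (p >= 3/4) yields `NA`.
#'
#' @param seq1,seq2 equal-length sequences (characters compared per site;
#'   positions with non-ACGT characters are skipped).
#' @return corrected distance.
#' @export
pairwise_jc_distance <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  stopifnot(length(a) == length(b))
  use <- a %in% BASES & b %in% BASES
  if (!any(use)) return(NA_real_)
  jc_correct(mean(a[use] != b[use]))
}

#' Genome size from a k-mer histogram
#'
#' size = total k-mer mass / homozygous peak depth. Error-tail depths
#' (<= `error_tail`, default 2) are excluded from the total. The
#' homozygous peak is the highest-depth local maximum among the two most
#' prominent peaks (a diploid histogram shows the heterozygous peak at
#' roughly half the homozygous depth).
#'
#' @param hist data.frame (depth, count).
#' @param error_tail maximum depth treated as sequencing-error k-mers.
#' @return list (genome_size, peak_depth, total_kmers, peaks).
#' @export
kmer_genome_size <- function(hist, error_tail = 2L) {
  stopifnot(nrow(hist) > 0, all(hist$depth >= 1))
  h <- hist[order(hist$depth), ]
  h <- h[h$depth > error_tail, , drop = FALSE]
  if (!nrow(h)) stop("no histogram mass beyond the error tail")
  y <- h$count
  n <- length(y)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i] > y[i - 1L] else TRUE
    right <- if (i < n) y[i] >= y[i + 1L] else FALSE
    left && right
  }, logical(1))
  peaks <- h$depth[is_peak]
  if (!length(peaks))
    stop("no detectable coverage peak; check the histogram (max count at ",
         "depth ", h$depth[which.max(y)], ")")
  top2 <- peaks[order(-y[is_peak])][seq_len(min(2L, length(peaks)))]
  peak_depth <- max(top2)
  total <- sum(as.numeric(h$depth) * as.numeric(h$count))
  list(genome_size = total / peak_depth, peak_depth = peak_depth,
       total_kmers = total, peaks = sort(top2))
}
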