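#' @importFrom stats cor density dist dnbinom hclust cutree lm median optimize
#'   p.adjust pnorm prcomp quantile rbinom rlnorm rnbinom rnorm runif sd setNames
#'   var pt
#' @importFrom utils head read.delim write.table tail
NULL

BASES <- c("A", "C", "G", "T")

## Standard genetic code keyed by codon string ("TTT" -> "F", stops "*").
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

is_stop_codon <- function(codon) {
  unname(codon_table()[codon] == "*")
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

## Random in-frame CDS of n_codons sense codons starting ATG, no internal stops.
random_cds <- function(n_codons) {
  ct <- codon_table()
  sense <- names(ct)[ct != "*"]
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     if.fuzzy.codon = "X"))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible child seed from a parent seed and a stream label,
## kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two clusterings of the same items, corrected for chance;
#' 1 means identical partitions, 0 is the expectation under random labels.
#' Used to score planted-module recovery in coexpression tests.
#'
#' @param a,b integer or character vectors of cluster labels, same length.
#' @return a single number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Mann-Whitney-Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with tie-corrected variance and no continuity
#' correction, matching the large-sample form used for category contrasts.
#'
#' @param x,y numeric samples.
#' @return list with statistic `W` (rank-sum U for `x`) and `p.value`.
#' @export
mww_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(W = W, p.value = 1))
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  list(W = W, p.value = min(1, 2 * pnorm(-abs(z))))
}
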