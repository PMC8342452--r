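## Shared fixtures (memoized across test files) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## A small diploid world reused by several test files.
small_world <- function(seed = 11L) {
  memo(paste0("world", seed), {
    cfg <- sim_config(seed = seed, n_chromosome_pairs = 2L,
                      genes_per_chromosome = 60L, block_size = 20L,
                      n_ltr = 300L, n_ks = 2000L, cds_codons = 200L)
    gen <- generate_diploid_annotation(cfg)
    cdsres <- simulate_cds_pairs(gen$truth, cfg)
    cnt <- simulate_counts(cdsres$truth, cfg)
    list(cfg = cfg, annotation = gen$annotation, genome = gen$genome,
         truth = cdsres$truth, cds = cdsres$cds, counts = cnt)
  })
}

## ---------- independent oracles ----------

## NG86 site fractions by direct enumeration (independent of the package's
## cached table construction).
oracle_ng86_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0; valid <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] == "*") next
      valid <- valid + 1
      if (gc[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

## Pathway-averaged differences by explicit permutation enumeration.
oracle_path_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm_list(v[-i]), function(r) c(v[i], r))))
  }
  tot <- c(0, 0); nv <- 0
  for (ord in perm_list(pos)) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") { valid <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) { tot <- tot + c(sd, nd); nv <- nv + 1 }
  }
  if (nv == 0) return(c(sd = length(pos) / 2, nd = length(pos) / 2))
  c(sd = tot[1] / nv, nd = tot[2] / nv)
}

## Best-scoring valid chain by subset enumeration (<= 12 matches).
oracle_best_chain <- function(m, max_gap = 25L) {
  n <- nrow(m)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 2L && length(idx) != 1L) next
    sub <- m[idx, , drop = FALSE]
    sub <- sub[order(sub$rankA), , drop = FALSE]
    valid_f <- all(diff(sub$rankA) > 0 & diff(sub$rankA) <= max_gap) &&
      (nrow(sub) == 1L ||
       all(diff(sub$rankB) > 0 & diff(sub$rankB) <= max_gap))
    valid_r <- all(diff(sub$rankA) > 0 & diff(sub$rankA) <= max_gap) &&
      (nrow(sub) == 1L ||
       all(diff(sub$rankB) < 0 & -diff(sub$rankB) <= max_gap))
    if (valid_f || valid_r) best <- max(best, sum(sub$score))
  }
  best
}

## Exact PWM score tail by enumerating all 4^L words (binned like the
## scanner).
oracle_pwm_tail <- function(x, L = ncol(x$mat)) {
  sb <- round(log2((x$mat + x$pseudocount) /
                   x$background[rownames(x$mat)]) / 1e-3)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    sc <- sc + sb[cbind(words[, j], j)]
    pr <- pr * x$background[words[, j]]
  }
  function(threshold_bin) sum(pr[sc >= threshold_bin])
}

random_pwm <- function(L, id = "R1", concentration = 2) {
  mat <- sapply(seq_len(L), function(j) {
    v <- stats::rgamma(4, concentration)
    v / sum(v)
  })
  rownames(mat) <- c("A", "C", "G", "T")
  pwm(id, mat)
}
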