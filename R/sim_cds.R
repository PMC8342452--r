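#' Simulate CDS pairs evolved to planted (Ka, Ks) targets
#'
#' For every planted allele pair an ancestral CDS is generated and mutated
#' along the two haplotype lineages: synonymous and nonsynonymous
#' substitution quotas are derived from the planted (Ka, Ks) by inverting
#' the Jukes-Cantor correction against the ancestor's NG86 site counts, and
#' single-nucleotide substitutions of the required class are placed at
#' distinct positions (never creating a stop codon) until the quotas are
#' met. Unpaired noise genes receive independent random CDS; paralogous
#' decoy genes are mutated copies of their source gene at the decoy (Ka, Ks)
#' target, so that decoy collinear blocks carry high Ks.
#'
#' @param truth a `truth_table` from [generate_diploid_annotation()].
#' @param config the [sim_config()] used to generate it.
#' @return list with `cds` (named character vector, one in-frame CDS per
#'   annotated gene) and the unchanged `truth`.
#' @export
simulate_cds_pairs <- function(truth, config) {
  if (!length(config$kaks_grid)) stop("kaks_grid must be nonempty")
  set.seed(child_seed(config$seed, "cds"))
  n_codons <- config$cds_codons

  for (kk in config$kaks_grid) check_ks_range(kk[2], n_codons)
  check_ks_range(truth$decoy_kaks[["ks"]], n_codons)

  cds <- character(0)
  pk <- truth$planted_kaks
  for (i in seq_len(nrow(truth$pairs))) {
    anc <- random_cds(n_codons)
    pair <- mutate_lineages(anc, pk$ka[i], pk$ks[i])
    cds[[truth$pairs$geneA[i]]] <- pair[1]
    cds[[truth$pairs$geneB[i]]] <- pair[2]
  }
  for (g in truth$unpaired) cds[[g]] <- random_cds(n_codons)
  if (nrow(truth$decoys)) {
    for (i in seq_len(nrow(truth$decoys))) {
      src <- cds[[truth$decoys$source_gene[i]]]
      cds[[truth$decoys$gene_id[i]]] <-
        mutate_to_target(src, truth$decoy_kaks[["ka"]],
                         truth$decoy_kaks[["ks"]])
    }
  }
  list(cds = cds, truth = truth)
}

## A finite Ks always inverts to pS < 3/4, but within 1e-3 of saturation
## (Ks beyond ~5) the correction is numerically useless, so such targets
## are rejected.
check_ks_range <- function(ks, n_codons) {
  pS <- 0.75 * (1 - exp(-4 * ks / 3))
  if (pS >= 0.749)
    stop("requested Ks = ", ks, " implies pS ~ 3/4: beyond the ",
         "Jukes-Cantor-correctable range")
  invisible(pS)
}

## Split the substitution quotas between the two lineages, mutating disjoint
## positions so that the pairwise raw differences equal the full quotas.
mutate_lineages <- function(ancestor, ka, ks) {
  quotas <- substitution_quotas(ancestor, ka, ks)
  sA <- quotas["syn"] %/% 2; nA <- quotas["nonsyn"] %/% 2
  sB <- quotas["syn"] - sA;  nB <- quotas["nonsyn"] - nA
  used <- integer(0)
  a <- apply_substitutions(ancestor, sA, nA, forbidden = used)
  b <- apply_substitutions(ancestor, sB, nB, forbidden = attr(a, "positions"))
  c(as.character(a), as.character(b))
}

mutate_to_target <- function(seqn, ka, ks) {
  quotas <- substitution_quotas(seqn, ka, ks)
  as.character(apply_substitutions(seqn, quotas["syn"], quotas["nonsyn"],
                                   forbidden = integer(0)))
}

substitution_quotas <- function(seqn, ka, ks) {
  tab <- ng86_site_table()
  cods <- split_codons(seqn)
  S <- sum(tab[cods, "s"]); N <- 3 * length(cods) - S
  pS <- 0.75 * (1 - exp(-4 * ks / 3))
  pN <- 0.75 * (1 - exp(-4 * ka / 3))
  c(syn = round(pS * S), nonsyn = round(pN * N))
}

## Place `n_syn` synonymous and `n_non` nonsynonymous single-base changes at
## distinct, previously untouched positions; substitutions creating stop
## codons are rejected. Attempts are capped; a shortfall raises a warning.
apply_substitutions <- function(seqn, n_syn, n_non, forbidden) {
  ct <- codon_table()
  chars <- strsplit(seqn, "")[[1]]
  len <- length(chars)
  touched <- forbidden
  placed_s <- 0; placed_n <- 0
  attempts <- 0L; max_attempts <- 500L * (n_syn + n_non + 1L)
  while ((placed_s < n_syn || placed_n < n_non) && attempts < max_attempts) {
    attempts <- attempts + 1L
    pos <- sample.int(len, 1L)
    if (pos %in% touched || pos <= 3L) next   # keep the ATG start intact
    ci <- (pos - 1L) %/% 3L
    cod <- paste(chars[ci * 3L + 1:3], collapse = "")
    if (ct[[cod]] == "*") next
    newb <- sample(setdiff(BASES, chars[pos]), 1L)
    newcod <- cod
    substr(newcod, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- newb
    if (ct[[newcod]] == "*") next
    syn <- ct[[newcod]] == ct[[cod]]
    if (syn && placed_s < n_syn) {
      placed_s <- placed_s + 1
    } else if (!syn && placed_n < n_non) {
      placed_n <- placed_n + 1
    } else next
    chars[pos] <- newb
    touched <- c(touched, pos)
  }
  if (placed_s < n_syn || placed_n < n_non)
    warning("substitution quota not met (", placed_s, "/", n_syn, " syn, ",
            placed_n, "/", n_non, " nonsyn)")
  out <- paste(chars, collapse = "")
  attr(out, "positions") <- touched
  out
}
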