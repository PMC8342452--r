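## Codon-aware divergence: protein-guided alignment, NG86 site and
## pathway-averaged difference counting, Jukes-Cantor correction.

.kaks_cache <- new.env(parent = emptyenv())

sense_codons <- function() {
  ct <- codon_table()
  names(ct)[ct != "*"]
}

#' NG86 synonymous/nonsynonymous site fractions of a codon
#'
#' Averages over the nine single-nucleotide mutants of the codon: at each of
#' the three positions the synonymous fraction is the number of synonymous
#' changes divided by the number of non-stop changes at that position
#' (mutations creating a stop codon are excluded from the denominator).
#' S + N = 3 for every sense codon.
#'
#' @param codon a 3-letter DNA string (sense codon).
#' @return named numeric vector `c(s, n)`.
#' @export
ng86_sites <- function(codon) {
  tab <- ng86_site_table()
  row <- tab[codon, ]
  if (any(is.na(row))) stop("not a sense codon: ", codon)
  c(s = row[[1]], n = row[[2]])
}

ng86_site_table <- function() {
  if (!is.null(.kaks_cache$sites)) return(.kaks_cache$sites)
  ct <- codon_table()
  codons <- sense_codons()
  s <- vapply(codons, function(cd) {
    aa <- ct[[cd]]
    ssum <- 0
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(cd, pos, pos))
      muts <- vapply(alts, function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, character(1))
      aas <- ct[muts]
      keep <- aas != "*"
      if (any(keep)) ssum <- ssum + sum(aas[keep] == aa) / sum(keep)
    }
    ssum
  }, numeric(1))
  tab <- data.frame(s = s, n = 3 - s, row.names = codons)
  .kaks_cache$sites <- tab
  tab
}

## Pathway-averaged synonymous/nonsynonymous differences between two sense
## codons. All orderings of the differing positions are enumerated; paths
## through stop codons are dropped. If every path passes through a stop the
## raw differences are split equally between classes.
codon_path_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .kaks_cache$paths[[key]]
  if (!is.null(hit)) return(hit)
  ct <- codon_table()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  res <- if (k == 0L) c(sd = 0, nd = 0) else {
    perms <- permutations_of(diff_pos)
    acc <- c(0, 0); n_valid <- 0L
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (ct[[nxt]] == "*") { ok <- FALSE; break }
        if (ct[[cur]] == ct[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { acc <- acc + c(sd, nd); n_valid <- n_valid + 1L }
    }
    if (n_valid > 0L) c(sd = acc[1] / n_valid, nd = acc[2] / n_valid)
    else c(sd = k / 2, nd = k / 2)
  }
  if (is.null(.kaks_cache$paths)) .kaks_cache$paths <- new.env(parent = emptyenv())
  .kaks_cache$paths[[key]] <- res
  res
}

## Lazily built 61 x 61 pathway-difference lookup tables.
path_diff_tables <- function() {
  if (!is.null(.kaks_cache$sd_mat)) return(list(sd = .kaks_cache$sd_mat,
                                                nd = .kaks_cache$nd_mat))
  codons <- sense_codons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- codon_path_diffs(codons[i], codons[j])
    sd[i, j] <- d[["sd"]]; nd[i, j] <- d[["nd"]]
  }
  .kaks_cache$sd_mat <- sd; .kaks_cache$nd_mat <- nd
  list(sd = sd, nd = nd)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' d = -(3/4) log(1 - (4/3) p). Proportions at or beyond the correctable
#' range (p >= 3/4) return `NA` (saturation).
#'
#' @param p observed proportion of differing sites.
#' @return corrected distance (substitutions per site) or `NA`.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Codon-aware pairwise alignment of two CDS
#'
#' Globally aligns the translated proteins (BLOSUM62, affine gaps) and
#' threads the gaps back onto codons, yielding two equal-length vectors of
#' codons and `---` gap triplets.
#'
#' @param cdsA,cdsB in-frame coding sequences (length divisible by 3, no
#'   internal stop codons).
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return object of class `codon_alignment`: list with codon vectors `a`,
#'   `b` and the protein alignment `score`.
#' @export
align_codons <- function(cdsA, cdsB, gap_opening = 10, gap_extension = 0.5) {
  check_cds <- function(x, label) {
    if (nchar(x) %% 3L != 0L)
      stop(label, ": length not divisible by 3")
    cods <- split_codons(x)
    body <- cods[-length(cods)]
    stops <- which(codon_table()[body] == "*")
    if (length(stops))
      stop(label, ": internal stop codon at codon ", stops[1])
    cods
  }
  codA <- check_cds(cdsA, "cdsA")
  codB <- check_cds(cdsB, "cdsB")
  pa <- translate_cds(cdsA); pb <- translate_cds(cdsB)
  pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  outA <- character(length(sa)); outB <- character(length(sb))
  for (i in seq_along(sa)) {
    if (sa[i] == "-") outA[i] <- "---" else { ia <- ia + 1L; outA[i] <- codA[ia] }
    if (sb[i] == "-") outB[i] <- "---" else { ib <- ib + 1L; outB[i] <- codB[ib] }
  }
  structure(list(a = outA, b = outB, score = Biostrings::score(aln)),
            class = "codon_alignment")
}

#' Ka/Ks estimation for one aligned allele pair
#'
#' NG86: synonymous/nonsynonymous sites averaged over both sequences,
#' differences counted by pathway averaging, and proportions corrected with
#' [jc_correct()]. The optional `YN` method reweights site counting by a
#' transition/transversion ratio (kappa) estimated from the alignment, a
#' light-weight stand-in for the full Yang-Nielsen model. Ks values above
#' `ks_ceiling` (default 5) are flagged `excluded` rather than removed.
#'
#' @param x a `codon_alignment` from [align_codons()], or a CDS string (then
#'   `y` must be the second CDS and the pair is aligned first).
#' @param y optional second CDS.
#' @param method `"NG86"` (default) or `"YN"`.
#' @param ks_ceiling saturation flagging threshold on Ks.
#' @return data.frame row: ka, ks, ratio, n_sites, s_sites, n_diffs,
#'   s_diffs, method, excluded, note.
#' @export
kaks <- function(x, y = NULL, method = c("NG86", "YN"), ks_ceiling = 5) {
  method <- match.arg(method)
  aln <- if (inherits(x, "codon_alignment")) x else align_codons(x, y)
  keep <- aln$a != "---" & aln$b != "---"
  ca <- aln$a[keep]; cb <- aln$b[keep]
  ct <- codon_table()
  sense <- !(ct[ca] == "*" | ct[cb] == "*")
  ca <- ca[sense]; cb <- cb[sense]
  if (!length(ca))
    return(kaks_row(NA, NA, 0, 0, 0, 0, method, FALSE, "empty alignment"))

  kappa <- if (method == "YN") estimate_kappa(ca, cb) else 1
  tabS <- if (method == "YN") kappa_site_table(kappa) else ng86_site_table()
  S <- (sum(tabS[ca, "s"]) + sum(tabS[cb, "s"])) / 2
  N <- 3 * length(ca) - S

  pd <- path_diff_tables()
  Sd <- sum(pd$sd[cbind(ca, cb)]); Nd <- sum(pd$nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc_correct(pS); ka <- jc_correct(pN)
  note <- ""
  if (is.na(ks) && pS >= 0.75) note <- "pS saturated (>= 3/4)"
  if (is.na(ka) && pN >= 0.75) note <- paste(note, "pN saturated (>= 3/4)")
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  excluded <- !is.na(ks) && ks > ks_ceiling
  kaks_row(ka, ks, S, N, Sd, Nd, method, excluded, trimws(note), ratio)
}

kaks_row <- function(ka, ks, S, N, Sd, Nd, method, excluded, note,
                     ratio = NA_real_) {
  data.frame(ka = ka, ks = ks, ratio = ratio, n_sites = N, s_sites = S,
             n_diffs = Nd, s_diffs = Sd, method = method,
             excluded = excluded, note = note, stringsAsFactors = FALSE)
}

## Kimura-style kappa estimate from the codon-aligned nucleotide columns.
estimate_kappa <- function(ca, cb) {
  a <- strsplit(paste(ca, collapse = ""), "")[[1]]
  b <- strsplit(paste(cb, collapse = ""), "")[[1]]
  diff <- a != b
  if (!any(diff)) return(2)
  transition <- function(x, y) (x %in% c("A", "G") & y %in% c("A", "G")) |
    (x %in% c("C", "T") & y %in% c("C", "T"))
  P <- sum(diff & transition(a, b)) / length(a)
  Q <- sum(diff & !transition(a, b)) / length(a)
  if (Q == 0 || P == 0) return(2)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(2)
  ts <- -0.5 * log(w1) + 0.25 * log(w2)
  tv <- -0.5 * log(w2)
  if (tv <= 0) return(2)
  max(ts / tv, 0.1)
}

## Site fractions with transition mutations weighted kappa : 1.
kappa_site_table <- function(kappa) {
  ct <- codon_table()
  codons <- sense_codons()
  transversion_partner <- list(A = c("C", "T"), G = c("C", "T"),
                               C = c("A", "G"), T = c("A", "G"))
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  s <- vapply(codons, function(cd) {
    aa <- ct[[cd]]
    ssum <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      alts <- setdiff(BASES, ref)
      w <- ifelse(alts == transition_partner[[ref]], kappa, 1)
      muts <- vapply(alts, function(b) { x <- cd; substr(x, pos, pos) <- b; x },
                     character(1))
      aas <- ct[muts]
      keep <- aas != "*"
      if (any(keep))
        ssum <- ssum + sum(w[keep] * (aas[keep] == aa)) / sum(w[keep])
    }
    ssum
  }, numeric(1))
  data.frame(s = s, n = 3 - s, row.names = codons)
}

#' Ka/Ks for a table of allele pairs
#'
#' @param cds named `DNAStringSet` (or named character vector) of CDS.
#' @param pairs data.frame with columns `geneA`, `geneB` (and optionally
#'   `locus_id`).
#' @param method passed to [kaks()].
#' @return data.frame with one row per pair.
#' @export
kaks_pairs <- function(cds, pairs, method = "NG86") {
  cds <- setNames(as.character(cds), names(cds))
  ok <- pairs$geneA %in% names(cds) & pairs$geneB %in% names(cds) &
    nchar(cds[pairs$geneA]) %% 3L == 0L & nchar(cds[pairs$geneB]) %% 3L == 0L
  rows <- vector("list", nrow(pairs))
  if (any(ok)) {
    ia <- which(ok)
    pa <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[pairs$geneA[ia]]), if.fuzzy.codon = "X")))
    pb <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[pairs$geneB[ia]]), if.fuzzy.codon = "X")))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pa), Biostrings::AAStringSet(pb),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    patt <- as.character(Biostrings::alignedPattern(aln))
    subj <- as.character(Biostrings::alignedSubject(aln))
    scores <- Biostrings::score(aln)
    for (j in seq_along(ia)) {
      i <- ia[j]
      ca <- thread_codons(strsplit(patt[j], "")[[1]],
                          split_codons(cds[[pairs$geneA[i]]]))
      cb <- thread_codons(strsplit(subj[j], "")[[1]],
                          split_codons(cds[[pairs$geneB[i]]]))
      caln <- structure(list(a = ca, b = cb, score = scores[j]),
                        class = "codon_alignment")
      rows[[i]] <- kaks(caln, method = method)
    }
  }
  for (i in which(!ok))
    rows[[i]] <- kaks_row(NA, NA, NA, NA, NA, NA, method, FALSE,
                          "missing or untranslatable CDS")
  out <- do.call(rbind, rows)
  if (!is.null(pairs$locus_id)) out <- cbind(locus_id = pairs$locus_id, out)
  cbind(out, geneA = pairs$geneA, geneB = pairs$geneB)
}

## thread aligned protein characters back onto codons
thread_codons <- function(aln_chars, codons) {
  out <- character(length(aln_chars))
  gap <- aln_chars == "-"
  out[gap] <- "---"
  out[!gap] <- codons[seq_len(sum(!gap))]
  out
}
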