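## Weighted coexpression network: soft power selection, unsigned TOM,
## module detection, eigengenes, allele-divergence classification.

#' Network construction parameters
#'
#' @param soft_power integer in 1..30 or `"auto"` (first power whose
#'   scale-free fit exceeds `scale_free_target`).
#' @param scale_free_target scale-free topology fit target (default 0.9).
#' @param min_module_size minimum genes per module (default 60).
#' @param merge_cut_height eigengene dissimilarity (1 - correlation) below
#'   which modules are merged (default 0.15).
#' @return list of class `network_config`.
#' @export
network_config <- function(soft_power = "auto", scale_free_target = 0.9,
                           min_module_size = 60L, merge_cut_height = 0.15) {
  if (!identical(soft_power, "auto")) {
    soft_power <- as.integer(soft_power)
    stopifnot(soft_power >= 1L, soft_power <= 30L)
  }
  stopifnot(scale_free_target > 0, scale_free_target < 1,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(soft_power = soft_power,
                 scale_free_target = scale_free_target,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height),
            class = "network_config")
}

## log-transformed expression and correlation; constant genes removed
prepare_expr <- function(tpm) {
  x <- log2(tpm + 1)
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) removed")
    x <- x[sds > 0, , drop = FALSE]
  }
  x
}

#' Scale-free topology fit for a soft power
#'
#' @param acor absolute gene-gene correlation matrix.
#' @param beta candidate soft power.
#' @param n_bins connectivity histogram bins.
#' @return signed R^2 of log10 p(k) on log10 k (negative when the slope is
#'   positive), or NA when connectivity is degenerate.
#' @export
scale_free_fit <- function(acor, beta, n_bins = 10L) {
  a <- acor^beta
  k <- rowSums(a) - diag(a)
  if (max(k) - min(k) < 1e-12) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- as.numeric(table(cuts)) / length(k)
  use <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(use) < 3L) return(NA_real_)
  fit <- lm(log10(pk[use]) ~ log10(dk[use]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2]
  if (!is.na(slope) && slope > 0) -r2 else r2
}

#' Select the soft-thresholding power
#'
#' Scans beta = 1..30 and returns the first power whose scale-free fit
#' index reaches the target (default 0.9); if none qualifies, the argmax
#' power is returned with attribute `reached_target = FALSE`.
#'
#' @param tpm TPM matrix (genes x samples) of expressed genes.
#' @param config a [network_config()].
#' @return integer power with attributes `fit` (per-power vector) and
#'   `reached_target`.
#' @export
pick_soft_power <- function(tpm, config = network_config()) {
  x <- prepare_expr(tpm)
  if (nrow(x) < 20L) stop("need at least 20 genes")
  if (ncol(x) < 4L) stop("need at least 4 samples")
  acor <- abs(cor(t(x)))
  fits <- vapply(1:30, function(b) scale_free_fit(acor, b), numeric(1))
  ok <- which(!is.na(fits) & fits >= config$scale_free_target)
  if (length(ok)) {
    beta <- ok[1]
    reached <- TRUE
  } else if (all(is.na(fits))) {
    beta <- 6L                      # degenerate network: conventional default
    reached <- FALSE
  } else {
    beta <- which.max(fits)
    reached <- FALSE
  }
  structure(as.integer(beta), fit = fits, reached_target = reached)
}

#' Unsigned topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for an
#' unsigned adjacency a = |cor|^beta; diagonal set to 1.
#'
#' @param adj adjacency matrix (zero diagonal assumed; forced internally).
#' @return TOM matrix in [0, 1].
#' @export
tom_similarity <- function(adj) {
  diag(adj) <- 0
  L <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' Detect coexpression modules
#'
#' Unsigned adjacency at the chosen soft power, TOM dissimilarity,
#' average-linkage hierarchical clustering, and a fixed-height tree cut
#' scanned over heights to maximize the number of modules meeting
#' `min_module_size` (an intentionally simple stand-in for dynamic tree
#' cutting). Genes in undersized clusters go to module 0 (grey). Modules
#' whose eigengenes are closer than `merge_cut_height` on the
#' 1 - correlation scale are merged iteratively.
#'
#' @param tpm TPM matrix of expressed genes (genes x samples).
#' @param config a [network_config()].
#' @return list of class `module_assignment`: `modules` (named integer
#'   vector, 0 = unassigned), `eigengenes` (modules x samples matrix,
#'   unit-norm rows), `soft_power`, `config`.
#' @export
detect_modules <- function(tpm, config = network_config()) {
  x <- prepare_expr(tpm)
  beta <- if (identical(config$soft_power, "auto"))
    pick_soft_power(tpm, config) else config$soft_power
  if (nrow(x) < config$min_module_size) {
    modules <- setNames(rep(0L, nrow(x)), rownames(x))
    return(structure(list(modules = modules,
                          eigengenes = matrix(numeric(0), 0, ncol(x)),
                          soft_power = as.integer(beta), config = config),
                     class = "module_assignment"))
  }
  adj <- abs(cor(t(x)))^beta
  tom <- tom_similarity(adj)
  hc <- hclust(as.dist(1 - tom), method = "average")

  heights <- quantile(hc$height, probs = seq(0.05, 0.99, by = 0.02))
  best <- NULL; best_score <- c(-1, -1)
  for (h in unique(heights)) {
    cl <- cutree(hc, h = h)
    sizes <- table(cl)
    ok <- as.integer(names(sizes)[sizes >= config$min_module_size])
    score <- c(length(ok), sum(sizes[as.character(ok)]))
    if (score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2])) {
      best_score <- score
      keep <- cl %in% ok
      lab <- integer(length(cl))
      lab[keep] <- as.integer(factor(cl[keep]))
      best <- setNames(lab, rownames(x))
    }
  }
  modules <- best
  me <- module_eigengenes(x, modules)
  merged <- merge_close_modules(x, modules, me, config$merge_cut_height)
  structure(list(modules = merged$modules, eigengenes = merged$eigengenes,
                 soft_power = as.integer(beta), config = config),
            class = "module_assignment")
}

#' Module eigengenes
#'
#' First principal component of each module's row-standardized expression,
#' as a unit-norm sample-space profile, sign-oriented to correlate
#' positively with the module mean profile.
#'
#' @param x log-expression matrix (genes x samples).
#' @param modules named integer module vector (0 ignored).
#' @return matrix modules x samples; rownames are module ids.
#' @export
module_eigengenes <- function(x, modules) {
  ids <- sort(unique(modules[modules > 0]))
  me <- t(vapply(ids, function(mid) {
    xm <- x[names(modules)[modules == mid], , drop = FALSE]
    xs <- t(scale(t(xm)))
    xs[!is.finite(xs)] <- 0
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (cor(v, colMeans(xs)) < 0) v <- -v
    v
  }, numeric(ncol(x))))
  rownames(me) <- ids
  colnames(me) <- colnames(x)
  me
}

merge_close_modules <- function(x, modules, me, cut_height) {
  repeat {
    if (nrow(me) < 2L) break
    dm <- 1 - cor(t(me))
    diag(dm) <- Inf
    i <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    if (dm[i[1], i[2]] >= cut_height) break
    keep_id <- as.integer(rownames(me)[min(i)])
    drop_id <- as.integer(rownames(me)[max(i)])
    modules[modules == drop_id] <- keep_id
    ## relabel densely
    ids <- sort(unique(modules[modules > 0]))
    modules[modules > 0] <- match(modules[modules > 0], ids)
    me <- module_eigengenes(x, modules)
  }
  list(modules = modules, eigengenes = me)
}

#' Classify allele-pair coexpression divergence
#'
#' Alleles in the same module are `coordinated`. For alleles in different
#' modules, the Euclidean distance between their module eigengenes is
#' compared with a threshold equal to 50% of the median, over modules, of
#' each module's maximum pairwise eigengene distance to any other module:
#' strictly above the threshold is `divergent`, otherwise `similar`. Pairs
#' with an unassigned (grey) allele are withheld.
#'
#' @param pairs data.frame (locus_id, geneA, geneB).
#' @param assignment a `module_assignment`.
#' @param threshold_fraction fraction of the median maximum distance
#'   (default 0.5).
#' @return data.frame (locus_id, moduleA, moduleB, distance, threshold,
#'   class) with class in coordinated/similar/divergent/withheld.
#' @export
classify_allele_divergence <- function(pairs, assignment,
                                       threshold_fraction = 0.5) {
  mods <- assignment$modules
  me <- assignment$eigengenes
  thr <- if (nrow(me) >= 2L)
    divergence_threshold(as.matrix(dist(me)), threshold_fraction)
  else NA_real_

  mA <- mods[pairs$geneA]; mB <- mods[pairs$geneB]
  distance <- rep(NA_real_, nrow(pairs))
  cls <- rep("withheld", nrow(pairs))
  known <- !is.na(mA) & !is.na(mB) & mA > 0 & mB > 0
  same <- known & mA == mB
  cls[same] <- "coordinated"
  distance[same] <- 0
  diff_idx <- which(known & !same)
  if (length(diff_idx)) {
    distance[diff_idx] <- sqrt(rowSums(
      (me[as.character(mA[diff_idx]), , drop = FALSE] -
       me[as.character(mB[diff_idx]), , drop = FALSE])^2))
    cls[diff_idx] <- ifelse(distance[diff_idx] > thr, "divergent", "similar")
  }
  data.frame(locus_id = pairs$locus_id, moduleA = unname(mA),
             moduleB = unname(mB), distance = distance,
             threshold = thr, class = cls, stringsAsFactors = FALSE)
}

#' Divergence threshold from an eigengene distance matrix
#'
#' threshold = fraction x median over modules of each module's maximum
#' distance to any other module. Per-module maxima {2, 3, 4} with the
#' default fraction give 1.5.
#'
#' @param dist_matrix square matrix of pairwise eigengene distances.
#' @param fraction fraction of the median maximum (default 0.5).
#' @return the threshold.
#' @export
divergence_threshold <- function(dist_matrix, fraction = 0.5) {
  d <- as.matrix(dist_matrix)
  stopifnot(nrow(d) == ncol(d), nrow(d) >= 2L)
  diag(d) <- NA
  fraction * median(apply(d, 1, max, na.rm = TRUE))
}
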