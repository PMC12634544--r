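## Alpha diversity, Bray-Curtis dissimilarity, principal coordinates and
## PERMANOVA. Standard distance and permutation machinery is delegated to
## vegan and ape; the diversity estimators are the small closed-form
## formulas stated in their definitions.

as_count_input <- function(m) {
  if (inherits(m, "count_matrix")) m <- m$counts
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.numeric(m)) abort("counts must be numeric")
  if (any(m < 0)) abort("counts must be nonnegative")
  m
}

#' Bias-corrected Chao1 richness estimate
#'
#' `Chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the
#' numbers of singleton and doubleton taxa. The bias-corrected form is
#' defined even when no doubletons are observed. Always at least the
#' observed richness, with equality iff `F1 <= 1`.
#'
#' @param counts nonnegative integer abundance vector for one sample.
#' @return Estimated richness (taxa).
#' @export
#' @examples
#' chao1(c(1, 1, 2, 3, 4))  # 5 + 2*1/4 = 5.5
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be nonnegative integers")
  if (sum(counts) == 0) abort("all-zero count vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Simpson diversity
#'
#' Default is the Gini-Simpson index `1 - sum(p_i^2)` on relative abundances
#' (the probability that two random reads belong to different taxa); the
#' classical dominance `D = sum(p_i^2)` is available via
#' `index = "dominance"`.
#'
#' @param counts nonnegative abundance vector with positive total.
#' @param index `"gini-simpson"` (default) or `"dominance"`.
#' @return Index value in `[0, 1)` for Gini-Simpson.
#' @export
simpson <- function(counts, index = c("gini-simpson", "dominance")) {
  index <- match.arg(index)
  if (any(counts < 0)) abort("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) abort("all-zero count vector")
  d <- sum((counts / total)^2)
  if (index == "dominance") d else 1 - d
}

#' Per-sample alpha diversity table
#'
#' @param m a `count_matrix` from [generate_count_matrix()] or a taxa x
#'   sample numeric matrix.
#' @return data.frame with `sample`, `observed`, `chao1`, `simpson` (and
#'   `treatment` when the input carries a sample map).
#' @export
alpha_diversity <- function(m) {
  treatments <- if (inherits(m, "count_matrix")) m$treatments else NULL
  counts <- as_count_input(m)
  out <- data.frame(
    sample = colnames(counts),
    observed = apply(counts, 2, function(x) sum(x > 0)),
    chao1 = apply(counts, 2, chao1),
    simpson = apply(counts, 2, simpson),
    row.names = NULL)
  if (!is.null(treatments)) out$treatment <- treatments[out$sample]
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y)`, computed on raw
#' counts by default (set `relative = TRUE` to close each sample to
#' proportions first). Delegates to [vegan::vegdist()].
#'
#' @param m a `count_matrix` or taxa x sample numeric matrix.
#' @param relative close samples to relative abundances before computing.
#' @return A `dist` object over samples with entries in `[0, 1]`.
#' @export
bray_curtis <- function(m, relative = FALSE) {
  counts <- as_count_input(m)
  if (ncol(counts) < 2L) abort("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    abort("all-zero sample(s): %s", paste(colnames(counts)[zero], collapse = ", "))
  x <- t(counts)
  if (relative) x <- x / rowSums(x)
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower-centred eigendecomposition of the squared-distance matrix (classical
#' metric multidimensional scaling), delegating to [ape::pcoa()]. When the
#' most negative eigenvalue has magnitude above `1e-8` — the usual situation
#' for non-Euclidean Bray-Curtis matrices — the Cailliez correction is
#' applied and tagged in the result.
#'
#' @param d a `dist` object or symmetric matrix of dissimilarities.
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (non-increasing), `proportion_explained`
#'   (relative to the sum of positive eigenvalues) and `correction`
#'   (`"none"` or `"cailliez"`).
#' @export
pcoa <- function(d) {
  if (is.matrix(d)) {
    check_symmetric(d, "distance matrix")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) abort("d must be a dist object or symmetric matrix")
  res <- ape::pcoa(d)
  eig <- res$values$Eigenvalues
  correction <- "none"
  coords <- res$vectors
  if (min(eig) < -1e-8) {
    res <- ape::pcoa(d, correction = "cailliez")
    coords <- if (!is.null(res$vectors.cor)) res$vectors.cor else res$vectors
    eig <- if ("Corr_eig" %in% names(res$values)) res$values$Corr_eig else res$values$Eigenvalues
    correction <- "cailliez"
  }
  pos <- eig[eig > 1e-12]
  k <- ncol(coords)
  prop <- (eig[seq_len(k)] / sum(pos))
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = pmax(prop, 0),
                 correction = correction),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA (%s correction): %d axes\n", x$correction,
              ncol(x$coordinates)))
  cat("Variance explained:",
      paste0(round(100 * x$proportion_explained[1:min(3, length(x$proportion_explained))], 1),
             "%", collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's
#' distance-based decomposition) via [vegan::adonis2()], with free
#' permutation of sample labels and
#' `p = (1 + #\{permuted F >= observed F\}) / (n_permutations + 1)`, so the
#' smallest attainable p-value is `1 / (n_permutations + 1)`.
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; every group needs at least 2
#'   samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `permanova_result`: list with `F` (pseudo-F),
#'   `R2`, `p`, `df`, `n_permutations` and `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  if (is.matrix(d)) {
    check_symmetric(d, "distance matrix")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (length(groups) != n)
    abort("groups length (%d) must match sample count (%d)", length(groups), n)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(table(groups) < 2L)) abort("every group needs at least 2 samples")
  set.seed(substream_seed(seed, "permanova"))
  df <- data.frame(.group = groups)
  fit <- vegan::adonis2(d ~ .group, data = df, permutations = n_permutations)
  structure(list(F = fit$F[1],
                 R2 = fit$R2[1],
                 R2_residual = fit$R2[2],
                 p = fit$`Pr(>F)`[1],
                 df = fit$Df[1],
                 n_permutations = n_permutations,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$F, x$R2, x$p, x$n_permutations))
  invisible(x)
}
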