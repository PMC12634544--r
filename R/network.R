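## Compositional co-occurrence networks: SparCC correlation inference
## (log-ratio variance procedure), permutation significance, BH-FDR
## thresholding at |rho| > 0.6 & q < 0.01, and igraph-based topology.

#' SparCC compositional correlations
#'
#' Estimates correlations between the unobserved basis (absolute) abundances
#' of taxa from compositional counts via the log-ratio variance procedure:
#' for fractions `x`, `T_ij = var(log(x_i / x_j))` is computed for all pairs,
#' basis variances `w_i^2` are solved from the linear system implied by the
#' sparsity assumption (most pairs uncorrelated), and
#' `rho_ij = (w_i^2 + w_j^2 - T_ij) / (2 w_i w_j)`, clipped to `[-1, 1]`.
#' Pairs whose estimated |rho| exceeds `exclusion_threshold` are iteratively
#' excluded from the basis-variance system (strong correlations violate the
#' sparsity assumption), up to `max_exclusions` pairs.
#'
#' Zeros are handled by a pseudocount of 1 before closing counts to
#' fractions (default, deterministic), or by Dirichlet resampling of the
#' fractions (`alpha = count + 1`, `n_inner_iterations` draws, element-wise
#' median of the estimates).
#'
#' @param m a `count_matrix` or taxa x sample numeric matrix with at least 4
#'   taxa and 5 samples.
#' @param method `"pseudocount"` (default) or `"dirichlet"`.
#' @param n_inner_iterations Dirichlet resampling iterations (default 20;
#'   ignored for pseudocount).
#' @param exclusion_threshold |rho| above which a pair is excluded from the
#'   basis-variance system (default 0.8).
#' @param max_exclusions maximum excluded pairs (default `floor(n_taxa / 3)`).
#' @param seed seed for Dirichlet resampling.
#' @return An object of class `sparcc_estimate`: list with `rho` (symmetric,
#'   unit diagonal), `excluded_pairs`, `iterations`, `method`, and slots `p`
#'   and `q` filled by [sparcc_pvalues()].
#' @export
sparcc <- function(m, method = c("pseudocount", "dirichlet"),
                   n_inner_iterations = 20,
                   exclusion_threshold = 0.8,
                   max_exclusions = NULL, seed = 1) {
  method <- match.arg(method)
  counts <- as_count_input(m)
  d <- nrow(counts)
  n <- ncol(counts)
  if (d < 4L) abort("SparCC needs at least 4 taxa (basis system underdetermined)")
  if (n < 5L) abort("SparCC needs at least 5 samples")
  if (any(apply(counts, 1, stats::sd) == 0) && method == "pseudocount" &&
      all(counts == counts[, 1]))
    abort("degenerate input: all samples identical")
  if (is.null(max_exclusions)) max_exclusions <- floor(d / 3)

  run_once <- function(frac) {
    sparcc_core(frac, exclusion_threshold, max_exclusions)
  }

  if (method == "pseudocount") {
    frac <- sweep(counts + 1, 2, colSums(counts + 1), `/`)
    res <- run_once(frac)
    rho <- res$rho
    excluded <- res$excluded
    iters <- 1L
  } else {
    set.seed(substream_seed(seed, "sparcc_dirichlet"))
    iters <- as.integer(n_inner_iterations)
    rhos <- array(NA_real_, c(d, d, iters))
    excluded <- NULL
    for (it in seq_len(iters)) {
      frac <- apply(counts + 1, 2, function(a) {
        g <- stats::rgamma(length(a), shape = a)
        g / sum(g)
      })
      res <- run_once(frac)
      rhos[, , it] <- res$rho
      excluded <- res$excluded
    }
    rho <- apply(rhos, c(1, 2), stats::median)
  }
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  structure(list(rho = rho, excluded_pairs = excluded, iterations = iters,
                 method = method,
                 exclusion_threshold = exclusion_threshold,
                 max_exclusions = max_exclusions,
                 p = NULL, q = NULL),
            class = "sparcc_estimate")
}

## one SparCC pass on a fractions matrix (taxa x samples)
sparcc_core <- function(frac, exclusion_threshold, max_exclusions) {
  d <- nrow(frac)
  lf <- log(frac)
  # T_ij = var(log(x_i / x_j)); var of difference expands via the covariance
  V <- stats::cov(t(lf))
  Tm <- outer(diag(V), diag(V), `+`) - 2 * V
  diag(Tm) <- 0
  # basis system: M w2 = t, M = (d-2) I + J initially; exclusions knock
  # pair contributions out of both M and t
  M <- matrix(1, d, d)
  diag(M) <- d - 1
  active <- matrix(TRUE, d, d)
  diag(active) <- FALSE
  excluded <- matrix(integer(0), 0, 2)
  repeat {
    tvec <- rowSums(Tm * active)
    w2 <- solve(M, tvec)
    w2 <- pmax(w2, 1e-12)
    w <- sqrt(w2)
    rho <- (outer(w2, w2, `+`) - Tm) / (2 * outer(w, w))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (nrow(excluded) >= max_exclusions) break
    cand <- abs(rho) * active
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    active[i, j] <- active[j, i] <- FALSE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    excluded <- rbind(excluded, sort(c(i, j)))
  }
  list(rho = rho, excluded = excluded)
}

#' @export
print.sparcc_estimate <- function(x, ...) {
  cat(sprintf("SparCC estimate (%s): %d taxa, %d excluded pair(s)\n",
              x$method, nrow(x$rho), nrow(x$excluded_pairs)))
  if (!is.null(x$p)) cat("Permutation p-values and BH q-values attached\n")
  invisible(x)
}

#' Permutation p-values and BH q-values for a SparCC estimate
#'
#' Builds the null by independently permuting each taxon's counts across
#' samples (destroying all between-taxon dependence while preserving
#' marginals) and re-estimating the correlation matrix. Two-sided p-value
#' per pair: `(1 + #\{|rho_perm| >= |rho_obs|\}) / (n_permutations + 1)`,
#' comparing each pair against its own permuted values. Benjamini-Hochberg
#' q-values are computed over the upper triangle and attached alongside.
#'
#' @param estimate a `sparcc_estimate` computed on `m`.
#' @param m the `count_matrix` (or matrix) the estimate came from.
#' @param n_permutations at least 19 (otherwise p < 0.05 is unreachable).
#' @param seed integer seed.
#' @param pool pool null values across all pairs before comparing (finer
#'   null resolution at the same cost; default `FALSE`, each pair against
#'   its own permuted values with denominator `n_permutations + 1`).
#' @return The estimate with matrices `p` and `q` filled in.
#' @export
sparcc_pvalues <- function(estimate, m, n_permutations = 99, seed = 1,
                           pool = FALSE) {
  stopifnot(inherits(estimate, "sparcc_estimate"))
  counts <- as_count_input(m)
  if (n_permutations < 19)
    abort("n_permutations must be at least 19 to resolve p < 0.05")
  d <- nrow(counts)
  set.seed(substream_seed(seed, "sparcc_permutation"))
  obs <- abs(estimate$rho[upper.tri(estimate$rho)])
  if (pool) null_pool <- numeric(0)
  exceed <- numeric(length(obs))
  for (b in seq_len(n_permutations)) {
    perm <- t(apply(counts, 1, sample))
    est_b <- sparcc(perm, method = estimate$method,
                    exclusion_threshold = estimate$exclusion_threshold,
                    max_exclusions = estimate$max_exclusions,
                    seed = seed + b)
    vals <- abs(est_b$rho[upper.tri(est_b$rho)])
    if (pool) null_pool <- c(null_pool, vals)
    else exceed <- exceed + (vals >= obs)
  }
  if (pool) {
    n_null <- length(null_pool)
    srt <- sort(null_pool)
    ge <- n_null - findInterval(obs - 1e-15, srt)
    p_up <- (1 + ge) / (1 + n_null)
  } else {
    p_up <- (1 + exceed) / (1 + n_permutations)
  }
  p <- matrix(1, d, d, dimnames = dimnames(estimate$rho))
  p[upper.tri(p)] <- p_up
  p <- pmin(p, t(p))
  diag(p) <- NA_real_
  estimate$p <- p
  estimate$q <- bh_fdr(p)
  estimate$n_permutations <- n_permutations
  estimate
}

#' Benjamini-Hochberg FDR adjustment over a symmetric p-value matrix
#'
#' Applies the step-up adjustment ([stats::p.adjust()] with `method = "BH"`)
#' to the upper triangle and mirrors the result. Also accepts a plain vector.
#'
#' @param p symmetric matrix (diagonal ignored) or vector of p-values in
#'   `[0, 1]`.
#' @return q-values with the same shape as the input.
#' @export
bh_fdr <- function(p) {
  vals <- if (is.matrix(p)) p[upper.tri(p)] else p
  if (any(!is.na(vals) & (vals < 0 | vals > 1)))
    abort("p-values must lie in [0, 1]")
  q_up <- stats::p.adjust(vals, method = "BH")
  if (!is.matrix(p)) return(q_up)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  q[upper.tri(q)] <- q_up
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  q
}

#' Threshold a SparCC estimate into a co-occurrence network
#'
#' Retains exactly the pairs with `|rho| > rho_min` and `q < q_max`
#' (defaults 0.6 and 0.01), recording each edge's sign. Taxa without any
#' retained edge are dropped from the node set unless `keep_isolates = TRUE`.
#'
#' @param estimate a `sparcc_estimate` with q-values attached
#'   (see [sparcc_pvalues()]).
#' @param rho_min correlation-magnitude threshold in `[0, 1)`.
#' @param q_max FDR threshold in `(0, 1]`.
#' @param keep_isolates keep taxa with no retained edges as isolated nodes.
#' @return An object of class `cooccurrence_network`: list with `edges`
#'   (data.frame: `taxon_a`, `taxon_b`, `rho`, `p`, `q`, `sign`), `nodes`,
#'   `thresholds` and `keep_isolates`.
#' @export
build_network <- function(estimate, rho_min = 0.6, q_max = 0.01,
                          keep_isolates = FALSE) {
  stopifnot(inherits(estimate, "sparcc_estimate"))
  if (is.null(estimate$q))
    abort("estimate has no q-values; run sparcc_pvalues() first")
  if (rho_min < 0 || rho_min >= 1) abort("rho_min must lie in [0, 1)")
  if (q_max <= 0 || q_max > 1) abort("q_max must lie in (0, 1]")
  rho <- estimate$rho
  q <- estimate$q
  idx <- which(upper.tri(rho) & abs(rho) > rho_min & q < q_max, arr.ind = TRUE)
  taxa <- rownames(rho)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(rho)))
  edges <- data.frame(
    taxon_a = taxa[idx[, 1]],
    taxon_b = taxa[idx[, 2]],
    rho = rho[idx],
    p = estimate$p[idx],
    q = q[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  nodes <- if (keep_isolates) taxa else sort(unique(c(edges$taxon_a, edges$taxon_b)))
  structure(list(edges = edges, nodes = nodes,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 keep_isolates = keep_isolates),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (|rho| > %g, q < %g)\n",
              length(x$nodes), nrow(x$edges),
              x$thresholds["rho_min"], x$thresholds["q_max"]))
  if (nrow(x$edges))
    cat(sprintf("  %d positive, %d negative\n",
                sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

## internal: igraph object from a cooccurrence_network
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "rho", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Global topology metrics of a co-occurrence network
#'
#' Node and edge counts, average degree `2E / N`, global transitivity
#' (3 x triangles / connected triples), graph density, and the modularity Q
#' of the partition found by greedy agglomerative community detection on the
#' unweighted graph (via igraph). An empty network returns all-zero metrics
#' with `empty = TRUE`.
#'
#' @param net a `cooccurrence_network`.
#' @return An object of class `network_topology`: list with `n_nodes`,
#'   `n_edges`, `average_degree`, `transitivity`, `density`, `modularity`
#'   and `empty`.
#' @export
network_topology <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n_nodes <- length(net$nodes)
  n_edges <- nrow(net$edges)
  if (n_nodes == 0L || n_edges == 0L) {
    return(structure(list(n_nodes = n_nodes, n_edges = n_edges,
                          average_degree = 0, transitivity = 0, density = 0,
                          modularity = 0, empty = TRUE),
                     class = "network_topology"))
  }
  g <- as_igraph(net)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  comm <- igraph::cluster_fast_greedy(g)
  structure(list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    average_degree = 2 * n_edges / n_nodes,
    transitivity = trans,
    density = igraph::edge_density(g),
    modularity = igraph::modularity(g, igraph::membership(comm)),
    empty = FALSE), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0("Network topology: %d nodes, %d edges, avg degree %.2f, ",
                     "transitivity %.3f, density %.3f, modularity %.3f\n"),
              x$n_nodes, x$n_edges, x$average_degree, x$transitivity,
              x$density, x$modularity))
  invisible(x)
}

#' Aggregate a count matrix to a higher taxonomic level
#'
#' Sums counts of taxa that share a lineage label — e.g. collapse ASV-level
#' counts to phylum-level counts before network inference.
#'
#' @param m a `count_matrix` or taxa x sample matrix.
#' @param lineage character vector, one label per taxon (row).
#' @param top keep only the `top` most abundant aggregated groups
#'   (default all).
#' @return A matrix (groups x samples); for a `count_matrix` input, a
#'   `count_matrix` with the same treatments map.
#' @export
aggregate_taxa <- function(m, lineage, top = NULL) {
  counts <- as_count_input(m)
  if (length(lineage) != nrow(counts))
    abort("lineage must have one label per taxon")
  agg <- rowsum(counts, group = lineage)
  if (!is.null(top)) {
    keep <- order(rowSums(agg), decreasing = TRUE)[seq_len(min(top, nrow(agg)))]
    agg <- agg[sort(keep), , drop = FALSE]
  }
  if (inherits(m, "count_matrix")) {
    out <- m
    out$counts <- agg
    out$true_correlation <- NULL
    return(out)
  }
  agg
}
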