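# Shared fixtures built in code.

# Table of group means/SDs bundled with the package, reshaped wide for
# convenient lookup: params("LAP", "B3") -> c(mean, sd)
soil_params <- soil_param_table()
param <- function(variable, treatment, field = "mean") {
  soil_params[soil_params$variable == variable &
              soil_params$treatment == treatment, field]
}

# small config helpers
count_config <- function(seed, n_taxa, n_samples, log_cov = diag(n_taxa),
                         read_depth = 2000, log_mean = rep(0, n_taxa),
                         fold_changes = NULL) {
  synthetic_config(seed = seed, variable_specs = NULL,
                   count_spec = list(n_taxa = n_taxa, read_depth = read_depth,
                                     log_mean = log_mean, log_cov = log_cov,
                                     fold_changes = fold_changes,
                                     n_samples_per_treatment = n_samples))
}

latent_config <- function(seed, beta = 0.8, loadings = 0.9, n = 500,
                          blocks = list(LV1 = c("x1", "x2", "x3"),
                                        LV2 = c("x4", "x5", "x6"))) {
  synthetic_config(seed = seed, variable_specs = NULL, latent_spec = list(
    blocks = blocks,
    path_matrix = matrix(c(0, 0, beta, 0), 2, 2, byrow = TRUE),
    loadings = loadings, noise_sd = NULL, n_samples = n))
}

# fabricate a sparcc_estimate with prescribed rho / q (for thresholding tests)
fake_estimate <- function(rho_pairs, q_pairs, d) {
  rho <- diag(d); q <- matrix(NA_real_, d, d)
  for (k in seq_along(rho_pairs)) {
    ij <- attr(rho_pairs, "pairs")[[k]]
    rho[ij[1], ij[2]] <- rho[ij[2], ij[1]] <- rho_pairs[k]
    q[ij[1], ij[2]] <- q[ij[2], ij[1]] <- q_pairs[k]
  }
  q[is.na(q)] <- 1
  diag(q) <- NA_real_
  dimnames(rho) <- dimnames(q) <- list(paste0("t", 1:d), paste0("t", 1:d))
  structure(list(rho = rho, p = q, q = q, excluded_pairs = NULL,
                 iterations = 1L, method = "pseudocount"),
            class = "sparcc_estimate")
}

pairs_spec <- function(x, pairs) { attr(x, "pairs") <- pairs; x }

# wrap an edge index matrix as a cooccurrence_network (keeping all nodes)
edges_to_net <- function(edges, nodes) {
  lab <- function(x) if (length(x)) paste0("n", x) else character(0)
  structure(list(
    edges = data.frame(taxon_a = lab(edges[, 1]),
                       taxon_b = lab(edges[, 2]),
                       rho = rep(0.9, nrow(edges)), p = rep(0.001, nrow(edges)),
                       q = rep(0.001, nrow(edges)),
                       sign = rep("positive", nrow(edges)),
                       stringsAsFactors = FALSE),
    nodes = paste0("n", nodes),
    thresholds = c(rho_min = 0.6, q_max = 0.01), keep_isolates = TRUE),
    class = "cooccurrence_network")
}

# brute-force global clustering coefficient by triple counting
brute_transitivity <- function(adj) {
  n <- nrow(adj); tri <- 0; triples <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] && adj[j, k]) {
      triples <- triples + 1
      if (adj[i, k]) tri <- tri + 1
    }
  }
  if (triples == 0) 0 else tri / triples
}
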